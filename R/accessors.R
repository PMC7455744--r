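# Accessor and show methods.

#' @rdname GenomeModel-class
#' @export
setMethod("chromLengths", "GenomeModel", function(object) {
  sl <- seqlengths(object@genes)
  stats::setNames(as.double(sl), names(sl))
})

#' @rdname GenomeModel-class
#' @export
setMethod("codingSize", "GenomeModel", function(object) object@codingSize)

#' @rdname GenomeModel-class
#' @export
setMethod("autosomeSize", "GenomeModel",
          function(object) sum(chromLengths(object)))

#' @rdname GenomeModel-class
#' @export
setMethod("geneCatalogue", "GenomeModel", function(object) object@genes)

setMethod("show", "GenomeModel", function(object) {
  cl <- chromLengths(object)
  cat("GenomeModel with", length(cl), "autosomes,",
      sprintf("%.1f Mbp total", sum(cl) / 1e6), "\n")
  cat("  coding:", sprintf("%.1f Mbp", codingSize(object) / 1e6),
      " genes:", length(object@genes), "\n")
})

#' @rdname SexBiasDataset-class
#' @export
setMethod("donorTable", "SexBiasDataset", function(object) object@cohort)

#' @rdname SexBiasDataset-class
#' @export
setMethod("driverMatrix", "SexBiasDataset", function(object) object@drivers)

#' @rdname SexBiasDataset-class
#' @export
setMethod("snvTable", "SexBiasDataset", function(object) object@snv)

#' @rdname SexBiasDataset-class
#' @export
setMethod("segmentTable", "SexBiasDataset", function(object) object@segments)

#' @rdname SexBiasDataset-class
#' @export
setMethod("clonalityTable", "SexBiasDataset",
          function(object) object@clonality)

#' @rdname SexBiasDataset-class
#' @export
setMethod("timingTable", "SexBiasDataset", function(object) object@timing)

#' @rdname SexBiasDataset-class
#' @export
setMethod("signatureCounts", "SexBiasDataset",
          function(object) object@signatures)

#' @rdname SexBiasDataset-class
#' @export
setMethod("signatureClasses", "SexBiasDataset",
          function(object) object@signatureClass)

#' @rdname SexBiasDataset-class
#' @export
setMethod("genomeModel", "SexBiasDataset", function(object) object@genome)

#' @rdname SexBiasDataset-class
#' @export
setMethod("plantedTruth", "SexBiasDataset", function(object) object@truth)

setMethod("show", "SexBiasDataset", function(object) {
  co <- object@cohort
  cat("SexBiasDataset:", nrow(co), "donors,",
      length(unique(co$subtype)), "subtypes",
      sprintf("(%d male / %d female)\n",
              sum(co$sex == "male"), sum(co$sex == "female")))
  comp <- c(
    drivers = ncol(object@drivers),
    `snv donors` = nrow(object@snv),
    segments = length(object@segments),
    `clonality donors` = nrow(object@clonality),
    `timing rows` = nrow(object@timing),
    signatures = ncol(object@signatures),
    `planted effects` = nrow(object@truth))
  for (nm in names(comp)) cat("  ", nm, ": ", comp[[nm]], "\n", sep = "")
})

#' @rdname FeatureSet-class
#' @export
setMethod("featureValues", "FeatureSet", function(object) object@values)

#' @rdname FeatureSet-class
#' @export
setMethod("featureInfo", "FeatureSet", function(object) object@info)

setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet:", nrow(object@info), "features,",
      nrow(object@values), "donor-level values\n")
  tab <- table(object@info$analysis)
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
})

#' Combine feature sets
#'
#' @param ... `FeatureSet` objects with disjoint feature ids.
#' @return A single `FeatureSet`.
#' @export
combineFeatures <- function(...) {
  fs <- list(...)
  fs <- fs[!vapply(fs, is.null, logical(1))]
  stopifnot(all(vapply(fs, is, logical(1), "FeatureSet")))
  new("FeatureSet",
      values = do.call(rbind, lapply(fs, featureValues)),
      info = do.call(rbind, lapply(fs, featureInfo)))
}

#' @rdname SexBiasReport-class
#' @export
setMethod("stage1Results", "SexBiasReport", function(object) object@stage1)

#' @rdname SexBiasReport-class
#' @export
setMethod("stage2Results", "SexBiasReport", function(object) object@stage2)

#' @rdname SexBiasReport-class
#' @export
setMethod("robustnessResults", "SexBiasReport",
          function(object) object@robustness)

#' @rdname SexBiasReport-class
#' @export
setMethod("extendedResults", "SexBiasReport", function(object) object@extended)

#' @rdname SexBiasReport-class
#' @export
setMethod("findingsTable", "SexBiasReport", function(object) object@findings)

#' @rdname SexBiasReport-class
#' @export
setMethod("truthComparison", "SexBiasReport",
          function(object) object@truthComparison)

setMethod("show", "SexBiasReport", function(object) {
  s1 <- object@stage1; s2 <- object@stage2; fd <- object@findings
  cat("SexBiasReport\n")
  cat(sprintf("  stage 1: %d comparisons, %d candidates (q < %.2g)\n",
              nrow(s1), sum(s1$candidate %in% TRUE),
              object@config$thresholds$qCandidate %||% 0.1))
  cat(sprintf("  stage 2: %d fits, %d significant\n",
              nrow(s2), sum(s2$significant %in% TRUE)))
  cat(sprintf("  stage 3: %d down-sampling verdicts (%d pass)\n",
              nrow(object@robustness),
              sum(object@robustness$verdict %in% "pass")))
  if (nrow(fd)) {
    tab <- table(fd$status)
    cat("  findings:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  } else cat("  findings: none\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
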