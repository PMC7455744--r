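# Stage 0: derive per-donor analysis features from raw-style inputs.

.featureSet <- function(values, info) {
  rownames(values) <- NULL; rownames(info) <- NULL
  new("FeatureSet", values = values, info = info)
}

.featDf <- function(donor, feature, value) {
  data.frame(donor_id = donor, feature_id = feature, value = value,
             stringsAsFactors = FALSE)
}

.infoDf <- function(feature, analysis, kind, group = NA_character_) {
  data.frame(feature_id = feature, analysis = analysis, kind = kind,
             group = group, stringsAsFactors = FALSE)
}

#' Mutation density features (mutations per Mbp)
#'
#' Overall density divides total SNVs by the autosome size, coding density
#' divides coding SNVs by the coding size, and non-coding density divides
#' the remainder by the non-coding size (autosome minus coding: the two
#' regions partition the autosome exhaustively).
#'
#' @param snv data.frame with donor_id, coding_count, noncoding_count.
#' @param genome A \linkS4class{GenomeModel}.
#' @return A \linkS4class{FeatureSet} with features density_overall,
#'   density_coding, density_noncoding.
#' @export
computeMutationDensity <- function(snv, genome) {
  autoMbp <- autosomeSize(genome) / 1e6
  codMbp <- codingSize(genome) / 1e6
  nonMbp <- autoMbp - codMbp
  if (autoMbp <= 0 || codMbp <= 0 || nonMbp <= 0)
    stop("genome sizes give a zero denominator")
  if (any(snv$coding_count < 0) || any(snv$noncoding_count < 0))
    stop("SNV counts must be non-negative")
  vals <- rbind(
    .featDf(snv$donor_id, "density_overall",
            (snv$coding_count + snv$noncoding_count) / autoMbp),
    .featDf(snv$donor_id, "density_coding", snv$coding_count / codMbp),
    .featDf(snv$donor_id, "density_noncoding",
            snv$noncoding_count / nonMbp))
  info <- .infoDf(c("density_overall", "density_coding",
                    "density_noncoding"),
                  "density", "continuous",
                  c("overall", "coding", "noncoding"))
  .featureSet(vals, info)
}

#' Percent chromosome / genome gained, lost and altered
#'
#' Basepairs in gain (loss) segments are summed per donor and chromosome
#' and divided by the chromosome size, x100.  "Altered" sums segments with
#' any aberration; because gain and loss intervals are disjoint by
#' invariant, altered = gained + lost.  Autosome-wide values divide by the
#' total autosome size.  Donors without segments score 0 everywhere, which
#' is why the full donor list must be supplied.
#'
#' @param segments `GRanges` with donor_id and call metadata columns.
#' @param genome A \linkS4class{GenomeModel}.
#' @param donors Character vector of all donor ids to emit values for.
#' @param chromLevel Also emit per-chromosome features (default TRUE).
#' @return A \linkS4class{FeatureSet} with features
#'   `pga_{gain,loss,alt}_auto` and optionally `pga_{gain,loss,alt}_chr*`.
#' @export
computeInstability <- function(segments, genome, donors,
                               chromLevel = TRUE) {
  cl <- chromLengths(genome)
  if (length(segments)) {
    lim <- cl[as.character(seqnames(segments))]
    if (any(start(segments) < 1L) || any(end(segments) > lim))
      stop("segment outside chromosome bounds")
  }
  nD <- length(donors)
  dIdx <- seq_len(nD); names(dIdx) <- donors
  sumBp <- function(sel) {
    # donors x chrom matrix of aberrant bp for the selected segments
    m <- matrix(0, nD, length(cl), dimnames = list(donors, names(cl)))
    if (any(sel)) {
      s <- segments[sel]
      agg <- stats::aggregate(
        width ~ donor_id + chrom,
        data = data.frame(donor_id = s$donor_id,
                          chrom = as.character(seqnames(s)),
                          width = width(s)),
        FUN = sum)
      m[cbind(unname(dIdx[agg$donor_id]),
              match(agg$chrom, colnames(m)))] <- agg$width
    }
    m
  }
  gainBp <- sumBp(segments$call == "gain")
  lossBp <- sumBp(segments$call == "loss")
  altBp <- gainBp + lossBp
  vals <- list(); info <- list()
  emit <- function(feature, value, group) {
    vals[[length(vals) + 1L]] <<- .featDf(donors, feature, value)
    info[[length(info) + 1L]] <<-
      .infoDf(feature, "instability", "continuous", group)
  }
  for (piece in list(list("gain", gainBp), list("loss", lossBp),
                     list("alt", altBp))) {
    lab <- piece[[1]]; m <- piece[[2]]
    emit(sprintf("pga_%s_auto", lab), rowSums(m) / sum(cl) * 100, "auto")
    if (chromLevel)
      for (ch in names(cl))
        emit(sprintf("pga_%s_chr%s", lab, ch), m[, ch] / cl[[ch]] * 100,
             ch)
  }
  .featureSet(do.call(rbind, vals), do.call(rbind, info))
}

#' Gene-level copy number calls from segments
#'
#' Assigns each (donor, gene) a call in gain/neutral/loss.  Under the
#' default "majority" rule a gene is called gained when more than half of
#' its length is covered by gain segments, else lost when more than half is
#' covered by loss segments, else neutral (an exact 50/50 tie is neutral).
#' Under "any", the direction with the larger covered length wins as soon
#' as any aberrant overlap exists (ties neutral).  Genes with no
#' overlapping aberrant segment are neutral; neutral segments need not be
#' present in the input.
#'
#' @param segments `GRanges` with donor_id and call metadata columns.
#' @param genome A \linkS4class{GenomeModel} with a non-empty gene
#'   catalogue.
#' @param donors Character vector of all donor ids.
#' @param rule "majority" (default) or "any".
#' @return Character matrix donors x genes with values gain/neutral/loss.
#' @export
callGeneCna <- function(segments, genome, donors,
                        rule = c("majority", "any")) {
  rule <- match.arg(rule)
  genes <- geneCatalogue(genome)
  if (!length(genes)) stop("gene catalogue is empty")
  nD <- length(donors); dIdx <- stats::setNames(seq_len(nD), donors)
  cov <- function(call) {
    m <- matrix(0, nD, length(genes),
                dimnames = list(donors, genes$gene_id))
    sel <- which(segments$call == call)
    if (length(sel)) {
      s <- segments[sel]
      hits <- findOverlaps(genes, s)
      if (length(hits)) {
        ow <- width(pintersect(genes[queryHits(hits)], s[subjectHits(hits)]))
        df <- stats::aggregate(
          w ~ d + g, FUN = sum,
          data = data.frame(d = s$donor_id[subjectHits(hits)],
                            g = queryHits(hits), w = ow))
        m[cbind(unname(dIdx[df$d]), df$g)] <- df$w
      }
    }
    m
  }
  gainBp <- cov("gain"); lossBp <- cov("loss")
  gl <- rep(width(genes), each = nD)
  calls <- matrix("neutral", nD, length(genes),
                  dimnames = list(donors, genes$gene_id))
  if (rule == "majority") {
    calls[gainBp * 2 > gl] <- "gain"
    calls[gainBp * 2 <= gl & lossBp * 2 > gl] <- "loss"
  } else {
    some <- gainBp > 0 | lossBp > 0
    calls[some & gainBp > lossBp] <- "gain"
    calls[some & lossBp > gainBp] <- "loss"
  }
  calls
}

#' Binary gain/loss features per gene
#'
#' @param calls Matrix from [callGeneCna()].
#' @return A \linkS4class{FeatureSet} with features `cna_gain_<gene>` and
#'   `cna_loss_<gene>`.
#' @export
geneCnaFeatures <- function(calls) {
  donors <- rownames(calls)
  vals <- list(); info <- list()
  for (dir in c("gain", "loss")) {
    for (g in colnames(calls)) {
      id <- sprintf("cna_%s_%s", dir, g)
      vals[[id]] <- .featDf(donors, id, as.numeric(calls[, g] == dir))
      info[[id]] <- .infoDf(id, "gene_cna", "binary", dir)
    }
  }
  .featureSet(do.call(rbind, vals), do.call(rbind, info))
}

#' Polyclonality indicator
#'
#' A tumour with one subclonal cluster is monoclonal (0); more than one
#' cluster is polyclonal (1).
#'
#' @param clonality data.frame with donor_id, n_clusters.
#' @return A \linkS4class{FeatureSet} with the binary `polyclonal` feature.
#' @export
binarizeClonality <- function(clonality) {
  if (any(clonality$n_clusters < 1L))
    stop("n_clusters must be >= 1")
  .featureSet(
    .featDf(clonality$donor_id, "polyclonal",
            as.numeric(clonality$n_clusters > 1L)),
    .infoDf("polyclonal", "clonality", "binary"))
}

#' Truncal variant fraction per class
#'
#' fraction = truncal / (truncal + subclonal) per variant class.  Donors
#' with zero variants of a class carry no information about that class's
#' timing; 0/0 is undefined, so they are excluded from that feature
#' (complete-case convention).
#'
#' @param timing data.frame with donor_id, variant_class, n_truncal,
#'   n_subclonal.
#' @return A \linkS4class{FeatureSet} with features `truncal_<class>`.
#' @export
computeTruncalFraction <- function(timing) {
  if (any(timing$n_truncal < 0) || any(timing$n_subclonal < 0))
    stop("timing counts must be non-negative")
  tot <- timing$n_truncal + timing$n_subclonal
  keep <- tot > 0
  t2 <- timing[keep, , drop = FALSE]
  classes <- unique(timing$variant_class)
  vals <- .featDf(t2$donor_id, paste0("truncal_", t2$variant_class),
                  t2$n_truncal / tot[keep])
  .featureSet(vals,
              .infoDf(paste0("truncal_", classes), "timing", "continuous",
                      classes))
}

#' Signature presence and activity features
#'
#' Per signature: a binary "signature-positive" indicator (any attributed
#' mutations) and, among positive donors, the fraction of the donor's
#' class-total mutations attributed to the signature.  Donors whose class
#' total is zero carry no attribution information for that class and are
#' excluded from both feature kinds.
#'
#' @param counts Integer matrix donors x signatures.
#' @param classes Named character, signature -> class.
#' @return A \linkS4class{FeatureSet} with features `sig_<id>_present`
#'   (binary) and `sig_<id>_activity` (continuous fractions).
#' @export
computeSignatureFeatures <- function(counts, classes) {
  if (any(counts < 0)) stop("attributed counts must be non-negative")
  donors <- rownames(counts)
  vals <- list(); info <- list()
  for (clName in unique(classes)) {
    jj <- names(classes)[classes == clName]
    tot <- rowSums(counts[, jj, drop = FALSE])
    ok <- tot > 0
    for (id in jj) {
      pid <- sprintf("sig_%s_present", id)
      aid <- sprintf("sig_%s_activity", id)
      pos <- counts[ok, id] > 0
      vals[[pid]] <- .featDf(donors[ok], pid, as.numeric(pos))
      info[[pid]] <- .infoDf(pid, "sig_presence", "binary", clName)
      posD <- which(ok)[pos]
      if (length(posD)) {
        vals[[aid]] <- .featDf(donors[posD], aid,
                               counts[posD, id] / tot[posD])
      } else {
        vals[[aid]] <- .featDf(character(), aid, numeric())
      }
      info[[aid]] <- .infoDf(aid, "sig_activity", "continuous", clName)
    }
  }
  .featureSet(do.call(rbind, vals), do.call(rbind, info))
}

#' Binary driver-event features
#'
#' @param drivers Integer 0/1 matrix, donors x events.
#' @return A \linkS4class{FeatureSet} with features `driver_<event>`.
#' @export
driverFeatures <- function(drivers) {
  donors <- rownames(drivers)
  vals <- list(); info <- list()
  for (ev in colnames(drivers)) {
    id <- paste0("driver_", ev)
    vals[[id]] <- .featDf(donors, id, as.numeric(drivers[, ev]))
    info[[id]] <- .infoDf(id, "driver", "binary")
  }
  .featureSet(do.call(rbind, vals), do.call(rbind, info))
}

#' Derive all analysis features from a dataset
#'
#' Runs the per-component feature derivations for the requested analyses,
#' skipping analyses whose raw component is absent from the dataset.
#'
#' @param dataset A \linkS4class{SexBiasDataset}.
#' @param analyses Character subset of driver, density, instability,
#'   gene_cna, clonality, timing, sig_presence, sig_activity.
#' @param chromLevel Emit per-chromosome instability features.
#' @param cnaRule Gene CNA call rule, see [callGeneCna()].
#' @return A \linkS4class{FeatureSet}.
#' @export
computeFeatures <- function(dataset,
                            analyses = c("driver", "density",
                                         "instability", "gene_cna",
                                         "clonality", "timing",
                                         "sig_presence", "sig_activity"),
                            chromLevel = TRUE,
                            cnaRule = "majority") {
  analyses <- match.arg(analyses, several.ok = TRUE)
  donors <- donorTable(dataset)$donor_id
  parts <- list()
  if ("driver" %in% analyses && ncol(driverMatrix(dataset)))
    parts$driver <- driverFeatures(driverMatrix(dataset))
  if ("density" %in% analyses && nrow(snvTable(dataset)))
    parts$density <- computeMutationDensity(snvTable(dataset),
                                            genomeModel(dataset))
  if ("instability" %in% analyses)
    parts$instability <- computeInstability(
      segmentTable(dataset), genomeModel(dataset), donors,
      chromLevel = chromLevel)
  if ("gene_cna" %in% analyses && length(segmentTable(dataset)))
    parts$gene_cna <- geneCnaFeatures(
      callGeneCna(segmentTable(dataset), genomeModel(dataset), donors,
                  rule = cnaRule))
  if ("clonality" %in% analyses && nrow(clonalityTable(dataset)))
    parts$clonality <- binarizeClonality(clonalityTable(dataset))
  if ("timing" %in% analyses && nrow(timingTable(dataset)))
    parts$timing <- computeTruncalFraction(timingTable(dataset))
  if (any(c("sig_presence", "sig_activity") %in% analyses) &&
      ncol(signatureCounts(dataset))) {
    sig <- computeSignatureFeatures(signatureCounts(dataset),
                                    signatureClasses(dataset))
    keep <- featureInfo(sig)$analysis %in% analyses
    ids <- featureInfo(sig)$feature_id[keep]
    sig <- .featureSet(
      featureValues(sig)[featureValues(sig)$feature_id %in% ids, ,
                         drop = FALSE],
      featureInfo(sig)[keep, , drop = FALSE])
    parts$signatures <- sig
  }
  if (!length(parts)) stop("no features could be derived")
  do.call(combineFeatures, unname(parts))
}
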