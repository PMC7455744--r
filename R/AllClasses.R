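#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect mcols
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom GenomeInfoDb seqlengths seqlevels Seqinfo seqinfo
NULL

.emptyDf <- function(...) {
  cols <- list(...)
  as.data.frame(lapply(cols, function(cl) vector(cl, 0L)),
                col.names = names(cols), stringsAsFactors = FALSE)
}

#' GenomeModel: an autosome-only reference model
#'
#' Holds chromosome sizes for (a subset of) the 22 human autosomes, a gene
#' catalogue as a \linkS4class{GRanges}, and the total size of the coding
#' portion of the autosomes.  Sex chromosomes are deliberately absent: the
#' analyses this package implements are restricted to the autosome.
#'
#' Coordinates are stored 1-based closed (the GRanges convention); on-disk
#' interchange uses 0-based half-open BED-like columns, converted at the I/O
#' boundary.
#'
#' @slot genes A `GRanges` of gene intervals with a `gene_id` metadata column;
#'   seqinfo carries the chromosome lengths.
#' @slot codingSize Total coding basepairs across the autosomes.
#' @export
setClass("GenomeModel",
  representation(genes = "GRanges", codingSize = "numeric"))

setValidity("GenomeModel", function(object) {
  msg <- character()
  sl <- seqlengths(object@genes)
  if (length(sl) == 0L || any(is.na(sl)))
    msg <- c(msg, "chromosome lengths must be defined in seqinfo")
  if (!all(seqlevels(object@genes) %in% as.character(1:22)))
    msg <- c(msg, "only autosomes '1'..'22' are allowed")
  if (any(sl <= 0, na.rm = TRUE))
    msg <- c(msg, "chromosome lengths must be positive")
  if (length(object@codingSize) != 1L || !is.finite(object@codingSize) ||
      object@codingSize <= 0)
    msg <- c(msg, "codingSize must be a single positive number")
  else if (object@codingSize >= sum(as.double(sl)))
    msg <- c(msg, "codingSize must be smaller than the autosome total")
  if (length(object@genes)) {
    if (is.null(object@genes$gene_id) || anyDuplicated(object@genes$gene_id))
      msg <- c(msg, "genes need a unique gene_id column")
    if (any(width(object@genes) < 1L))
      msg <- c(msg, "gene intervals must have positive width")
    lim <- sl[as.character(seqnames(object@genes))]
    if (any(start(object@genes) < 1L) || any(end(object@genes) > lim))
      msg <- c(msg, "gene intervals must lie within chromosome bounds")
  }
  if (length(msg)) msg else TRUE
})

#' SexBiasDataset: raw per-donor inputs for the pipeline
#'
#' Container for a cohort annotation table and the raw-style genomic inputs
#' the pipeline consumes: binary driver-event calls, coding/non-coding SNV
#' counts, ploidy-adjusted gain/loss segments, subclonal cluster counts,
#' truncal/subclonal variant counts per class, and per-signature attributed
#' mutation counts.  Components that a given analysis does not use may be
#' left empty.  When the dataset was simulated, `truth` records the planted
#' sex effects for recovery assessment.
#'
#' @slot cohort data.frame with donor_id, sex, age, ancestry, subtype,
#'   stage, grade.
#' @slot drivers integer 0/1 matrix, donors x driver events.
#' @slot snv data.frame with donor_id, coding_count, noncoding_count.
#' @slot segments `GRanges` with metadata columns donor_id and call
#'   ("gain"/"loss").
#' @slot clonality data.frame with donor_id, n_clusters.
#' @slot timing data.frame with donor_id, variant_class, n_truncal,
#'   n_subclonal.
#' @slot signatures integer matrix of attributed mutation counts,
#'   donors x signatures.
#' @slot signatureClass named character, signature id -> class
#'   ("SBS", "DBS" or "ID").
#' @slot genome A \linkS4class{GenomeModel}.
#' @slot truth data.frame of planted effects (feature_id, scope,
#'   effect_form, magnitude, favoured_sex); zero rows when unknown.
#' @export
setClass("SexBiasDataset",
  representation(cohort = "data.frame", drivers = "matrix",
                 snv = "data.frame", segments = "GRanges",
                 clonality = "data.frame", timing = "data.frame",
                 signatures = "matrix", signatureClass = "character",
                 genome = "GenomeModel", truth = "data.frame"))

setValidity("SexBiasDataset", function(object) {
  msg <- character()
  co <- object@cohort
  need <- c("donor_id", "sex", "age", "ancestry", "subtype", "stage", "grade")
  if (!all(need %in% names(co)))
    return(paste("cohort must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(co$donor_id)) msg <- c(msg, "duplicate donor_id in cohort")
  if (any(is.na(co$sex)) || !all(co$sex %in% c("male", "female")))
    msg <- c(msg, "sex must be 'male' or 'female' and never missing")
  if (any(is.na(co$subtype))) msg <- c(msg, "subtype must never be missing")
  donors <- co$donor_id
  checkDonors <- function(ids, what) {
    if (length(ids) && !all(ids %in% donors))
      paste0(what, " refers to donors absent from the cohort") else character()
  }
  msg <- c(msg,
    checkDonors(rownames(object@drivers), "driver matrix"),
    checkDonors(object@snv$donor_id, "snv table"),
    checkDonors(object@segments$donor_id, "segment table"),
    checkDonors(object@clonality$donor_id, "clonality table"),
    checkDonors(object@timing$donor_id, "timing table"),
    checkDonors(rownames(object@signatures), "signature matrix"))
  if (length(object@segments)) {
    if (!all(object@segments$call %in% c("gain", "loss")))
      msg <- c(msg, "segment call must be 'gain' or 'loss'")
  }
  if (ncol(object@signatures) &&
      !all(colnames(object@signatures) %in% names(object@signatureClass)))
    msg <- c(msg, "every signature column needs a class annotation")
  if (length(object@signatureClass) &&
      !all(object@signatureClass %in% c("SBS", "DBS", "ID")))
    msg <- c(msg, "signature classes must be SBS, DBS or ID")
  if (length(msg)) msg else TRUE
})

#' FeatureSet: derived per-donor analysis features
#'
#' Long-format feature values (one row per donor and feature) plus feature
#' metadata assigning each feature to an analysis, a value kind and an
#' optional grouping label (mutation context, variant class, CNA direction
#' or signature class) used to construct false discovery rate families.
#'
#' @slot values data.frame with donor_id, feature_id, value.
#' @slot info data.frame with feature_id, analysis, kind
#'   ("binary"/"continuous"), group.
#' @export
setClass("FeatureSet",
  representation(values = "data.frame", info = "data.frame"))

setValidity("FeatureSet", function(object) {
  msg <- character()
  if (!all(c("donor_id", "feature_id", "value") %in% names(object@values)))
    return("values needs columns donor_id, feature_id, value")
  if (!all(c("feature_id", "analysis", "kind", "group") %in%
           names(object@info)))
    return("info needs columns feature_id, analysis, kind, group")
  if (anyDuplicated(object@info$feature_id))
    msg <- c(msg, "duplicate feature_id in info")
  if (!all(object@values$feature_id %in% object@info$feature_id))
    msg <- c(msg, "every value row must reference a described feature")
  if (!all(object@info$kind %in% c("binary", "continuous")))
    msg <- c(msg, "kind must be 'binary' or 'continuous'")
  bin <- object@info$feature_id[object@info$kind == "binary"]
  bv <- object@values$value[object@values$feature_id %in% bin]
  if (length(bv) && !all(bv %in% c(0, 1)))
    msg <- c(msg, "binary feature values must be 0/1")
  if (length(msg)) msg else TRUE
})

#' SexBiasReport: staged results of a full pipeline run
#'
#' @slot stage1 data.frame of univariate screening results.
#' @slot stage2 data.frame of covariate-adjusted model fits.
#' @slot robustness data.frame of down-sampling verdicts.
#' @slot extended data.frame of extended-model (stage/grade) refits.
#' @slot findings data.frame reconciling all stages per finding, with a
#'   final status of confirmed, trending or rejected.
#' @slot truthComparison data.frame comparing findings against planted
#'   effects (empty when no truth was available).
#' @slot config the `PipelineConfig`-style list the run used.
#' @export
setClass("SexBiasReport",
  representation(stage1 = "data.frame", stage2 = "data.frame",
                 robustness = "data.frame", extended = "data.frame",
                 findings = "data.frame", truthComparison = "data.frame",
                 config = "list"),
  prototype(
    findings = data.frame(feature_id = character(), scope = character(),
                          analysis = character(), effect1 = numeric(),
                          p1 = numeric(), q1 = numeric(),
                          sex_coefficient = numeric(), p2 = numeric(),
                          q2 = numeric(), verdicts = character(),
                          robust_pass = logical(),
                          extended_q = numeric(), status = character(),
                          reason = character(),
                          stringsAsFactors = FALSE)))
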