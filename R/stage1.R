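# Stage 1: univariate screening of every feature for sex association.

# FDR family assignment.  Families follow the per-analysis adjustment rules
# of the underlying framework: driver events per scope; clonality in one
# family across all scopes; mutation density per context with pan-cancer
# and subtype p-values pooled; instability per scope over gained, lost and
# altered together; gene CNAs per scope and direction; signature presence
# and activity each per scope.
.fdrFamily <- function(analysis, group, scope) {
  switch(analysis,
    driver = paste0("driver|", scope),
    clonality = "clonality",
    density = paste0("density|", group),
    instability = paste0("instability|", scope),
    timing = paste0("timing|", group),
    gene_cna = paste0("cna|", group, "|", scope),
    sig_presence = paste0("sigpresence|", scope),
    sig_activity = paste0("sigactivity|", scope),
    paste0(analysis, "|", scope))
}

#' Stage-one univariate screen
#'
#' Tests every feature for a sex difference in every eligible scope
#' (pan-cancer plus each tumour subtype with at least `minN` donors
#' contributing values to the feature).  Binary features use the
#' continuity-corrected two-sample proportion test (reported with a
#' chi-squared label for signature presence, where that test is the
#' convention); continuous features use the Mann-Whitney U test with a
#' Hodges-Lehmann location shift, and signature activity additionally gets
#' a Kolmogorov-Smirnov comparison whose p-value acts as a retention
#' filter on candidates.  q-values are Benjamini-Hochberg within
#' analysis-specific families and candidates are flagged at
#' `q < qCandidate`.
#'
#' @param features A \linkS4class{FeatureSet}.
#' @param cohort Cohort data.frame with donor_id, sex, subtype.
#' @param minN Minimum `n_male + n_female` for a subtype scope (default 15).
#' @param qCandidate Candidate threshold on q (default 0.1).
#' @param ksKeep Signature-activity candidates additionally require a KS
#'   p-value below this (default 0.1: significant or trending).
#' @param scopes Scopes to test; default pan-cancer plus every subtype.
#' @param conf Compute rank-inversion confidence intervals and the
#'   Hodges-Lehmann shift for continuous features.  With `conf = FALSE`
#'   and `exact = FALSE` a fast screening path is taken: identical
#'   p-values via the tie-corrected normal approximation, no confidence
#'   intervals, and a median difference reported as the effect.
#' @param exact Passed to [mannWhitneyTest()]; NULL keeps the exact-test
#'   defaults, FALSE forces the normal approximation everywhere.
#' @return data.frame of univariate results, one row per feature x scope.
#' @export
runStage1 <- function(features, cohort, minN = 15L, qCandidate = 0.1,
                      ksKeep = 0.1, scopes = NULL, conf = TRUE,
                      exact = NULL) {
  info <- featureInfo(features)
  vals <- featureValues(features)
  sexOf <- stats::setNames(cohort$sex, cohort$donor_id)
  subOf <- stats::setNames(cohort$subtype, cohort$donor_id)
  vals <- vals[!is.na(vals$value), , drop = FALSE]
  vals$sex <- sexOf[vals$donor_id]
  vals$subtype <- subOf[vals$donor_id]
  if (anyNA(vals$sex)) stop("feature values for donors absent from cohort")
  if (is.null(scopes))
    scopes <- c("pan-cancer", sort(unique(cohort$subtype)))
  byFeat <- split(seq_len(nrow(vals)), vals$feature_id)
  fast <- !conf && identical(exact, FALSE)
  cap <- nrow(info) * length(scopes)
  acc <- list(feature_id = character(cap), scope = character(cap),
              analysis = character(cap), test = character(cap),
              statistic = numeric(cap), p = numeric(cap),
              effect = numeric(cap), ci_low = numeric(cap),
              ci_high = numeric(cap), n_male = integer(cap),
              n_female = integer(cap), family = character(cap),
              ks_stat = numeric(cap), ks_p = numeric(cap))
  nr <- 0L
  for (fi in seq_len(nrow(info))) {
    fid <- info$feature_id[fi]
    idx <- byFeat[[fid]]
    if (is.null(idx)) next
    value <- vals$value[idx]
    male <- vals$sex[idx] == "male"
    subt <- vals$subtype[idx]
    for (scope in scopes) {
      if (scope == "pan-cancer") {
        v <- value; isM <- male
      } else {
        sel <- subt == scope
        v <- value[sel]; isM <- male[sel]
      }
      nM <- sum(isM); nF <- length(isM) - nM
      if (scope != "pan-cancer" && nM + nF < minN) next
      if (nM < 1L || nF < 1L) next
      ksP <- NA_real_; ksD <- NA_real_
      ciL <- NA_real_; ciH <- NA_real_
      if (info$kind[fi] == "binary") {
        xM <- sum(v[isM]); xF <- sum(v[!isM])
        if (fast) {
          ft <- .fastProp(xM, nM, xF, nF)
          stat <- ft$stat; p <- ft$p
        } else {
          tst <- twoProportionTest(xM, nM, xF, nF)
          stat <- tst$statistic; p <- tst$p
          ciL <- tst$ciLow; ciH <- tst$ciHigh
        }
        eff <- xM / nM - xF / nF
        testLab <- if (info$analysis[fi] == "sig_presence") "chi2" else
          "two_prop"
      } else {
        vm <- v[isM]; vf <- v[!isM]
        if (fast) {
          # screening path: tie-corrected normal approximation and a
          # median difference in place of the Hodges-Lehmann shift
          ft <- .fastMW(vm, vf)
          stat <- ft$U; p <- ft$p
          eff <- stats::median(vm) - stats::median(vf)
        } else {
          tst <- mannWhitneyTest(vm, vf, conf = conf, exact = exact)
          stat <- tst$statistic; p <- tst$p; eff <- tst$effect
          ciL <- tst$ciLow; ciH <- tst$ciHigh
        }
        testLab <- "mann_whitney"
        if (info$analysis[fi] == "sig_activity") {
          ks <- ksTest(vm, vf)
          ksP <- ks$p; ksD <- ks$D
        }
      }
      nr <- nr + 1L
      acc$feature_id[nr] <- fid; acc$scope[nr] <- scope
      acc$analysis[nr] <- info$analysis[fi]; acc$test[nr] <- testLab
      acc$statistic[nr] <- stat; acc$p[nr] <- p; acc$effect[nr] <- eff
      acc$ci_low[nr] <- ciL; acc$ci_high[nr] <- ciH
      acc$n_male[nr] <- nM; acc$n_female[nr] <- nF
      acc$family[nr] <- .fdrFamily(info$analysis[fi], info$group[fi],
                                   scope)
      acc$ks_stat[nr] <- ksD; acc$ks_p[nr] <- ksP
    }
  }
  if (!nr)
    return(.emptyDf(feature_id = "character", scope = "character",
                    analysis = "character", test = "character",
                    statistic = "numeric", p = "numeric",
                    effect = "numeric", ci_low = "numeric",
                    ci_high = "numeric", n_male = "integer",
                    n_female = "integer", family = "character",
                    ks_stat = "numeric", ks_p = "numeric",
                    q = "numeric", candidate = "logical"))
  res <- as.data.frame(lapply(acc, `[`, seq_len(nr)),
                       stringsAsFactors = FALSE)
  res$q <- NA_real_
  for (fam in unique(res$family)) {
    sel <- res$family == fam
    res$q[sel] <- bhFdr(res$p[sel])
  }
  res$candidate <- res$q < qCandidate &
    (res$analysis != "sig_activity" | (!is.na(res$ks_p) & res$ks_p < ksKeep))
  res
}
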