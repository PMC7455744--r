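# Stage 3: down-sampling vetting of stage-two findings, plus extended
# models.

#' Down-sampling configuration
#'
#' @param reps Number of resampling repetitions (default 10,000; reduced
#'   values are appropriate for exploratory runs and verdicts are stable
#'   from about 1,000 reps for strongly-signed findings).
#' @param imbalanceThreshold Sex-balance down-sampling applies when one sex
#'   exceeds this fraction of a scope (default 0.60).
#' @param pReject Findings whose median down-sampled p exceeds this are
#'   rejected (default 0.05).
#' @param ciLevels Percentiles of the male-female difference distribution
#'   forming the confidence interval (default 2.5% and 97.5%).
#' @param seed Integer seed.
#' @param sexMode "larger" resamples only the over-represented sex down to
#'   the smaller sex's count, keeping the smaller sex whole; "both"
#'   resamples both sexes to that count.
#' @return A DownsampleConfig list.
#' @export
downsampleConfig <- function(reps = 10000L, imbalanceThreshold = 0.60,
                             pReject = 0.05, ciLevels = c(0.025, 0.975),
                             seed = 1L, sexMode = c("larger", "both")) {
  stopifnot(reps >= 1L, imbalanceThreshold > 0.5, imbalanceThreshold < 1)
  list(reps = as.integer(reps), imbalanceThreshold = imbalanceThreshold,
       pReject = pReject, ciLevels = ciLevels, seed = seed,
       sexMode = match.arg(sexMode))
}

#' Median tumour-subtype sample size
#'
#' The target size for subtype-balance down-sampling.  For an even number
#' of subtypes the lower median is used, keeping the target an attainable
#' integer sample size.
#'
#' @param cohort Cohort data.frame.
#' @return Integer.
#' @export
#' @examples
#' co <- data.frame(donor_id = as.character(1:30), sex = "male",
#'                  subtype = rep(c("A", "B"), c(10, 20)))
#' medianSubtypeSize(co)  # lower median of (10, 20) = 10
medianSubtypeSize <- function(cohort) {
  if (!nrow(cohort)) stop("empty cohort")
  sizes <- sort(as.integer(table(cohort$subtype)))
  sizes[ceiling(length(sizes) / 2)]
}

# Shared per-rep measurement: male-female difference in proportion (binary)
# or in median (continuous), plus the stage-1 univariate p-value.
.measure <- function(value, isMale, binary) {
  nM <- sum(isMale); nF <- length(isMale) - nM
  if (nM < 1L || nF < 1L) return(c(NA_real_, NA_real_))
  vm <- value[isMale]; vf <- value[!isMale]
  if (binary) {
    c(mean(vm) - mean(vf), .fastProp(sum(vm), nM, sum(vf), nF)$p)
  } else {
    # resampled draws contain ties, so the tie-corrected normal
    # approximation is the branch wilcox.test would take anyway
    c(stats::median(vm) - stats::median(vf), .fastMW(vm, vf)$p)
  }
}

#' Subtype-balance down-sampling for a pan-cancer finding
#'
#' Each repetition draws every tumour subtype down (or up) to the median
#' subtype sample size with replacement, irrespective of sex, so the
#' within-subtype sex composition is preserved while subtype weights are
#' equalised.  Per repetition, the male-female difference (in proportion
#' for binary features, in median otherwise) and the univariate p-value
#' are recorded.
#'
#' @param feature data.frame with donor_id and value (complete cases for
#'   this feature).
#' @param cohort Cohort data.frame (defines subtype membership and sex).
#' @param config A [downsampleConfig()].
#' @param binary Is the feature binary?
#' @param nTarget Override the per-subtype target size (default: median
#'   subtype size of the donors carrying the feature).
#' @return list with diffs, ps (length-reps vectors), n (donors drawn per
#'   rep), nTarget and mode.
#' @export
downsamplePancancer <- function(feature, cohort, config, binary = FALSE,
                                nTarget = NULL) {
  dat <- merge(feature, cohort[, c("donor_id", "sex", "subtype")],
               by = "donor_id")
  byType <- split(seq_len(nrow(dat)), dat$subtype)
  if (is.null(nTarget))
    nTarget <- medianSubtypeSize(dat)
  if (nTarget < 1L) stop("down-sampling target below 1")
  reps <- config$reps
  diffs <- numeric(reps); ps <- numeric(reps)
  isMale <- dat$sex == "male"; value <- dat$value
  withSeed(config$seed, {
    for (r in seq_len(reps)) {
      idx <- unlist(lapply(byType, resample, size = nTarget,
                           replace = TRUE), use.names = FALSE)
      m <- .measure(value[idx], isMale[idx], binary)
      diffs[r] <- m[1]; ps[r] <- m[2]
    }
  })
  list(diffs = diffs, ps = ps, n = length(byType) * nTarget,
       nTarget = nTarget, mode = "subtype_balance")
}

#' Sex-balance down-sampling for a sex-imbalanced scope
#'
#' Applies when one sex exceeds the imbalance threshold (60% by default)
#' of the scope's samples.  Each repetition resamples the larger sex with
#' replacement down to the smaller sex's count (the smaller sex is kept
#' whole under the default mode) and records the male-female difference
#' and univariate p-value.
#'
#' @inheritParams downsamplePancancer
#' @return list with diffs, ps, n (donors used per rep) and mode.
#' @export
downsampleSex <- function(feature, cohort, config, binary = FALSE) {
  dat <- merge(feature, cohort[, c("donor_id", "sex")], by = "donor_id")
  iM <- which(dat$sex == "male"); iF <- which(dat$sex == "female")
  if (!length(iM) || !length(iF)) stop("a sex is absent from the scope")
  nSmall <- min(length(iM), length(iF))
  small <- if (length(iM) <= length(iF)) iM else iF
  large <- if (length(iM) <= length(iF)) iF else iM
  reps <- config$reps
  diffs <- numeric(reps); ps <- numeric(reps)
  isMale <- dat$sex == "male"; value <- dat$value
  both <- identical(config$sexMode, "both")
  withSeed(config$seed, {
    for (r in seq_len(reps)) {
      idx <- c(if (both) resample(small, nSmall, replace = TRUE) else small,
               resample(large, nSmall, replace = TRUE))
      m <- .measure(value[idx], isMale[idx], binary)
      diffs[r] <- m[1]; ps[r] <- m[2]
    }
  })
  list(diffs = diffs, ps = ps, n = 2L * nSmall, mode = "sex_balance")
}

#' Verdict from a down-sampling distribution
#'
#' The 95% confidence interval is the empirical 2.5/97.5 percentile
#' interval of the male-female difference distribution.  A finding is
#' rejected when this interval overlaps 0 (closed containment, so a bound
#' exactly at 0 rejects), or otherwise when the median down-sampled
#' p-value exceeds the 0.05 threshold.
#'
#' @param diffs,ps Equal-length distributions from a down-sampling run.
#' @param config A [downsampleConfig()].
#' @return list with ciLow, ciHigh, medianP and verdict in
#'   pass/reject_ci/reject_p.
#' @export
evaluateRobustness <- function(diffs, ps, config = downsampleConfig()) {
  if (!length(diffs) || length(diffs) != length(ps))
    stop("need non-empty distributions of equal length")
  ci <- unname(stats::quantile(diffs, config$ciLevels, na.rm = TRUE))
  medianP <- stats::median(ps, na.rm = TRUE)
  verdict <- if (ci[1] <= 0 && ci[2] >= 0) "reject_ci"
    else if (medianP > config$pReject) "reject_p"
    else "pass"
  list(ciLow = ci[1], ciHigh = ci[2], medianP = medianP,
       verdict = verdict)
}

#' Stage-three vetting of stage-two findings
#'
#' Pan-cancer findings undergo subtype-balance down-sampling; any finding
#' (pan-cancer or subtype) whose scope has one sex above the imbalance
#' threshold additionally undergoes sex-balance down-sampling.  Findings
#' with no applicable mode pass by default.  Each finding also gets an
#' extended-model refit (stage and grade added on the complete-case
#' subset) whose sex q-values are adjusted within the finding's FDR
#' family.
#'
#' @param stage2 Stage-two results (only `significant` rows are vetted).
#' @param cohort Cohort data.frame.
#' @param features A \linkS4class{FeatureSet}.
#' @param config A [downsampleConfig()].
#' @return list with `robustness` (one row per finding x mode) and
#'   `extended` (extended-model fits).
#' @export
runStage3 <- function(stage2, cohort, features,
                      config = downsampleConfig()) {
  sig <- stage2[stage2$significant %in% TRUE, , drop = FALSE]
  vals <- featureValues(features)
  info <- featureInfo(features)
  kindOf <- stats::setNames(info$kind, info$feature_id)
  rows <- list()
  for (i in seq_len(nrow(sig))) {
    fr <- sig[i, ]
    binary <- kindOf[[fr$feature_id]] == "binary"
    fv <- vals[vals$feature_id == fr$feature_id & !is.na(vals$value),
               c("donor_id", "value")]
    scopeCohort <- if (fr$scope == "pan-cancer") cohort else
      cohort[cohort$subtype == fr$scope, , drop = FALSE]
    fv <- fv[fv$donor_id %in% scopeCohort$donor_id, , drop = FALSE]
    sexes <- scopeCohort$sex[match(fv$donor_id, scopeCohort$donor_id)]
    maleFrac <- mean(sexes == "male")
    cfgI <- config
    cfgI$seed <- childSeed(config$seed, i)
    applied <- FALSE
    addVerdict <- function(ds) {
      ev <- evaluateRobustness(ds$diffs, ds$ps, config)
      rows[[length(rows) + 1L]] <<- data.frame(
        feature_id = fr$feature_id, scope = fr$scope, mode = ds$mode,
        diff_ci_low = ev$ciLow, diff_ci_high = ev$ciHigh,
        median_p = ev$medianP, verdict = ev$verdict,
        stringsAsFactors = FALSE)
    }
    if (fr$scope == "pan-cancer") {
      addVerdict(downsamplePancancer(fv, scopeCohort, cfgI, binary))
      applied <- TRUE
    }
    if (max(maleFrac, 1 - maleFrac) > config$imbalanceThreshold) {
      cfgI$seed <- childSeed(config$seed, i + 100000L)
      addVerdict(downsampleSex(fv, scopeCohort, cfgI, binary))
      applied <- TRUE
    }
    if (!applied)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = fr$feature_id, scope = fr$scope, mode = "none",
        diff_ci_low = NA_real_, diff_ci_high = NA_real_,
        median_p = NA_real_, verdict = "pass", stringsAsFactors = FALSE)
  }
  robustness <- if (length(rows)) do.call(rbind, rows) else
    .emptyDf(feature_id = "character", scope = "character",
             mode = "character", diff_ci_low = "numeric",
             diff_ci_high = "numeric", median_p = "numeric",
             verdict = "character")
  # extended models for the vetted findings
  extended <- if (nrow(sig)) {
    s1 <- sig
    s1$candidate <- TRUE
    runStage2(s1, cohort, features, qSignificant = 0.1, extended = TRUE)
  } else .emptyDf(feature_id = "character", scope = "character",
                  analysis = "character", model = "character",
                  sex_coefficient = "numeric", se = "numeric",
                  p_sex = "numeric", lambda = "numeric",
                  n_used = "integer", converged = "logical",
                  family = "character", note = "character",
                  q_sex = "numeric", significant = "logical")
  list(robustness = robustness, extended = extended)
}
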