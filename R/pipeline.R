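# Full pipeline orchestration: simulate -> features -> stage1 -> stage2 ->
# stage3 -> findings report.

#' Run the full three-stage pipeline
#'
#' Executes the staged analysis end to end.  When `dataset` is NULL a
#' synthetic dataset is simulated from `config$simulation` under `seed`.
#' The findings table reconciles the three stages: a finding is
#' **confirmed** when it is a stage-one candidate (q < 0.1), significant
#' in the stage-two covariate-adjusted model (q < 0.1), passes every
#' applicable down-sampling verdict, and its extended model (where
#' estimable) keeps q below the significance threshold; an extended q in
#' [0.1, 0.2) leaves the finding **trending**; anything else is
#' **rejected**.
#'
#' @param config A [pipelineConfig()].
#' @param seed Integer master seed for the run.
#' @param dataset Optional \linkS4class{SexBiasDataset}; bypasses
#'   simulation.
#' @return A \linkS4class{SexBiasReport}.
#' @export
#' @examples
#' cfg <- pipelineConfig(demoSimulationConfig(nPerSubtype = 60),
#'                       reps = 100, chromLevel = FALSE)
#' rep <- runPipeline(cfg, seed = 11)
#' rep
runPipeline <- function(config, seed = 1L, dataset = NULL) {
  if (is.null(dataset))
    dataset <- simulateDataset(config$simulation, seed)
  cohort <- donorTable(dataset)
  features <- computeFeatures(dataset, analyses = config$analyses,
                              chromLevel = config$chromLevel,
                              cnaRule = config$cnaRule)
  thr <- config$thresholds
  stage1 <- runStage1(features, cohort, minN = thr$minSubtypeN,
                      qCandidate = thr$qCandidate, ksKeep = config$ksKeep,
                      scopes = config$scopes, conf = config$stage1Conf,
                      exact = config$stage1Exact)
  stage2 <- runStage2(stage1, cohort, features,
                      qSignificant = thr$qSignificant)
  dsCfg <- downsampleConfig(reps = config$reps,
                            imbalanceThreshold = thr$imbalanceThreshold,
                            pReject = thr$pReject,
                            seed = childSeed(seed,
                                             .seedStreams[["stage3"]]))
  s3 <- runStage3(stage2, cohort, features, dsCfg)
  findings <- .assembleFindings(stage1, stage2, s3$robustness,
                                s3$extended, thr)
  truthCmp <- .compareTruth(findings, plantedTruth(dataset))
  new("SexBiasReport", stage1 = stage1, stage2 = stage2,
      robustness = s3$robustness, extended = s3$extended,
      findings = findings, truthComparison = truthCmp, config = config)
}

.assembleFindings <- function(stage1, stage2, robustness, extended, thr) {
  if (!nrow(stage2))
    return(.emptyDf(feature_id = "character", scope = "character",
                    analysis = "character", effect1 = "numeric",
                    p1 = "numeric", q1 = "numeric",
                    sex_coefficient = "numeric", p2 = "numeric",
                    q2 = "numeric", verdicts = "character",
                    robust_pass = "logical", extended_q = "numeric",
                    status = "character", reason = "character"))
  key <- function(d) paste(d$feature_id, d$scope, sep = "\r")
  s1k <- key(stage1); rbk <- key(robustness); exk <- key(extended)
  rows <- lapply(seq_len(nrow(stage2)), function(i) {
    fr <- stage2[i, ]
    k <- paste(fr$feature_id, fr$scope, sep = "\r")
    s1 <- stage1[match(k, s1k), ]
    rb <- robustness[rbk == k, , drop = FALSE]
    ex <- extended[match(k, exk), ]
    verdicts <- if (nrow(rb))
      paste(rb$mode, rb$verdict, sep = ":", collapse = ";") else ""
    robustPass <- !nrow(rb) || all(rb$verdict == "pass")
    extQ <- if (!is.na(ex$feature_id %||% NA) && isTRUE(ex$converged))
      ex$q_sex else NA_real_
    status <- "rejected"; reason <- ""
    if (!isTRUE(fr$significant)) {
      reason <- "stage2"
    } else if (!robustPass) {
      reason <- "downsampling"
    } else if (!is.na(extQ) && extQ >= thr$qSignificant) {
      if (extQ < 0.2) { status <- "trending"; reason <- "extended" }
      else reason <- "extended"
    } else {
      status <- "confirmed"
    }
    data.frame(
      feature_id = fr$feature_id, scope = fr$scope,
      analysis = fr$analysis, effect1 = s1$effect, p1 = s1$p, q1 = s1$q,
      sex_coefficient = fr$sex_coefficient, p2 = fr$p_sex,
      q2 = fr$q_sex, verdicts = verdicts, robust_pass = robustPass,
      extended_q = extQ, status = status, reason = reason,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.compareTruth <- function(findings, truth) {
  empty <- .emptyDf(feature_id = "character", scope = "character",
                    planted = "logical", magnitude = "numeric",
                    favoured_sex = "character", detected = "logical",
                    sign_ok = "logical", class = "character")
  if (!nrow(truth)) return(empty)
  confirmed <- findings[findings$status == "confirmed", , drop = FALSE]
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    fd <- findings[findings$feature_id == tr$feature_id &
                     findings$scope == tr$scope, , drop = FALSE]
    det <- nrow(fd) > 0 && any(fd$status == "confirmed")
    signOk <- NA
    if (det) {
      cf <- fd$sex_coefficient[fd$status == "confirmed"][1]
      signOk <- if (tr$favoured_sex == "male") cf > 0 else cf < 0
    }
    planted <- tr$magnitude != 0
    data.frame(feature_id = tr$feature_id, scope = tr$scope,
               planted = planted, magnitude = tr$magnitude,
               favoured_sex = tr$favoured_sex, detected = det,
               sign_ok = signOk,
               class = if (planted && det) "TP"
                       else if (planted) "FN"
                       else if (det) "FP" else "TN",
               stringsAsFactors = FALSE)
  })
  cmp <- do.call(rbind, rows)
  # confirmed findings on features never configured at all are also FPs
  extra <- confirmed[!confirmed$feature_id %in% truth$feature_id, ,
                     drop = FALSE]
  if (nrow(extra)) {
    cmp <- rbind(cmp, data.frame(
      feature_id = extra$feature_id, scope = extra$scope,
      planted = FALSE, magnitude = 0, favoured_sex = NA_character_,
      detected = TRUE, sign_ok = NA, class = "FP",
      stringsAsFactors = FALSE))
  }
  cmp
}
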