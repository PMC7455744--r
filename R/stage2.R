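# Stage 2: covariate-adjusted modelling of stage-one candidates.

#' Construct a model specification for a candidate feature
#'
#' Covariates follow the framework's conventions: sex always; age and
#' ancestry where available; tumour subtype only in pan-cancer models;
#' overall SNV density in every mutational-signature model (to absorb the
#' tendency to attribute more signatures in SNV-dense samples); stage and
#' grade only in extended models.
#'
#' @param feature_id,scope,analysis,kind Identify the candidate.
#' @param extended Add stage and grade (extended model).
#' @return A ModelSpec list.
#' @export
makeModelSpec <- function(feature_id, scope, analysis, kind,
                          extended = FALSE) {
  covs <- c("sex", "age", "ancestry")
  if (identical(scope, "pan-cancer")) covs <- c(covs, "subtype")
  if (analysis %in% c("sig_presence", "sig_activity"))
    covs <- c(covs, "snv_density")
  ext <- if (extended) c("stage", "grade") else character()
  list(feature_id = feature_id, scope = scope, analysis = analysis,
       family = if (kind == "binary") "logistic" else "linear",
       covariates = covs, extendedCovariates = ext,
       transform = kind != "binary", extended = extended)
}

#' Build a regression design for one candidate
#'
#' Assembles outcome and covariates on the candidate's scope, applying the
#' covariate inclusion screen: a covariate is dropped when more than 15%
#' of its values are missing (extended covariates are exempt; including
#' them despite missingness is the point of the extended models), when it
#' has fewer than two observed levels after complete-case filtering, or
#' when its design columns correlate above 0.9 in absolute value with an
#' earlier covariate's.  Categorical covariates are treatment-coded with
#' the most frequent level as reference; sex is coded female -> male so a
#' positive sex coefficient means male-dominated bias.  Rows are
#' complete-case over the retained covariates.
#'
#' @param cohort Cohort data.frame.
#' @param features A \linkS4class{FeatureSet} (source of the outcome and of
#'   the snv_density covariate).
#' @param spec A ModelSpec from [makeModelSpec()].
#' @return list with `data` (model frame), `formula`, `nUsed`, `dropped`
#'   (named character of drop reasons), `covariates` (retained).
#' @export
buildDesign <- function(cohort, features, spec) {
  vals <- featureValues(features)
  fv <- vals[vals$feature_id == spec$feature_id & !is.na(vals$value), ]
  dat <- if (identical(spec$scope, "pan-cancer")) cohort else
    cohort[cohort$subtype == spec$scope, , drop = FALSE]
  dat$.outcome <- fv$value[match(dat$donor_id, fv$donor_id)]
  dat <- dat[!is.na(dat$.outcome), , drop = FALSE]
  if (!nrow(dat)) stop("outcome entirely missing in scope ", spec$scope)
  if ("snv_density" %in% c(spec$covariates, spec$extendedCovariates)) {
    dv <- vals[vals$feature_id == "density_overall", ]
    dat$snv_density <- dv$value[match(dat$donor_id, dv$donor_id)]
  }
  covs <- c(spec$covariates, spec$extendedCovariates)
  exempt <- spec$extendedCovariates
  dropped <- character()
  keep <- character()
  for (cv in covs) {
    if (!cv %in% names(dat)) { dropped[cv] <- "unavailable"; next }
    missFrac <- mean(is.na(dat[[cv]]))
    if (!cv %in% exempt && cv != "sex" && missFrac >= 0.15) {
      dropped[cv] <- sprintf("missingness %.0f%%", 100 * missFrac)
      next
    }
    keep <- c(keep, cv)
  }
  repeat {
    cc <- stats::complete.cases(dat[, c(".outcome", keep), drop = FALSE])
    sub <- dat[cc, , drop = FALSE]
    low <- keep[vapply(keep, function(cv)
      length(unique(sub[[cv]])) < 2L, logical(1))]
    if (!length(low)) break
    if ("sex" %in% low)
      stop("sex has a single level after filtering: unestimable")
    for (cv in low) dropped[cv] <- "fewer than two levels"
    keep <- setdiff(keep, low)
  }
  if (!"sex" %in% keep) stop("sex covariate is mandatory")
  # treatment coding, modal reference; then collinearity screen in order
  sub$sex <- factor(sub$sex, levels = c("female", "male"))
  for (cv in setdiff(keep, "sex")) {
    if (is.character(sub[[cv]]) || is.factor(sub[[cv]])) {
      x <- as.character(sub[[cv]])
      sub[[cv]] <- factor(x, levels = c(modalLevel(x),
                                        setdiff(sort(unique(x)),
                                                modalLevel(x))))
    }
  }
  colsSoFar <- NULL
  retained <- character()
  for (cv in keep) {
    mm <- stats::model.matrix(stats::as.formula(paste("~", cv)),
                              data = sub)[, -1, drop = FALSE]
    if (!is.null(colsSoFar) && ncol(mm)) {
      cors <- suppressWarnings(abs(stats::cor(mm, colsSoFar)))
      cors[is.na(cors)] <- 0
      if (any(cors > 0.9)) {
        if (cv == "sex") stop("sex is collinear with an earlier covariate")
        dropped[cv] <- "collinear (|r| > 0.9)"
        next
      }
    }
    colsSoFar <- cbind(colsSoFar, mm)
    retained <- c(retained, cv)
  }
  if (length(dropped))
    message("design for ", spec$feature_id, " [", spec$scope,
            "]: dropped ", paste(names(dropped), dropped,
                                 sep = ": ", collapse = "; "))
  list(data = sub[, c(".outcome", retained), drop = FALSE],
       formula = stats::as.formula(
         paste(".outcome ~", paste(retained, collapse = " + "))),
       nUsed = nrow(sub), dropped = dropped, covariates = retained)
}

#' Fit a stage-two model
#'
#' Logistic regression (maximum likelihood) for binary outcomes, linear
#' regression for continuous outcomes; continuous outcomes are first
#' Yeo-Johnson transformed with the power selected by profile likelihood
#' on the pooled outcome (both sexes), so the transform cannot itself
#' encode a sex effect.  The reported p-value is the two-sided Wald test
#' of the sex coefficient.  Perfect separation in logistic fits is
#' flagged (`converged = FALSE`) rather than penalised, keeping inference
#' comparable across features; such fits are excluded from FDR adjustment
#' downstream.
#'
#' @param design A design from [buildDesign()].
#' @param family "logistic" or "linear".
#' @param transform Yeo-Johnson transform the outcome (linear only).
#' @return list with coefficient, se, p, lambda (NA unless transformed),
#'   nUsed, converged.
#' @export
fitModel <- function(design, family = c("logistic", "linear"),
                     transform = TRUE) {
  family <- match.arg(family)
  dat <- design$data
  if (nrow(dat) < length(design$covariates) + 2L)
    stop("too few rows for the number of covariates")
  lambda <- NA_real_
  converged <- TRUE
  if (family == "logistic") {
    y <- dat$.outcome
    if (length(unique(y)) < 2L)
      stop("binary outcome must have both classes")
    fit <- suppressWarnings(
      stats::glm(design$formula, data = dat, family = stats::binomial()))
    if (!fit$converged) converged <- FALSE
  } else {
    if (transform) {
      lambda <- selectLambda(dat$.outcome)
      dat$.outcome <- yeoJohnson(dat$.outcome, lambda)
    }
    fit <- stats::lm(design$formula, data = dat)
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("rank-deficient design")
  sm <- stats::coef(summary(fit))
  if (!"sexmale" %in% rownames(sm)) stop("sex term missing from fit")
  # a (quasi-)separated sex contrast "converges" with an astronomical
  # coefficient and standard error; flag it rather than report Wald
  # nonsense.  Separation confined to a nuisance covariate level (a tiny
  # subtype with no events, say) leaves the sex term estimable and is
  # tolerated.
  if (family == "logistic" &&
      (sm["sexmale", 2] > 1e3 || abs(sm["sexmale", 1]) > 20))
    converged <- FALSE
  list(coefficient = sm["sexmale", 1], se = sm["sexmale", 2],
       p = sm["sexmale", 4], lambda = lambda, nUsed = nrow(dat),
       converged = converged)
}

#' Stage-two modelling of stage-one candidates
#'
#' Fits one covariate-adjusted model per candidate (logistic for binary
#' features, Yeo-Johnson + linear for continuous features) and adjusts the
#' sex-term p-values by Benjamini-Hochberg within the candidate's stage-one
#' FDR family.  Non-converged or unestimable fits are retained in the
#' output but excluded from adjustment and never significant.
#'
#' @param stage1 Stage-one results (only rows with `candidate = TRUE` are
#'   modelled).
#' @param cohort Cohort data.frame.
#' @param features A \linkS4class{FeatureSet}.
#' @param qSignificant Significance threshold on the adjusted q (default
#'   0.1).
#' @param extended Fit extended models (adds stage and grade).
#' @return data.frame of fits with q_sex and a `significant` flag.
#' @export
runStage2 <- function(stage1, cohort, features, qSignificant = 0.1,
                      extended = FALSE) {
  cand <- stage1[stage1$candidate %in% TRUE, , drop = FALSE]
  info <- featureInfo(features)
  kindOf <- stats::setNames(info$kind, info$feature_id)
  out <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cr <- cand[i, ]
    spec <- makeModelSpec(cr$feature_id, cr$scope, cr$analysis,
                          kindOf[[cr$feature_id]], extended = extended)
    fit <- tryCatch({
      des <- suppressMessages(buildDesign(cohort, features, spec))
      fitModel(des, spec$family, spec$transform)
    }, error = function(e)
      list(coefficient = NA_real_, se = NA_real_, p = NA_real_,
           lambda = NA_real_, nUsed = NA_integer_, converged = FALSE,
           note = conditionMessage(e)))
    out[[i]] <- data.frame(
      feature_id = cr$feature_id, scope = cr$scope,
      analysis = cr$analysis, model = spec$family,
      sex_coefficient = fit$coefficient, se = fit$se, p_sex = fit$p,
      lambda = fit$lambda, n_used = fit$nUsed,
      converged = fit$converged, family = cr$family,
      note = fit$note %||% "", stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    .emptyDf(feature_id = "character", scope = "character",
             analysis = "character", model = "character",
             sex_coefficient = "numeric", se = "numeric",
             p_sex = "numeric", lambda = "numeric", n_used = "integer",
             converged = "logical", family = "character",
             note = "character")
  res$q_sex <- rep(NA_real_, nrow(res))
  ok <- res$converged & !is.na(res$p_sex)
  for (fam in unique(res$family[ok])) {
    sel <- ok & res$family == fam
    res$q_sex[sel] <- bhFdr(res$p_sex[sel])
  }
  res$significant <- !is.na(res$q_sex) & res$q_sex < qSignificant
  res
}
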