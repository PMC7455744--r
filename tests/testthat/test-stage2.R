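# Stage-two modelling: design screens, fits, adjustment.

mkFeatures <- function(cohort, value, id = "f1", kind = "continuous",
                       analysis = "density") {
  toyFeatures(data.frame(donor_id = cohort$donor_id, feature_id = id,
                         value = value),
              analysis = analysis, kind = kind)
}

test_that("covariate screen drops unusable covariates and keeps sex", {
  co <- toyCohort(100)
  set.seed(6)
  co$ancestry[1:20] <- NA                      # 20% missing -> dropped
  co$stage <- "II"                             # single level
  co$age <- rnorm(100, 60, 8)
  fs <- mkFeatures(co, rnorm(100))
  spec <- makeModelSpec("f1", "pan-cancer", "density", "continuous")
  spec$covariates <- c("sex", "age", "ancestry")
  des <- suppressMessages(buildDesign(co, fs, spec))
  expect_true("ancestry" %in% names(des$dropped))
  expect_match(des$dropped[["ancestry"]], "missingness")
  expect_true(all(c("sex", "age") %in% des$covariates))

  spec$extendedCovariates <- c("stage")
  des <- suppressMessages(buildDesign(co, fs, spec))
  expect_match(des$dropped[["stage"]], "fewer than two levels")

  # a duplicate of an earlier covariate fails the collinearity screen
  co$age2 <- co$age
  spec$covariates <- c("sex", "age", "age2")
  spec$extendedCovariates <- character()
  des <- suppressMessages(buildDesign(co, fs, spec))
  expect_match(des$dropped[["age2"]], "collinear")

  coM <- toyCohort(40, maleFrac = 1)
  expect_error(
    buildDesign(coM, mkFeatures(coM, rnorm(40)), spec),
    "single level")
})

test_that("reference levels: female reference, modal category baseline", {
  co <- rbind(toyCohort(60, subtype = "A"), toyCohort(30, subtype = "B"))
  set.seed(7)
  fs <- mkFeatures(co, rnorm(90))
  spec <- makeModelSpec("f1", "pan-cancer", "density", "continuous")
  des <- suppressMessages(buildDesign(co, fs, spec))
  expect_equal(levels(des$data$sex), c("female", "male"))
  expect_equal(levels(des$data$subtype)[1], "A")  # most frequent first
})

test_that("logistic fits recover a planted log odds ratio", {
  set.seed(8)
  co <- toyCohort(2000)
  p <- plogis(qlogis(0.13) + log(3) * (co$sex == "male"))
  fs <- mkFeatures(co, rbinom(2000, 1, p), kind = "binary",
                   analysis = "driver")
  spec <- makeModelSpec("f1", "pan-cancer", "driver", "binary")
  des <- suppressMessages(buildDesign(co, fs, spec))
  fit <- fitModel(des, "logistic")
  expect_true(fit$converged)
  expect_equal(fit$coefficient, log(3), tolerance = 0.15)
  expect_true(is.na(fit$lambda))
})

test_that("linear fits transform the outcome and report lambda", {
  set.seed(9)
  co <- toyCohort(400)
  y <- exp(rnorm(400, 1 + 0.5 * (co$sex == "male"), 0.6))
  fs <- mkFeatures(co, y)
  spec <- makeModelSpec("f1", "pan-cancer", "density", "continuous")
  des <- suppressMessages(buildDesign(co, fs, spec))
  fit <- fitModel(des, "linear", transform = TRUE)
  expect_false(is.na(fit$lambda))
  expect_lt(fit$lambda, 0.6)       # strongly right-skewed outcome
  expect_gt(fit$coefficient, 0)
  expect_lt(fit$p, 1e-6)
  raw <- fitModel(des, "linear", transform = FALSE)
  expect_true(is.na(raw$lambda))
})

test_that("sex p-values are uniform under the null linear model", {
  set.seed(10)
  co <- toyCohort(200)
  ps <- vapply(1:150, function(i) {
    fs <- mkFeatures(co, rnorm(200) + 0.05 * co$age)
    des <- suppressMessages(buildDesign(
      co, fs, makeModelSpec("f1", "pan-cancer", "density",
                            "continuous")))
    fitModel(des, "linear")$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("perfect separation is flagged, not silently reported", {
  co <- toyCohort(60)
  fs <- mkFeatures(co, as.numeric(co$sex == "male"), kind = "binary",
                   analysis = "driver")
  spec <- makeModelSpec("f1", "pan-cancer", "driver", "binary")
  des <- suppressMessages(buildDesign(co, fs, spec))
  fit <- fitModel(des, "logistic")
  expect_false(fit$converged)
})

test_that("stage-two orchestration adjusts within families", {
  set.seed(11)
  co <- toyCohort(300)
  p <- plogis(qlogis(0.2) + 1.5 * (co$sex == "male"))
  fs <- combineFeatures(
    mkFeatures(co, rbinom(300, 1, p), id = "driver_hit", kind = "binary",
               analysis = "driver"),
    mkFeatures(co, rnorm(300), id = "density_overall"))
  s1 <- runStage1(fs, co)
  s2 <- runStage2(s1, co, fs)
  expect_true(all(s2$feature_id %in%
                    s1$feature_id[s1$candidate %in% TRUE]))
  hit <- s2[s2$feature_id == "driver_hit" & s2$scope == "pan-cancer", ]
  expect_true(hit$significant)
  expect_gt(hit$sex_coefficient, 0)
  # empty candidate set is handled gracefully
  none <- s1; none$candidate <- FALSE
  expect_equal(nrow(runStage2(none, co, fs)), 0)
})

test_that("a subtype-composition artifact dies at stage two", {
  # outcome depends on subtype only; subtype A is male-enriched, so the
  # pan-cancer marginal sex effect is pure confounding
  set.seed(12)
  co <- rbind(toyCohort(150, maleFrac = 0.8, subtype = "A"),
              toyCohort(150, maleFrac = 0.2, subtype = "B"))
  p <- ifelse(co$subtype == "A", 0.6, 0.1)
  fs <- mkFeatures(co, rbinom(300, 1, p), id = "driver_conf",
                   kind = "binary", analysis = "driver")
  s1 <- runStage1(fs, co)
  expect_true(s1$candidate[s1$scope == "pan-cancer"])
  s2 <- runStage2(s1, co, fs)
  pan <- s2[s2$scope == "pan-cancer", ]
  expect_gt(pan$p_sex, 0.1)      # subtype covariate absorbs the artifact
  expect_false(pan$significant)
})
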