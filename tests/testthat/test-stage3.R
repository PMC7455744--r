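# Stage-three down-sampling mechanics and verdicts.

test_that("median subtype size uses the lower median", {
  mk <- function(sizes) {
    do.call(rbind, lapply(seq_along(sizes), function(i)
      toyCohort(sizes[i], subtype = LETTERS[i])))
  }
  expect_equal(medianSubtypeSize(mk(c(10, 20, 30))), 20)
  expect_equal(medianSubtypeSize(mk(c(10, 20))), 10)
  expect_equal(medianSubtypeSize(mk(48)), 48)
  expect_error(medianSubtypeSize(toyCohort(2)[0, ]), "empty")
})

test_that("subtype-balance down-sampling draws n_median per subtype", {
  co <- rbind(toyCohort(30, subtype = "A"), toyCohort(48, subtype = "B"),
              toyCohort(90, subtype = "C"))
  set.seed(20)
  feat <- data.frame(donor_id = co$donor_id, value = rnorm(nrow(co)))
  cfg <- downsampleConfig(reps = 50, seed = 99)
  ds <- downsamplePancancer(feat, co, cfg)
  expect_equal(ds$nTarget, 48)
  expect_equal(ds$n, 3 * 48)        # every rep holds 3 x n_median draws
  expect_length(ds$diffs, 50)
  # determinism and rep-order independence
  ds2 <- downsamplePancancer(feat, co, cfg)
  expect_identical(ds, ds2)
  ev <- evaluateRobustness(ds$diffs, ds$ps, cfg)
  sh <- sample(50)
  ev2 <- evaluateRobustness(ds$diffs[sh], ds$ps[sh], cfg)
  expect_equal(ev$ciLow, ev2$ciLow)
  expect_equal(ev$medianP, ev2$medianP)
})

test_that("sex-balance down-sampling keeps the smaller sex whole", {
  co <- toyCohort(100, maleFrac = 0.7)
  set.seed(21)
  feat <- data.frame(donor_id = co$donor_id, value = rnorm(100))
  cfg <- downsampleConfig(reps = 40, seed = 7)
  ds <- downsampleSex(feat, co, cfg)
  expect_equal(ds$n, 60)            # 30 females kept + 30 male draws
  ds2 <- downsampleSex(feat, co, cfg)
  expect_identical(ds, ds2)
  coM <- toyCohort(30, maleFrac = 1)
  expect_error(downsampleSex(
    data.frame(donor_id = coM$donor_id, value = rnorm(30)), coM, cfg),
    "absent")
})

test_that("verdicts follow the two printed rejection rules", {
  cfg <- downsampleConfig(reps = 100)
  mk <- function(lo, hi, mp) {
    # a diff distribution with the requested percentile interval
    diffs <- qunif(seq(0.001, 0.999, length.out = 999), lo - 0.001,
                   hi + 0.001)
    diffs <- seq(lo, hi, length.out = 999)
    list(diffs = diffs, ps = rep(mp, 999))
  }
  d <- mk(0.05, 0.20, 0.01)
  expect_equal(evaluateRobustness(d$diffs, d$ps, cfg)$verdict, "pass")
  d <- mk(-0.02, 0.15, 0.01)
  expect_equal(evaluateRobustness(d$diffs, d$ps, cfg)$verdict,
               "reject_ci")
  d <- mk(0.01, 0.20, 0.20)
  expect_equal(evaluateRobustness(d$diffs, d$ps, cfg)$verdict,
               "reject_p")
  # a bound exactly at zero counts as overlapping (conservative)
  diffs <- c(rep(0, 100), rep(0.2, 900))
  expect_equal(
    evaluateRobustness(diffs, rep(0.01, 1000), cfg)$verdict,
    "reject_ci")
  expect_error(evaluateRobustness(numeric(), numeric(), cfg),
               "non-empty")
})

test_that("null features rarely produce a CI excluding zero", {
  co <- rbind(toyCohort(40, subtype = "A"), toyCohort(40, subtype = "B"))
  set.seed(22)
  cfg <- downsampleConfig(reps = 400, seed = 1)
  excl <- vapply(1:60, function(i) {
    feat <- data.frame(donor_id = co$donor_id, value = rnorm(80))
    cfg$seed <- i
    ds <- downsamplePancancer(feat, co, cfg)
    ev <- evaluateRobustness(ds$diffs, ds$ps, cfg)
    ev$verdict != "reject_ci"      # CI excluded zero
  }, logical(1))
  expect_lte(mean(excl), 0.12)     # nominal 5% plus Monte-Carlo slack
})

test_that("stage-three orchestration applies the right modes", {
  set.seed(23)
  co <- rbind(toyCohort(60, maleFrac = 0.5, subtype = "A"),
              toyCohort(60, maleFrac = 0.8, subtype = "B"))
  val <- rnorm(120) + 2 * (co$sex == "male")
  fs <- toyFeatures(data.frame(donor_id = co$donor_id,
                               feature_id = "f1", value = val))
  s1 <- runStage1(fs, co)
  s2 <- runStage2(s1, co, fs)
  s3 <- runStage3(s2, co, fs, downsampleConfig(reps = 200, seed = 3))
  rb <- s3$robustness
  # pan-cancer: subtype balance (sex split is ~65/35, below threshold)
  expect_true("subtype_balance" %in%
                rb$mode[rb$scope == "pan-cancer"])
  # subtype B is 80% male -> sex balance; subtype A balanced -> pass
  expect_true("sex_balance" %in% rb$mode[rb$scope == "B"])
  expect_equal(rb$mode[rb$scope == "A"], "none")
  expect_equal(rb$verdict[rb$scope == "A"], "pass")
  # a strong genuine effect survives every applicable mode
  expect_true(all(rb$verdict == "pass"))
})

test_that("verdicts agree between 1,000 and 10,000 reps for strong effects", {
  set.seed(24)
  co <- rbind(toyCohort(40, subtype = "A"), toyCohort(40, subtype = "B"),
              toyCohort(60, subtype = "C"))
  agree <- vapply(1:4, function(i) {
    feat <- data.frame(donor_id = co$donor_id,
                       value = rnorm(140) + 1.5 * (co$sex == "male"))
    v <- vapply(c(1000L, 10000L), function(reps) {
      cfg <- downsampleConfig(reps = reps, seed = i)
      ds <- downsamplePancancer(feat, co, cfg)
      evaluateRobustness(ds$diffs, ds$ps, cfg)$verdict
    }, character(1))
    v[1] == v[2]
  }, logical(1))
  expect_true(all(agree))
})
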