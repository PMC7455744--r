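# Synthetic-cohort generator: structure, determinism, planted effects.

test_that("cohort honours subtype sizes exactly and samples sex", {
  cfg <- list(cohort = list(subtypes = list(
    list(name = "A", n = 50, maleFraction = 0.5),
    list(name = "B", n = 50, maleFraction = 0.5),
    list(name = "C", n = 50, maleFraction = 0.5))))
  co <- simulateCohort(cfg, seed = 2)$cohort
  expect_equal(nrow(co), 150)
  expect_equal(as.vector(table(co$subtype)), c(50, 50, 50))
  expect_false(anyDuplicated(co$donor_id) > 0)
  nM <- sum(co$sex == "male")
  expect_true(abs(nM - 75) < 4 * sqrt(150 * 0.25))  # binomial envelope

  cfg$cohort$subtypes[[1]]$maleFraction <- 1
  co <- simulateCohort(cfg, seed = 2)$cohort
  expect_true(all(co$sex[co$subtype == "A"] == "male"))

  cfg$cohort$subtypes[[1]]$maleFraction <- 1.3
  expect_error(simulateCohort(cfg, 2), "maleFraction")
  cfg$cohort$subtypes[[1]]$maleFraction <- 0.5
  cfg$cohort$subtypes[[1]]$n <- 0
  expect_error(simulateCohort(cfg, 2), "n must be")
})

test_that("missingness rates are honoured and sex/subtype never missing", {
  cfg <- list(cohort = list(
    subtypes = list(list(name = "A", n = 4000, maleFraction = 0.5)),
    missing = c(age = 0.10, stage = 0.40, grade = 0.25)))
  co <- simulateCohort(cfg, seed = 5)$cohort
  expect_equal(mean(is.na(co$age)), 0.10, tolerance = 0.25)
  expect_equal(mean(is.na(co$stage)), 0.40, tolerance = 0.12)
  expect_equal(mean(is.na(co$grade)), 0.25, tolerance = 0.18)
  expect_false(anyNA(co$sex)); expect_false(anyNA(co$subtype))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- demoSimulationConfig(nSubtypes = 3L, nPerSubtype = 30L)
  d1 <- simulateDataset(cfg, seed = 17)
  d2 <- simulateDataset(cfg, seed = 17)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
  d3 <- simulateDataset(cfg, seed = 18)
  expect_false(identical(snvTable(d1), snvTable(d3)))
})

test_that("driver rates converge to the planted log odds ratio", {
  co <- toyCohort(40000)
  cfg <- list(drivers = list(events = list(
    list(id = "NULL1", baseline = 0.2, logOR = 0, favoured = "male"),
    list(id = "EFF1", baseline = 0.13, logOR = log(3),
         favoured = "male"))))
  dm <- simulateDriverMutations(co, cfg, seed = 4)
  isM <- co$sex == "male"
  expect_lt(abs(mean(dm[isM, "NULL1"]) - mean(dm[!isM, "NULL1"])), 0.02)
  # inverting the logistic: female 13% with log-OR log(3) -> male ~31%
  expect_equal(mean(dm[!isM, "EFF1"]), 0.13, tolerance = 0.03)
  expect_equal(mean(dm[isM, "EFF1"]), plogis(qlogis(0.13) + log(3)),
               tolerance = 0.03)
  # empirical log-OR within 10% relative error at this scale
  or <- (mean(dm[isM, "EFF1"]) / (1 - mean(dm[isM, "EFF1"]))) /
    (mean(dm[!isM, "EFF1"]) / (1 - mean(dm[!isM, "EFF1"])))
  expect_equal(log(or), log(3), tolerance = 0.1)
  expect_error(simulateDriverMutations(
    co, list(drivers = list(events = list(
      list(id = "X", baseline = 0, logOR = 0, favoured = "male")))), 1),
    "strictly in")
})

test_that("SNV counts recover the planted multiplier and Poisson limit", {
  gm <- makeGenomeModel(defaultGenomeConfig(genesPerChrom = 0L), 1)
  co <- toyCohort(1000)
  cfg <- list(snv = list(ratePerMbp = 1, dispersion = 2, multiplier = 2,
                         favoured = "male"))
  snv <- simulateSnvCounts(co, gm, cfg, seed = 6)
  tot <- snv$coding_count + snv$noncoding_count
  isM <- co$sex == "male"
  ratio <- median(tot[isM]) / median(tot[!isM])
  expect_gte(ratio, 1.8); expect_lte(ratio, 2.2)

  cfg <- list(snv = list(ratePerMbp = 1, dispersion = 1e7,
                         multiplier = 1, favoured = "male"))
  snv <- simulateSnvCounts(co, gm, cfg, seed = 6)
  tot <- snv$coding_count + snv$noncoding_count
  expect_lt(var(tot) / mean(tot), 1.2)   # near-Poisson dispersion
  expect_error(simulateSnvCounts(
    co, gm, list(snv = list(ratePerMbp = -1, dispersion = 2)), 1),
    "positive")
})

test_that("null SNV simulation gives uniform Mann-Whitney p-values", {
  gm <- makeGenomeModel(toyGenomeConfig(), 1)
  co <- toyCohort(500)
  cfg <- list(snv = list(ratePerMbp = 2, dispersion = 2, multiplier = 1))
  ps <- vapply(1:200, function(s) {
    snv <- simulateSnvCounts(co, gm, cfg, seed = s)
    tot <- snv$coding_count + snv$noncoding_count
    mannWhitneyTest(tot[co$sex == "male"], tot[co$sex == "female"],
                    conf = FALSE, exact = FALSE)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("CNA segments respect structure and planted boundary effects", {
  gm <- toyGenome()
  co <- toyCohort(40)
  # all probabilities zero -> no segments -> PGA 0 downstream
  segs <- simulateCnaSegments(co, gm, list(cna = list(gainProb = 0,
                                                      lossProb = 0)), 1)
  expect_length(segs, 0)
  pga <- featureValues(computeInstability(segs, gm, co$donor_id,
                                          chromLevel = FALSE))
  expect_true(all(pga$value == 0))

  # whole-chromosome gain for males only on chromosome "1"
  cfg <- list(cna = list(gainProb = 0, lossProb = 0, lengthFraction = 1,
                         effects = list(list(chrom = "1", call = "gain",
                                             shift = 1,
                                             favoured = "male"))))
  segs <- simulateCnaSegments(co, gm, cfg, 1)
  fv <- featureValues(computeInstability(segs, gm, co$donor_id))
  g1 <- fv[fv$feature_id == "pga_gain_chr1", ]
  sexOf <- setNames(co$sex, co$donor_id)
  expect_true(all(g1$value[sexOf[g1$donor_id] == "male"] == 100))
  expect_true(all(g1$value[sexOf[g1$donor_id] == "female"] == 0))

  # random configuration: per-donor/chrom disjointness and bounds
  cfg <- list(cna = list(gainProb = 0.6, lossProb = 0.6))
  segs <- simulateCnaSegments(co, gm, cfg, 2)
  expect_gt(length(segs), 0)
  df <- segmentsToDf(segs)
  expect_true(all(df$end > df$start))
  expect_true(all(df$end <= chromLengths(gm)[df$chrom]))
  for (key in unique(paste(df$donor_id, df$chrom))) {
    rows <- df[paste(df$donor_id, df$chrom) == key, ]
    if (nrow(rows) > 1) {
      o <- order(rows$start)
      expect_true(all(rows$start[o][-1] >= rows$end[o][-nrow(rows)]))
    }
  }
  # determinism
  expect_identical(
    serialize(simulateCnaSegments(co, gm, cfg, 2), NULL),
    serialize(simulateCnaSegments(co, gm, cfg, 2), NULL))
})

test_that("clonality and timing obey their invariants", {
  co <- toyCohort(300)
  cfg <- list(clonality = list(polyProb = 0, clusterLambda = 1),
              timing = list(classes = list(
                SNV = list(totalMean = 100, totalDisp = 2,
                           truncal = 0.5, kappa = 10))))
  ct <- simulateClonalityTiming(co, cfg, 1)
  expect_true(all(ct$clonality$n_clusters == 1))
  # monoclonal donors carry no subclonal variants
  expect_true(all(ct$timing$n_subclonal == 0))

  cfg$clonality$polyProb <- 1
  cfg$timing$classes$SNV$truncal <- 1
  ct <- simulateClonalityTiming(co, cfg, 1)
  expect_true(all(ct$clonality$n_clusters >= 2))
  expect_true(all(ct$timing$n_subclonal == 0))  # truncal parameter 1.0

  expect_error(simulateClonalityTiming(
    co, list(clonality = list(polyProb = 1.4)), 1), "polyProb")
})

test_that("planted truncal-fraction shift is recovered at n = 200 per sex", {
  co <- toyCohort(400)
  cfg <- list(
    clonality = list(polyProb = 1, clusterLambda = 0.5),
    timing = list(
      classes = list(SV = list(totalMean = 60, totalDisp = 3,
                               truncal = 0.82, kappa = 12)),
      effects = list(list(class = "SV", shift = 0.18,
                          favoured = "male"))))
  diffs <- vapply(1:20, function(s) {
    tm <- simulateClonalityTiming(co, cfg, s)$timing
    fr <- tm$n_truncal / (tm$n_truncal + tm$n_subclonal)
    sexOf <- setNames(co$sex, co$donor_id)
    median(fr[sexOf[tm$donor_id] == "male"], na.rm = TRUE) -
      median(fr[sexOf[tm$donor_id] == "female"], na.rm = TRUE)
  }, numeric(1))
  # male parameter is driven to 1.0; the female Beta median sits slightly
  # above its mean, so the recovered difference brackets the planted 0.18
  expect_gt(mean(diffs), 0.10)
  expect_lt(mean(diffs), 0.24)
})

test_that("signature counts conserve class totals and planted presence", {
  co <- toyCohort(8000)
  cfg <- demoSimulationConfig()["signatures"]
  sg <- simulateSignatures(co, cfg, seed = 3)
  cls <- sg$classes
  # per-donor counts within a class sum to the drawn class total by
  # construction; fractions over detected signatures must sum to 1
  for (clName in unique(cls)) {
    jj <- names(cls)[cls == clName]
    tot <- rowSums(sg$counts[, jj, drop = FALSE])
    ok <- tot > 0
    fr <- sg$counts[ok, jj, drop = FALSE] / tot[ok]
    expect_equal(unname(rowSums(fr)), rep(1, sum(ok)))
  }
  # planted SBS1 presence log-odds 1.48 towards female: 88% vs ~97%
  isM <- co$sex == "male"
  posM <- mean(sg$counts[isM, "SBS1"] > 0)
  posF <- mean(sg$counts[!isM, "SBS1"] > 0)
  expect_equal(posM, 0.88, tolerance = 0.03)
  expect_equal(posF, plogis(qlogis(0.88) + 1.48), tolerance = 0.03)

  # presence probability 1 for all -> everyone positive
  cfg2 <- list(signatures = list(
    catalogue = data.frame(id = c("S1", "S2"), class = "SBS",
                           presence = 1, weight = c(0.5, 0.5)),
    classTotals = list(SBS = c(500, 2))))
  sg2 <- simulateSignatures(toyCohort(200), cfg2, 1)
  expect_true(all(rowSums(sg2$counts > 0) == 2))

  bad <- list(signatures = list(
    catalogue = data.frame(id = "S1", class = "SBS", presence = 0.5,
                           weight = -1)))
  expect_error(simulateSignatures(co, bad, 1), "composition")
})

test_that("planted truth echoes the configuration", {
  cfg <- demoSimulationConfig(nSubtypes = 2L, nPerSubtype = 20L)
  ds <- simulateDataset(cfg, 1)
  tr <- plantedTruth(ds)
  expect_true(all(c("driver_DRV1", "polyclonal", "sig_SBS1_present",
                    "pga_gain_chr7", "truncal_SV", "density_overall") %in%
                    tr$feature_id))
  expect_equal(tr$magnitude[tr$feature_id == "driver_DRV1"], log(3))
  expect_equal(tr$magnitude[tr$feature_id == "driver_DRV2"], 0)
  # every planted feature id is one the pipeline can actually emit
  feats <- computeFeatures(ds)
  expect_true(all(tr$feature_id %in% featureInfo(feats)$feature_id))
})
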