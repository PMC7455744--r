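# Stage-0 feature derivation.

test_that("mutation densities match hand arithmetic", {
  gm <- makeGenomeModel(
    toyGenomeConfig(lengths = c("1" = 150e6, "2" = 150e6),
                    codingSize = 30e6), 1)
  snv <- data.frame(donor_id = c("a", "b", "c"),
                    coding_count = c(30, 0, 45),
                    noncoding_count = c(0, 0, 255))
  fv <- featureValues(computeMutationDensity(snv, gm))
  val <- function(d, f) fv$value[fv$donor_id == d & fv$feature_id == f]
  expect_equal(val("a", "density_coding"), 1.0)     # 30 / 30 Mbp
  expect_equal(val("b", "density_overall"), 0)
  expect_equal(val("b", "density_coding"), 0)
  # 45+255 over 300 Mbp; 45/30; 255/270
  expect_equal(val("c", "density_overall"), 1.0)
  expect_equal(val("c", "density_coding"), 1.5)
  expect_equal(val("c", "density_noncoding"), 255 / 270)
})

test_that("percent gained/lost/altered match hand arithmetic", {
  gm <- makeGenomeModel(
    toyGenomeConfig(lengths = c("1" = 100e6), codingSize = 1e6), 1)
  donors <- c("a", "b")
  # donor a: one 10 Mbp gain plus a disjoint 5 Mbp loss; donor b: nothing
  segs <- segGR(gm, c("a", "a"), c("1", "1"),
                start = c(0, 50e6), end = c(10e6, 55e6),
                call = c("gain", "loss"))
  fv <- featureValues(computeInstability(segs, gm, donors))
  val <- function(d, f) fv$value[fv$donor_id == d & fv$feature_id == f]
  expect_equal(val("a", "pga_gain_chr1"), 10)
  expect_equal(val("a", "pga_loss_chr1"), 5)
  expect_equal(val("a", "pga_alt_chr1"), 15)
  expect_equal(val("a", "pga_alt_auto"), 15)
  expect_true(all(fv$value[fv$donor_id == "b"] == 0))
  expect_true(all(fv$value >= 0 & fv$value <= 100))
  # out-of-bounds segments are rejected
  bad <- suppressWarnings(segGR(gm, "a", "1", 99e6, 101e6, "gain"))
  expect_error(computeInstability(bad, gm, donors), "bounds")
})

test_that("percent values equal the per-basepair brute-force oracle", {
  gm <- toyGenome()   # chromosomes of 10 kbp and 8 kbp
  co <- toyCohort(12)
  cfg <- list(cna = list(gainProb = 0.7, lossProb = 0.7))
  segs <- simulateCnaSegments(co, gm, cfg, 5)
  fv <- featureValues(computeInstability(segs, gm, co$donor_id))
  oracle <- brutePGA(segmentsToDf(segs), chromLengths(gm))
  for (i in seq_len(nrow(oracle))) {
    o <- oracle[i, ]
    L <- chromLengths(gm)[[o$chrom]]
    val <- function(f) fv$value[fv$donor_id == o$donor_id &
                                  fv$feature_id == f]
    for (piece in list(c("gain", "gained"), c("loss", "lost"),
                       c("alt", "altered"))) {
      got <- val(sprintf("pga_%s_chr%s", piece[1], o$chrom))
      want <- o[[piece[2]]]
      # the underlying basepair counts agree exactly; the percent scaling
      # is identical up to one float rounding of s/L*100 vs 100*s/L
      expect_identical(round(got * L / 100), round(want * L / 100))
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("percent values are scale invariant and monotone", {
  lens <- c("1" = 1e4, "2" = 8e3)
  gm <- makeGenomeModel(toyGenomeConfig(lengths = lens), 1)
  gm10 <- makeGenomeModel(toyGenomeConfig(lengths = lens * 10), 1)
  segs <- segGR(gm, c("a", "a", "b"), c("1", "2", "1"),
                start = c(100, 0, 4000), end = c(600, 8000, 9000),
                call = c("gain", "loss", "gain"))
  segs10 <- segGR(gm10, c("a", "a", "b"), c("1", "2", "1"),
                  start = c(1000, 0, 40000), end = c(6000, 80000, 90000),
                  call = c("gain", "loss", "gain"))
  f1 <- featureValues(computeInstability(segs, gm, c("a", "b")))
  f2 <- featureValues(computeInstability(segs10, gm10, c("a", "b")))
  expect_equal(f1$value, f2$value)

  # adding an aberrant segment never decreases percent altered
  more <- c(segs, segGR(gm, "b", "2", 0, 1000, "loss"))
  f3 <- featureValues(computeInstability(more, gm, c("a", "b")))
  alt1 <- f1$value[grepl("pga_alt", f1$feature_id)]
  alt3 <- f3$value[grepl("pga_alt", f3$feature_id)]
  expect_true(all(alt3 >= alt1))
})

test_that("gene-level CNA calls follow the majority rule", {
  lens <- c("1" = 1e4)
  cfg <- toyGenomeConfig(lengths = lens, genesPerChrom = 0L)
  si <- GenomeInfoDb::Seqinfo("1", 1e4)
  genes <- GenomicRanges::GRanges(
    "1", IRanges::IRanges(start = c(1001, 5001), width = 1000),
    gene_id = c("gA", "gB"), seqinfo = si)
  gm <- new("GenomeModel", genes = genes, codingSize = 1000)
  donors <- c("d1", "d2", "d3")
  segs <- c(
    segGR(gm, "d1", "1", 500, 2500, "gain"),    # covers gA fully
    segGR(gm, "d2", "1", 1000, 1600, "gain"),   # 60% of gA
    segGR(gm, "d3", "1", 1000, 1500, "gain"),   # exactly 50% -> neutral
    segGR(gm, "d3", "1", 5000, 5400, "loss"))   # 40% of gB -> neutral
  calls <- callGeneCna(segs, gm, donors)
  expect_equal(calls["d1", "gA"], "gain")
  expect_equal(calls["d2", "gA"], "gain")
  expect_equal(calls["d3", "gA"], "neutral")   # 50/50 tie
  expect_equal(calls["d1", "gB"], "neutral")   # no overlap
  expect_equal(calls["d3", "gB"], "neutral")   # minority loss
  anyCalls <- callGeneCna(segs, gm, donors, rule = "any")
  expect_equal(anyCalls["d3", "gA"], "gain")
  expect_equal(anyCalls["d3", "gB"], "loss")
  fs <- geneCnaFeatures(calls)
  gv <- featureValues(fs)
  expect_equal(gv$value[gv$feature_id == "cna_gain_gA" &
                          gv$donor_id == "d2"], 1)
})

test_that("clonality binarization and truncal fractions", {
  cl <- data.frame(donor_id = c("a", "b", "c"),
                   n_clusters = c(1L, 3L, 2L))
  fv <- featureValues(binarizeClonality(cl))
  expect_equal(fv$value, c(0, 1, 1))
  expect_error(binarizeClonality(
    data.frame(donor_id = "x", n_clusters = 0L)), ">= 1")

  tm <- data.frame(donor_id = c("a", "a", "b", "c"),
                   variant_class = c("SNV", "SV", "SNV", "SNV"),
                   n_truncal = c(3L, 5L, 0L, 0L),
                   n_subclonal = c(1L, 0L, 4L, 0L))
  fv <- featureValues(computeTruncalFraction(tm))
  val <- function(d, f) fv$value[fv$donor_id == d & fv$feature_id == f]
  expect_equal(val("a", "truncal_SNV"), 0.75)
  expect_equal(val("a", "truncal_SV"), 1.0)
  expect_equal(val("b", "truncal_SNV"), 0)
  # zero-total donor is excluded from the feature entirely
  expect_length(val("c", "truncal_SNV"), 0)
})

test_that("signature features: presence, fractions, exclusions", {
  counts <- rbind(d1 = c(10L, 30L, 5L),
                  d2 = c(0L, 50L, 0L),
                  d3 = c(0L, 0L, 7L))
  colnames(counts) <- c("sigA", "sigB", "idC")
  classes <- c(sigA = "SBS", sigB = "SBS", idC = "ID")
  fs <- computeSignatureFeatures(counts, classes)
  fv <- featureValues(fs)
  val <- function(d, f) fv$value[fv$donor_id == d & fv$feature_id == f]
  expect_equal(val("d1", "sig_sigA_present"), 1)
  expect_equal(val("d2", "sig_sigA_present"), 0)
  expect_equal(val("d1", "sig_sigA_activity"), 0.25)
  expect_equal(val("d1", "sig_sigB_activity"), 0.75)
  # count 0 -> no activity value for that donor
  expect_length(val("d2", "sig_sigA_activity"), 0)
  # zero class total -> excluded from that class's features
  expect_length(val("d3", "sig_sigA_present"), 0)
  expect_equal(val("d3", "sig_idC_present"), 1)
  # composition: fractions of detected signatures sum to 1 per class
  expect_equal(val("d1", "sig_sigA_activity") +
                 val("d1", "sig_sigB_activity"), 1)
  expect_error(computeSignatureFeatures(-counts, classes),
               "non-negative")
})
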