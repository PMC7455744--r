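# Small fixtures built in code.

toyGenomeConfig <- function(lengths = c("1" = 1e4, "2" = 8e3),
                            codingSize = 1e3, genesPerChrom = 0L) {
  list(chromLengths = lengths, codingSize = codingSize,
       genesPerChrom = genesPerChrom, geneSize = 200)
}

toyGenome <- function(...) makeGenomeModel(toyGenomeConfig(...), seed = 1)

# A minimal cohort with explicit sexes, one row per donor.
toyCohort <- function(n = 20, maleFrac = 0.5, subtype = "A") {
  nM <- round(n * maleFrac)
  data.frame(donor_id = sprintf("%s%03d", subtype, seq_len(n)),
             sex = rep(c("male", "female"), c(nM, n - nM)),
             age = 60, ancestry = "EUR", subtype = subtype,
             stage = "II", grade = "G2", stringsAsFactors = FALSE)
}

# GRanges builder for hand-specified segments (0-based half-open input).
segGR <- function(genome, donor, chrom, start, end, call) {
  GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start + 1L, end = end),
    donor_id = donor, call = call,
    seqinfo = GenomeInfoDb::seqinfo(geneCatalogue(genome)))
}

# FeatureSet from a plain data.frame of values.
toyFeatures <- function(values, analysis = "density",
                        kind = "continuous", group = NA_character_) {
  ids <- unique(values$feature_id)
  new("FeatureSet", values = values,
      info = data.frame(feature_id = ids, analysis = analysis,
                        kind = kind, group = group,
                        stringsAsFactors = FALSE))
}
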