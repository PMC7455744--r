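# Independent oracles used to freeze expected values.  These deliberately
# share no code with the implementation paths they check.

# Exact two-sided Mann-Whitney p by full enumeration of all C(N, nm)
# group assignments of the pooled sample (tie-free inputs only).
bruteMWp <- function(m, f) {
  pooled <- c(m, f)
  nm <- length(m)
  combos <- utils::combn(length(pooled), nm)
  uOf <- function(idx) {
    g1 <- pooled[idx]; g2 <- pooled[-idx]
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  }
  uAll <- apply(combos, 2, uOf)
  uObs <- uOf(seq_len(nm))
  min(1, 2 * min(mean(uAll <= uObs), mean(uAll >= uObs)))
}

# Brute-force Hodges-Lehmann estimate: median over every pairwise m - f.
bruteHL <- function(m, f) stats::median(outer(m, f, "-"))

# Literal step-up BH: q_(i) = min_{j >= i} m * p_(j) / j, computed by
# definition with an explicit loop.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[o[i]] <- min(1, min(m * p[o[js]] / js))
  }
  q
}

# Per-basepair accumulation oracle for percent gained/lost/altered on tiny
# chromosomes: mark every covered basepair in a logical vector.
brutePGA <- function(segDf, chromLengths) {
  # segDf: donor_id, chrom, start (0-based), end (half-open), call
  donors <- unique(segDf$donor_id)
  out <- list()
  for (d in donors) {
    for (ch in names(chromLengths)) {
      L <- chromLengths[[ch]]
      gain <- logical(L); loss <- logical(L)
      rows <- segDf[segDf$donor_id == d & segDf$chrom == ch, ,
                    drop = FALSE]
      for (i in seq_len(nrow(rows))) {
        bp <- seq.int(rows$start[i] + 1L, rows$end[i])
        if (rows$call[i] == "gain") gain[bp] <- TRUE else loss[bp] <- TRUE
      }
      out[[paste(d, ch)]] <- data.frame(
        donor_id = d, chrom = ch,
        gained = 100 * sum(gain) / L, lost = 100 * sum(loss) / L,
        altered = 100 * sum(gain | loss) / L, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# GRanges segments -> the BED-like data.frame brutePGA consumes.
segmentsToDf <- function(gr) {
  data.frame(donor_id = gr$donor_id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             call = gr$call, stringsAsFactors = FALSE)
}
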