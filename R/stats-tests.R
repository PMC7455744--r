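# Stage-1 univariate test primitives.  These are thin, contract-enforcing
# wrappers over the standard R tests so that every stage of the pipeline
# (including the down-sampling engine) applies identical semantics.

#' Two-sample proportion test (male vs female)
#'
#' Two-sided test of equal proportions with Yates continuity correction,
#' i.e. the classical continuity-corrected chi-squared test on the 2x2
#' table, with the matching continuity-corrected Wald interval for the
#' difference in proportions.  Degenerate tables whose test statistic is
#' undefined (both groups all-success or all-failure) return p = 1.
#'
#' @param xM,nM Successes and trials among male donors.
#' @param xF,nF Successes and trials among female donors.
#' @return list with p, statistic (X-squared), effect (male minus female
#'   proportion), ciLow, ciHigh.
#' @export
#' @examples
#' twoProportionTest(31, 100, 13, 100)
twoProportionTest <- function(xM, nM, xF, nF) {
  if (nM < 1 || nF < 1) stop("zero trials in a group")
  if (xM < 0 || xM > nM || xF < 0 || xF > nF)
    stop("successes must lie in [0, n]")
  ht <- suppressWarnings(
    stats::prop.test(c(xM, xF), c(nM, nF), correct = TRUE))
  p <- ht$p.value
  stat <- unname(ht$statistic)
  if (is.nan(p)) { p <- 1; stat <- 0 }
  list(p = p, statistic = stat, effect = xM / nM - xF / nF,
       ciLow = ht$conf.int[1], ciHigh = ht$conf.int[2])
}

#' Mann-Whitney U test with Hodges-Lehmann location shift
#'
#' Two-sided rank-sum test: exact for small tie-free samples, otherwise
#' normal approximation with tie correction and continuity correction (the
#' `wilcox.test` conventions).  The location shift is the Hodges-Lehmann
#' estimate, the median of all pairwise male-minus-female differences; with
#' `conf = TRUE` its rank-inversion 95% confidence interval is returned.
#'
#' @param m,f Numeric values for male and female donors (NAs dropped).
#' @param conf Compute the rank-inversion confidence interval (slower).
#' @param exact Passed to [stats::wilcox.test()]; NULL keeps its defaults.
#' @return list with p, statistic (U), effect (HL shift), ciLow, ciHigh.
#' @export
#' @examples
#' mannWhitneyTest(c(1, 2, 3, 4), c(5, 6, 7, 8))
mannWhitneyTest <- function(m, f, conf = TRUE, exact = NULL) {
  m <- m[!is.na(m)]; f <- f[!is.na(f)]
  if (!length(m) || !length(f)) stop("empty group")
  ht <- suppressWarnings(
    stats::wilcox.test(m, f, conf.int = conf, exact = exact,
                       correct = TRUE))
  # the pairwise median is computed directly: wilcox.test's large-sample
  # estimate comes from root-finding and deviates in the far decimals
  eff <- if (length(m) * length(f) <= 4e6)
    stats::median(outer(m, f, "-")) else unname(ht$estimate)
  ci <- if (conf) ht$conf.int else c(NA_real_, NA_real_)
  list(p = ht$p.value, statistic = unname(ht$statistic), effect = eff,
       ciLow = ci[1], ciHigh = ci[2])
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' @param m,f Numeric values for male and female donors (NAs dropped).
#' @return list with p and D (the maximum ECDF distance).
#' @export
ksTest <- function(m, f) {
  m <- m[!is.na(m)]; f <- f[!is.na(f)]
  if (!length(m) || !length(f)) stop("empty group")
  ht <- suppressWarnings(stats::ks.test(m, f))
  list(p = ht$p.value, D = unname(ht$statistic))
}

# Fast internal equivalents of the approximate test branches, used by the
# screening and down-sampling engines where per-call overhead dominates.
# .fastMW reproduces wilcox.test(correct = TRUE, exact = FALSE) exactly
# (normal approximation with tie and continuity correction); .fastProp
# reproduces prop.test(correct = TRUE)'s p-value (Yates chi-squared).

.fastMW <- function(m, f) {
  nm <- length(m); nf <- length(f)
  r <- rank(c(m, f))
  U <- sum(r[seq_len(nm)]) - nm * (nm + 1) / 2
  N <- nm + nf
  cnt <- tabulate(match(r, unique(r)))
  sigma2 <- (nm * nf / 12) *
    ((N + 1) - sum(cnt^3 - cnt) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1))
  z <- U - nm * nf / 2
  z <- z - sign(z) * 0.5
  p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
  list(U = U, p = p)
}

.fastProp <- function(xM, nM, xF, nF) {
  a <- xM; b <- nM - xM; c_ <- xF; d <- nF - xF
  n <- nM + nF
  s1 <- a + c_; s2 <- b + d
  if (s1 == 0 || s2 == 0) return(list(stat = 0, p = 1))
  num <- max(0, abs(a * d - b * c_) - n / 2)
  stat <- n * num^2 / (as.double(nM) * nF * s1 * s2)
  list(stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment; a thin validating wrapper over
#' `p.adjust(method = "BH")`, kept as a named operation because FDR-family
#' membership is a first-class concept in this pipeline.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length; elementwise `q >= p` and
#'   order-preserving.
#' @export
bhFdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}
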