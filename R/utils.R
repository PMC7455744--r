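# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Every stochastic operation in the package draws its own seed from a single
#' master seed through this splitting rule, so that each simulation component
#' is individually reproducible and insensitive to the order in which other
#' components run.  The rule is a fixed affine map modulo the Mersenne prime
#' 2^31 - 1:
#'
#' \deqn{child = (seed \times 7919 + stream \times 104729 + 17) \bmod (2^{31}-1)}
#'
#' All arithmetic stays below 2^53 so the map is exact in double precision.
#'
#' @param seed Integer master seed (any finite number; reduced mod 2^31-1).
#' @param stream Integer stream index identifying the consuming operation.
#' @return A single integer-valued numeric in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' childSeed(42, 1)
#' childSeed(42, 2)
childSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, is.finite(stream))
  s <- as.double(seed) %% 2147483647
  (s * 7919 + as.double(stream) %% 2147483647 * 104729 + 17) %% 2147483647
}

# Stream indices for the simulation components (documented part of the
# splitting rule; changing them changes every simulated dataset).
.seedStreams <- c(genome = 1L, cohort = 2L, drivers = 3L, snv = 4L,
                  cna = 5L, clonality = 6L, signatures = 7L, stage3 = 8L)

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# sample() misbehaves on length-1 vectors; this never does.
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Modal level of a character/factor vector (ties broken by first occurrence
# in frequency order), used for treatment-coding reference levels.
modalLevel <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1L]
}

stopIfNot01 <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(x)
}
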