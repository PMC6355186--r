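# Internal helpers shared across the package.

#' Population standard deviation
#'
#' Standard deviation with the n (not n-1) denominator. Retention-time and
#' concentration CVs in this package are descriptive summaries, so the
#' population form is used throughout (see [coefficientOfVariation()]).
#'
#' @param x Numeric vector, length >= 1.
#' @return A single non-negative number.
#' @keywords internal
popSd <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty vector")
  sqrt(sum((x - mean(x))^2) / n)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All stochastic fits and generators route through this so
# that seeded results are reproducible without clobbering the session stream.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministic per-unit substream seeds derived from a master seed, kept
# below 2^31 so they are valid R integer seeds. Adding units never perturbs
# the seeds of earlier units.
subSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483647)
}

.assertProb <- function(x, name = deparse(substitute(x))) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", name))
  }
  invisible(x)
}
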