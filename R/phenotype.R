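# Phenotype readouts: linear-phase growth rate, 4PL dose-response EC50 and
# the combination-treatment cell-death contrast.

#' Growth rate from the linear-like phase of a confluence curve
#'
#' Scans all contiguous windows covering at least
#' \code{minWindowFraction} of the time points, picks the window whose
#' least-squares line has the highest R-squared (ties broken towards
#' longer, then earlier windows), and reports that line's slope in
#' percent confluence per hour. A constant curve fits its own mean
#' perfectly and returns slope 0.
#'
#' @param time Time in hours, strictly increasing, >= 5 points.
#' @param confluence Percent confluence in [0, 100], same length.
#' @param minWindowFraction Minimum fraction of points a window must span
#'   (default 0.3).
#' @return List with \code{slope} (\%/h), \code{window} (start and end
#'   times), \code{r2} and \code{n} (points in the window).
#' @export
fitGrowthRate <- function(time, confluence, minWindowFraction = 0.3) {
  n <- length(time)
  if (n < 5L) stop("at least 5 time points are required")
  if (length(confluence) != n) stop("time and confluence lengths differ")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")

  # O(1) per-window regression via prefix sums
  ct <- cumsum(c(0, time)); ct2 <- cumsum(c(0, time^2))
  cy <- cumsum(c(0, confluence)); cy2 <- cumsum(c(0, confluence^2))
  cty <- cumsum(c(0, time * confluence))
  minLen <- max(2L, ceiling(minWindowFraction * n))

  best <- list(r2 = -Inf, len = 0L, start = Inf, slope = NA_real_)
  for (len in minLen:n) {
    for (s in seq_len(n - len + 1L)) {
      e <- s + len - 1L
      St <- ct[e + 1] - ct[s];  St2 <- ct2[e + 1] - ct2[s]
      Sy <- cy[e + 1] - cy[s];  Sy2 <- cy2[e + 1] - cy2[s]
      Sty <- cty[e + 1] - cty[s]
      Stt <- St2 - St^2 / len
      Syy <- Sy2 - Sy^2 / len
      Sxy <- Sty - St * Sy / len
      if (Stt <= 0) stop("degenerate window: constant time")
      if (Syy <= .Machine$double.eps * abs(Sy2)) {
        slope <- 0; r2 <- 1   # flat response: perfect constant fit
      } else {
        slope <- Sxy / Stt
        r2 <- (Sxy^2 / Stt) / Syy
        r2 <- min(1, r2)
      }
      better <- r2 > best$r2 + 1e-12 ||
        (abs(r2 - best$r2) <= 1e-12 &&
           (len > best$len || (len == best$len && s < best$start)))
      if (better) best <- list(r2 = r2, len = len, start = s, slope = slope)
    }
  }
  s <- best$start; e <- s + best$len - 1L
  list(slope = best$slope, window = c(start = time[s], end = time[e]),
       r2 = best$r2, n = best$len)
}

#' Four-parameter log-logistic EC50 fit
#'
#' Least-squares fit of \code{y = lower + (upper - lower) *
#' dose^hill / (dose^hill + ec50^hill)} to a dose-response series, with
#' bound constraints keeping the asymptotes in [0, 1] and the hill slope
#' positive. The EC50 is the dose at half-maximal response between the
#' fitted asymptotes; its standard error is reported as the \code{tol}
#' field. Unfittable data are reported as a failure
#' (\code{converged = FALSE}, EC50 \code{NA}) rather than extrapolated
#' silently; an EC50 outside the tested dose range is flagged
#' \code{extrapolated}.
#'
#' @param dose Doses in uM (>= 4 distinct values including 0 or a low
#'   anchor).
#' @param response Fraction affected in [0, 1], same length.
#' @return List with \code{ec50}, \code{hill}, \code{lower},
#'   \code{upper}, \code{tol} (EC50 standard error), \code{converged}
#'   and \code{extrapolated}.
#' @export
fitEc50 <- function(dose, response) {
  if (length(unique(dose)) < 4L) stop("at least 4 distinct doses are required")
  .assertProb(response, "response")
  if (any(dose < 0)) stop("doses must be non-negative")

  lo <- min(response); hi <- max(response)
  mid <- (lo + hi) / 2
  posDose <- dose[dose > 0]
  model <- function(p) p[1] + (p[2] - p[1]) * dose^p[4] / (dose^p[4] + p[3]^p[4])
  resid <- function(p) response - model(p)
  starts <- list(
    c(lo, hi, posDose[which.min(abs(response[dose > 0] - mid))], 1),
    c(0, 1, stats::median(posDose), 1.5),
    c(lo, hi, exp(mean(log(posDose))), 0.5)
  )
  best <- NULL
  for (start in starts) {
    out <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = start, fn = resid,
        lower = c(0, 0, min(posDose) * 1e-3, 0.05),
        upper = c(1, 1, max(posDose) * 1e3, 50),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (!is.null(out) && out$info %in% 1:4 &&
        (is.null(best) || out$deviance < best$deviance)) {
      best <- out
    }
  }
  if (is.null(best)) {
    return(list(ec50 = NA_real_, hill = NA_real_, lower = NA_real_,
                upper = NA_real_, tol = NA_real_, converged = FALSE,
                extrapolated = NA))
  }
  cf <- best$par
  dfres <- length(response) - 4L
  se <- tryCatch({
    covm <- solve(best$hessian) * best$deviance / max(dfres, 1L)
    sqrt(diag(covm))[3]
  }, error = function(e) NA_real_)
  list(ec50 = cf[3], hill = cf[4], lower = cf[1], upper = cf[2],
       tol = se, converged = TRUE,
       extrapolated = cf[3] < min(posDose) || cf[3] > max(dose))
}

#' Combination-treatment cell-death contrast
#'
#' Percent increase in cell death of a combination treatment over the
#' single agent. The default is the percentage-point difference
#' \code{pCombo - pSingle}; the relative alternative
#' \code{100 * (pCombo - pSingle) / pSingle} is available behind
#' \code{relative = TRUE}.
#'
#' @param pCombo,pSingle Percent dead in [0, 100].
#' @param relative Use the relative-percent convention.
#' @return Contrast in percentage points (or relative percent).
#' @export
percentIncreaseDeath <- function(pCombo, pSingle, relative = FALSE) {
  if (any(pCombo < 0 | pCombo > 100) || any(pSingle < 0 | pSingle > 100)) {
    stop("percent dead must lie in [0, 100]")
  }
  if (relative) {
    if (any(pSingle == 0)) stop("relative contrast undefined at pSingle = 0")
    100 * (pCombo - pSingle) / pSingle
  } else {
    pCombo - pSingle
  }
}
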