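# Local false discovery rates from a monotone (Grenander) density estimate of
# the p-value distribution. Under the two-groups model f(p) = eta0 + (1 -
# eta0) f_alt(p) with f_alt concentrated near 0, the p-value density is
# non-increasing; its Grenander estimate is the left derivative of the least
# concave majorant (LCM) of the empirical CDF, computed by pool-adjacent-
# violators on the ECDF increments.

#' Grenander (monotone) density estimate of p-values
#'
#' Computes the non-increasing step density given by the slopes of the least
#' concave majorant of the empirical CDF on `[0, 1]`. Knots are 0, the sorted
#' unique p-values, and 1; the density integrates to exactly 1.
#'
#' @param p_values Numeric vector of at least 10 p-values in `[0, 1]`.
#' @return An object of class `profdiff_grenander`: list with `knots`
#'   (increasing breakpoints, first 0, last 1), `heights` (non-increasing
#'   step density on each inter-knot interval), and `eta0` (`NA` until
#'   [estimate_eta0()] is applied).
#' @export
grenander_density <- function(p_values) {
  if (length(p_values) < 10) {
    pd_abort("at least 10 p-values are required", "profdiff_sample_size_error")
  }
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    pd_abort("p-values must lie in [0, 1]", "profdiff_validation_error")
  }
  n <- length(p_values)
  sp <- sort(unique(p_values))
  counts <- tabulate(match(sort(p_values), sp))
  knots <- c(0, sp)
  F <- c(0, cumsum(counts) / n)
  if (max(sp) < 1) {
    knots <- c(knots, 1)
    F <- c(F, 1)
  }
  dx <- diff(knots)
  slopes <- diff(F) / dx
  pooled <- pava_nonincreasing(slopes, dx)
  # collapse adjacent equal heights into single steps
  run <- rle(pooled)
  idx <- cumsum(run$lengths)
  structure(
    list(knots = c(0, knots[idx + 1]), heights = run$values, eta0 = NA_real_),
    class = "profdiff_grenander"
  )
}

# internal: weighted pool-adjacent-violators for a non-increasing fit
pava_nonincreasing <- function(values, weights) {
  n <- length(values)
  v <- numeric(n); w <- numeric(n); len <- integer(n)
  k <- 0
  for (i in seq_len(n)) {
    k <- k + 1
    v[k] <- values[i]; w[k] <- weights[i]; len[k] <- 1L
    while (k > 1 && v[k - 1] < v[k]) {
      v[k - 1] <- (v[k - 1] * w[k - 1] + v[k] * w[k]) / (w[k - 1] + w[k])
      w[k - 1] <- w[k - 1] + w[k]
      len[k - 1] <- len[k - 1] + len[k]
      k <- k - 1
    }
  }
  rep(v[seq_len(k)], len[seq_len(k)])
}

# internal: evaluate the step density at arbitrary p (left-continuous steps)
grenander_evaluate <- function(fit, p) {
  idx <- findInterval(p, fit$knots, left.open = TRUE)
  idx <- pmin(pmax(idx, 1L), length(fit$heights))
  fit$heights[idx]
}

# internal: the fitted (LCM) CDF at arbitrary p
grenander_cdf <- function(fit, p) {
  cums <- c(0, cumsum(fit$heights * diff(fit$knots)))
  idx <- findInterval(p, fit$knots, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(fit$heights))
  cums[idx] + fit$heights[idx] * (p - fit$knots[idx])
}

#' Estimate the null proportion from a Grenander fit
#'
#' The proportion of true-null positions, eta0, is estimated as the average
#' fitted density over the upper tail `[lambda, 1]` of the p-value scale,
#' where p-values from true alternatives are rare:
#' `eta0 = min(1, (1 - G(lambda)) / (1 - lambda))` with `G` the fitted
#' (least-concave-majorant) CDF. This is the monotone-density version of the
#' standard tail-based null-proportion estimator; by monotonicity it bounds
#' the density at 1 from above, so it errs on the conservative side.
#'
#' @param fit A `profdiff_grenander` object.
#' @param lambda Tail start in `(0, 1)` (default 0.5).
#' @return The fit with its `eta0` field set (a value in `(0, 1]`).
#' @export
estimate_eta0 <- function(fit, lambda = 0.5) {
  if (lambda <= 0 || lambda >= 1) {
    pd_abort("lambda must be in (0, 1)", "profdiff_validation_error")
  }
  eta0 <- (1 - grenander_cdf(fit, lambda)) / (1 - lambda)
  fit$eta0 <- max(min(eta0, 1), 1e-12)
  fit
}

#' Local false discovery rates from p-values
#'
#' For each p-value returns `min(1, eta0 / f(p))`, with `f` the Grenander
#' density estimate and `eta0` the estimated null proportion: the estimated
#' posterior probability that the position is null. Because `f` is
#' non-increasing, the local fdr is non-decreasing in p, so thresholding it
#' always calls a prefix of the p-sorted positions.
#'
#' @param p_values Numeric vector of at least 10 p-values in `[0, 1]`.
#' @param lambda Tail start for the eta0 estimate (default 0.5).
#' @return A numeric vector of local fdr values in `(0, 1]`, aligned with the
#'   input; the Grenander fit is attached as attribute `fit`.
#' @export
local_fdr <- function(p_values, lambda = 0.5) {
  fit <- estimate_eta0(grenander_density(p_values), lambda = lambda)
  f <- grenander_evaluate(fit, p_values)
  out <- pmin(1, ifelse(f > 0, fit$eta0 / f, 1))
  attr(out, "fit") <- fit
  out
}

#' @export
print.profdiff_grenander <- function(x, ...) {
  cat("<profdiff_grenander>\n")
  cat(sprintf("  %d steps on [0, 1]; eta0 = %s\n", length(x$heights),
              if (is.na(x$eta0)) "unset" else format(x$eta0, digits = 4)))
  invisible(x)
}
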