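# Dispersion estimation: per-position profile-likelihood estimates, a
# parametric mean-dispersion trend, and empirical-Bayes shrinkage toward the
# trend. All dispersions are clamped to [ALPHA_MIN, ALPHA_MAX].

# internal: maximize the NB log-likelihood in alpha for fixed fitted means
optimize_alpha <- function(y, mu, penalty = NULL) {
  obj <- function(la) {
    ll <- nb_loglik(y, mu, exp(la))
    if (!is.null(penalty)) ll <- ll + penalty(la)
    ll
  }
  opt <- optimize(obj, interval = log(c(ALPHA_MIN, ALPHA_MAX)), maximum = TRUE,
                  tol = 1e-6)
  exp(opt$maximum)
}

#' Per-position dispersion by profile likelihood
#'
#' Starting from a method-of-moments value on normalized counts, alternates
#' GLM fits (which give the group-wise fitted means) with maximization of the
#' NB likelihood in the dispersion, two cycles. All-zero positions return the
#' lower clamp with a `degenerate` attribute; they are excluded from trend
#' fitting and reported with p = 1 downstream.
#'
#' @param counts Non-negative integer counts, one per sample.
#' @param factors Positive normalization factors.
#' @param condition Two-level condition (factor or 0/1).
#' @return Dispersion estimate in `[1e-8, 10]`, with attribute `degenerate`.
#' @export
estimate_dispersion_raw <- function(counts, factors, condition) {
  if (all(counts == 0)) {
    return(structure(ALPHA_MIN, degenerate = TRUE))
  }
  x <- condition_indicator(condition)
  ync <- counts / factors
  m <- mean(ync)
  s2 <- stats::var(ync)
  alpha <- min(max((s2 - m) / m^2, ALPHA_MIN), ALPHA_MAX)
  for (cycle in 1:2) {
    fit <- nb_irls(counts, factors, x, alpha,
                   ridge = if (any(tapply(counts, x, sum) == 0)) 1e-6 else 0)
    alpha <- optimize_alpha(counts, fit$mu)
  }
  structure(min(max(alpha, ALPHA_MIN), ALPHA_MAX), degenerate = FALSE)
}

#' Fit the parametric mean-dispersion trend
#'
#' Regresses raw per-position dispersions on the reciprocal mean,
#' `alpha_tr(mu) = a1 / mu + a0`, by iteratively reweighted gamma-family
#' least squares, excluding gross outliers (ratio raw/trend outside
#' `[1e-4, 15]`) between iterations. Coefficients are clamped at zero. With
#' fewer than 50 usable positions the trend falls back to the flat median of
#' the raw dispersions, with a warning.
#'
#' @param raw_alphas Per-position raw dispersions.
#' @param base_means Per-position mean normalized counts.
#' @param degenerate Optional logical vector marking positions to exclude.
#' @return A list: coefficients `a0`, `a1`, the `trend` function of `mu`, and
#'   `fallback` (logical).
#' @export
fit_dispersion_trend <- function(raw_alphas, base_means, degenerate = NULL) {
  usable <- is.finite(raw_alphas) & is.finite(base_means) & base_means > 0
  if (!is.null(degenerate)) usable <- usable & !degenerate
  if (sum(usable) < 50) {
    rlang::warn(sprintf(
      "only %d usable positions; using the flat median dispersion as trend",
      sum(usable)
    ))
    a0 <- stats::median(raw_alphas[usable])
    if (!is.finite(a0)) a0 <- 0.1
    return(list(a0 = a0, a1 = 0,
                trend = function(mu) rep(a0, length(mu)), fallback = TRUE))
  }
  a <- raw_alphas[usable]
  xr <- 1 / base_means[usable]
  keep <- rep(TRUE, length(a))
  coef_old <- c(mean(a), 0)
  a0 <- coef_old[1]; a1 <- 0
  for (it in 1:10) {
    fitted <- pmax(a0 + a1 * xr, 1e-10)
    # gamma-family IRLS: weights 1 / fitted^2, identity link
    w <- ifelse(keep, 1 / fitted^2, 0)
    X <- cbind(1, xr)
    XtW <- t(X * w)
    cf <- tryCatch(unname(drop(solve(XtW %*% X, XtW %*% a))),
                   error = function(e) c(a0, a1))
    cf <- pmax(cf, 0)
    if (sum(cf) == 0) cf[1] <- stats::median(a)
    a0 <- cf[1]; a1 <- cf[2]
    fitted <- pmax(a0 + a1 * xr, 1e-10)
    keep <- a / fitted > 1e-4 & a / fitted < 15
    if (max(abs(cf - coef_old)) < 1e-6) break
    coef_old <- cf
  }
  list(a0 = a0, a1 = a1,
       trend = function(mu) a1 / mu + a0, fallback = FALSE)
}

#' Shrink a raw dispersion toward the trend
#'
#' Maximizes the NB likelihood (at the fitted means) plus a log-normal prior
#' centered at the trend value with standard deviation `prior_sd` in log
#' space. Raw estimates more than `2 * prior_sd` above the trend in log space
#' are treated as dispersion outliers and kept unshrunken.
#'
#' @param raw Raw dispersion for the position.
#' @param trend_alpha Trend value at this position's mean.
#' @param counts,factors,condition As in [estimate_dispersion_raw()].
#' @param prior_sd Prior standard deviation in log space (default 0.5).
#' @return The final (MAP) dispersion, clamped to `[1e-8, 10]`.
#' @export
shrink_dispersion <- function(raw, trend_alpha, counts, factors, condition,
                              prior_sd = 0.5) {
  if (isTRUE(attr(raw, "degenerate"))) {
    return(structure(ALPHA_MIN, degenerate = TRUE))
  }
  if (log(raw) > log(trend_alpha) + 2 * prior_sd) {
    return(structure(as.numeric(raw), outlier = TRUE))
  }
  x <- condition_indicator(condition)
  fit <- nb_irls(counts, factors, x, as.numeric(raw),
                 ridge = if (any(tapply(counts, x, sum) == 0)) 1e-6 else 0)
  penalty <- function(la) {
    stats::dnorm(la, mean = log(trend_alpha), sd = prior_sd, log = TRUE)
  }
  alpha <- optimize_alpha(counts, fit$mu, penalty = penalty)
  structure(min(max(alpha, ALPHA_MIN), ALPHA_MAX), outlier = FALSE)
}
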