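# Negative-binomial GLM core. Parametrization throughout: mean mu, dispersion
# alpha, variance mu + alpha * mu^2 (size = 1/alpha). Natural-log link
# internally; fold changes reported in log2.

ALPHA_MIN <- 1e-8
ALPHA_MAX <- 10

nb_loglik <- function(y, mu, alpha) {
  sum(dnbinom(y, size = 1 / alpha, mu = pmax(mu, 1e-300), log = TRUE))
}

# internal IRLS fit of mu_j = f_j * exp(b0 + b1 * x_j); x is the 0/1 condition
# indicator. Ridge > 0 stabilizes separated fits (a group of all zeros).
nb_irls <- function(y, f, x, alpha, ridge = 0, max_iter = 100, tol = 1e-8) {
  X <- cbind(1, x)
  o <- log(f)
  # initialize from zero-protected group means of normalized counts
  ync <- (y + 0.5) / f
  m0 <- mean(ync[x == 0])
  m1 <- mean(ync[x == 1])
  beta <- c(log(m0), log(m1) - log(m0))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta + o)
    w <- mu / (1 + alpha * mu)
    z <- eta + (y - mu) / mu
    XtW <- t(X * w)
    A <- XtW %*% X + diag(ridge, 2)
    beta_new <- drop(solve(A, XtW %*% z))
    if (any(!is.finite(beta_new))) break
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  mu <- drop(exp(X %*% beta + o))
  list(beta = beta, mu = mu, converged = converged)
}

#' Fit the per-position negative-binomial GLM
#'
#' Fits `mu_j = f_j * exp(b0 + b1 * I(condition_j == non-reference))` by
#' iteratively reweighted least squares at a fixed dispersion, and returns the
#' condition contrast on the log2 scale with its standard error from the
#' observed information. If one group has only zero counts the fit is
#' stabilized with a small ridge (1e-6) so the estimate stays finite.
#'
#' @param counts Non-negative integer counts, one per sample.
#' @param factors Strictly positive normalization factors, one per sample.
#' @param condition Factor (two levels) or 0/1 indicator; the first level is
#'   the reference.
#' @param alpha Dispersion (> 0).
#' @return A list: `log2fc`, `se`, `base_mean` (mean of `counts/factors`),
#'   `converged`.
#' @export
fit_nb_glm <- function(counts, factors, condition, alpha) {
  x <- condition_indicator(condition)
  if (any(factors <= 0)) {
    pd_abort("normalization factors must be positive", "profdiff_positivity_error")
  }
  base_mean <- mean(counts / factors)
  if (all(counts == 0)) {
    return(list(log2fc = 0, se = Inf, base_mean = 0, converged = TRUE))
  }
  zero_group <- all(counts[x == 0] == 0) || all(counts[x == 1] == 0)
  fit <- nb_irls(counts, factors, x, alpha,
                 ridge = if (zero_group) 1e-6 else 0)
  if (!zero_group && !fit$converged) {
    # retry with a mild ridge before declaring failure
    fit <- nb_irls(counts, factors, x, alpha, ridge = 1e-6)
  }
  mu <- fit$mu
  w_obs <- mu * (1 + alpha * counts) / (1 + alpha * mu)^2
  X <- cbind(1, x)
  info <- t(X * w_obs) %*% X
  se_nat <- tryCatch(sqrt(solve(info)[2, 2]), error = function(e) NA_real_)
  list(
    log2fc = unname(fit$beta[2]) / log(2),
    se = if (is.finite(se_nat)) unname(se_nat) / log(2) else Inf,
    base_mean = base_mean,
    converged = fit$converged
  )
}

#' Wald test against a minimum log2-fold-change threshold
#'
#' The null hypothesis is `|lfc| <= theta`: only positions whose estimated
#' change exceeds the threshold can score, which keeps spurious but
#' statistically detectable differences out of the called set. Inside the
#' threshold the statistic is 0 and p = 1; outside, the statistic is the
#' excess over the threshold in standard-error units and p is the two-sided
#' normal tail. With `theta = 0` this is the ordinary Wald test.
#'
#' @param log2fc Estimated log2 fold change(s).
#' @param se Standard error(s), > 0.
#' @param theta Non-negative log2 threshold.
#' @return A tibble with columns `stat` and `p_value`.
#' @export
wald_test_threshold <- function(log2fc, se, theta = 0) {
  if (theta < 0) {
    pd_abort("theta must be non-negative", "profdiff_validation_error")
  }
  stat <- ifelse(abs(log2fc) <= theta | !is.finite(se), 0,
                 (abs(log2fc) - theta) / se)
  p <- ifelse(stat == 0, 1, 2 * pnorm(stat, lower.tail = FALSE))
  tibble(stat = stat, p_value = pmin(p, 1))
}

# internal: coerce a condition spec to a 0/1 indicator (first level = ref)
condition_indicator <- function(condition) {
  if (is.numeric(condition)) {
    if (!all(condition %in% c(0, 1))) {
      pd_abort("numeric condition must be a 0/1 indicator",
               "profdiff_design_error")
    }
    x <- as.numeric(condition)
  } else {
    lev <- check_two_conditions(condition)
    x <- as.numeric(factor(condition, levels = lev)) - 1
  }
  if (length(unique(x)) != 2) {
    pd_abort("both condition groups must be present", "profdiff_design_error")
  }
  x
}
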