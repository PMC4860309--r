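#' Position-wise differential enrichment testing
#'
#' Runs the full inference pipeline on a profile dataset: Input library-size
#' matching and position-specific normalization factors, per-position
#' dispersion estimation with a parametric mean-dispersion trend and
#' empirical-Bayes shrinkage, a negative-binomial GLM per position, Wald tests
#' against the minimum log2-fold-change threshold `theta`, and (by default)
#' local false discovery rates over all positions.
#'
#' @param dataset A `profdiff_dataset` with exactly two conditions.
#' @param theta Minimum absolute log2 fold change built into the null
#'   hypothesis (default 0.05).
#' @param reference Reference condition level (default: first factor level);
#'   fold changes are non-reference over reference.
#' @param pseudocount Added to scaled Input counts before use as factors.
#' @param center_factors Row-center factors by their geometric mean.
#' @param prior_sd Dispersion shrinkage prior SD in log space.
#' @param compute_local_fdr Fill the `local_fdr` column (default `TRUE`); set
#'   to `FALSE` to apply [add_local_fdr()] separately.
#' @param lambda Tail start for the null-proportion estimate.
#' @return A `profdiff_results` object: a tibble with one row per position
#'   and columns `position`, `base_mean`, `log2fc`, `se`, `stat`, `p_value`,
#'   `local_fdr`, `dispersion`, plus attributes `theta`, `reference`, `eta0`.
#' @export
run_testing <- function(dataset, theta = 0.05, reference = NULL,
                        pseudocount = 1, center_factors = TRUE,
                        prior_sd = 0.5, compute_local_fdr = TRUE,
                        lambda = 0.5) {
  if (!inherits(dataset, "profdiff_dataset")) {
    pd_abort("dataset must be a profdiff_dataset", "profdiff_validation_error")
  }
  if (nrow(dataset$chip) == 0 || ncol(dataset$chip) == 0) {
    pd_abort("dataset is empty", "profdiff_validation_error")
  }
  if (theta < 0) pd_abort("theta must be >= 0", "profdiff_validation_error")
  cond <- dataset$annotation$condition
  lev <- check_two_conditions(cond)
  if (!is.null(reference)) {
    if (!reference %in% lev) {
      pd_abort(paste0("reference level '", reference, "' not found"),
               "profdiff_design_error")
    }
    lev <- c(reference, setdiff(lev, reference))
  }
  x <- as.numeric(factor(as.character(cond), levels = lev)) - 1

  factors <- dataset_normalization_factors(dataset, pseudocount = pseudocount,
                                           center = center_factors)
  counts <- dataset$chip
  n_pos <- nrow(counts)

  # per-position raw dispersions and base means
  raw <- vector("list", n_pos)
  for (i in seq_len(n_pos)) {
    raw[[i]] <- estimate_dispersion_raw(counts[i, ], factors[i, ], x)
  }
  raw_alpha <- vapply(raw, as.numeric, 0)
  degenerate <- vapply(raw, function(r) isTRUE(attr(r, "degenerate")), TRUE)
  base_mean <- rowMeans(counts / factors)

  trend <- fit_dispersion_trend(raw_alpha, base_mean, degenerate = degenerate)

  final_alpha <- raw_alpha
  log2fc <- numeric(n_pos); se <- rep(Inf, n_pos); conv <- rep(TRUE, n_pos)
  for (i in seq_len(n_pos)) {
    if (degenerate[i]) {
      final_alpha[i] <- ALPHA_MIN
      next
    }
    tr <- max(trend$trend(base_mean[i]), ALPHA_MIN)
    final_alpha[i] <- shrink_dispersion(raw[[i]], tr, counts[i, ],
                                        factors[i, ], x, prior_sd = prior_sd)
    fit <- fit_nb_glm(counts[i, ], factors[i, ], x, final_alpha[i])
    log2fc[i] <- fit$log2fc
    se[i] <- fit$se
    conv[i] <- fit$converged
  }

  wald <- wald_test_threshold(log2fc, se, theta)
  p <- wald$p_value
  p[degenerate | !conv] <- 1

  res <- tibble(
    position = dataset$positions,
    base_mean = base_mean,
    log2fc = log2fc,
    se = se,
    stat = wald$stat,
    p_value = p,
    local_fdr = NA_real_,
    dispersion = final_alpha
  )
  attr(res, "theta") <- theta
  attr(res, "reference") <- lev[1]
  attr(res, "eta0") <- NA_real_
  class(res) <- c("profdiff_results", class(res))
  if (compute_local_fdr) res <- add_local_fdr(res, lambda = lambda)
  res
}

#' Fill the local-fdr column of a results table
#'
#' @param results A `profdiff_results` table with a `p_value` column.
#' @param lambda Tail start for the null-proportion estimate (default 0.5).
#' @return The results with `local_fdr` filled and attributes `eta0` and
#'   `grenander_fit` set.
#' @export
add_local_fdr <- function(results, lambda = 0.5) {
  lf <- local_fdr(results$p_value, lambda = lambda)
  results$local_fdr <- as.numeric(lf)
  attr(results, "eta0") <- attr(lf, "fit")$eta0
  attr(results, "grenander_fit") <- attr(lf, "fit")
  results
}

#' Write a results table to tab-separated text
#'
#' @param results A `profdiff_results` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  readr::write_tsv(as_tibble(as.data.frame(results)), path, progress = FALSE)
  invisible(path)
}

#' @export
print.profdiff_results <- function(x, ...) {
  cat(sprintf(
    "<profdiff_results> %d positions; theta = %s; reference = %s; eta0 = %s\n",
    nrow(x), format(attr(x, "theta")), attr(x, "reference"),
    ifelse(is.na(attr(x, "eta0")), "unset",
           format(attr(x, "eta0"), digits = 4))
  ))
  NextMethod()
}

#' Tidy a results table
#'
#' @param x A `profdiff_results` object.
#' @param ... Unused.
#' @return A plain tibble of the per-position results.
#' @method tidy profdiff_results
#' @export
tidy.profdiff_results <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a testing run
#'
#' @param x A `profdiff_results` object.
#' @param cutoff Local-fdr significance cutoff (default 0.2).
#' @param ... Unused.
#' @return A one-row tibble: `n_positions`, `n_significant`, `eta0`, `theta`,
#'   `median_dispersion`.
#' @method glance profdiff_results
#' @export
glance.profdiff_results <- function(x, cutoff = 0.2, ...) {
  tibble(
    n_positions = nrow(x),
    n_significant = sum(x$local_fdr < cutoff, na.rm = TRUE),
    eta0 = attr(x, "eta0"),
    theta = attr(x, "theta"),
    median_dispersion = stats::median(x$dispersion)
  )
}
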