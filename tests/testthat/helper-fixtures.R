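# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (sort-and-average, O(n^2) hulls, direct likelihood maximization) so
# they stay independent of the implementation they check.

make_annotation <- function(n_per_cond = 2, upstream = 2, downstream = 2,
                            conditions = c("wt", "mut")) {
  ids <- paste0(rep(conditions, each = n_per_cond), "_",
                rep(seq_len(n_per_cond), length(conditions)))
  validate_sample_annotation(tibble::tibble(
    sample_id = ids,
    condition = rep(conditions, each = n_per_cond),
    chip_source = paste0(ids, "_chip.txt"),
    input_source = paste0(ids, "_input.txt"),
    upstream = upstream,
    downstream = downstream
  ))
}

make_dataset <- function(chip, input, n_per_cond = NULL) {
  n_pos <- nrow(chip)
  if (is.null(n_per_cond)) n_per_cond <- ncol(chip) / 2
  up <- (n_pos - 1) %/% 2
  ann <- make_annotation(n_per_cond, upstream = up,
                         downstream = n_pos - up - 1)
  assemble_dataset(ann, chip, input)
}

# O(n log n)-free brute-force trimmed mean: sort, drop, average
oracle_trimmed_mean <- function(v, trim) {
  k <- floor(trim * length(v))
  s <- sort(v)
  if (k > 0) s <- s[-c(seq_len(k), length(s) - seq_len(k) + 1)]
  mean(s)
}

# O(n^2) least concave majorant of points (x_i, y_i), x increasing:
# greedily walk from the left, always jumping to the point of maximal slope.
oracle_lcm_heights <- function(x, y) {
  knots <- 1
  i <- 1
  while (i < length(x)) {
    slopes <- (y[(i + 1):length(x)] - y[i]) / (x[(i + 1):length(x)] - x[i])
    j <- i + which.max(slopes)
    knots <- c(knots, j)
    i <- j
  }
  list(knots = x[knots], heights = diff(y[knots]) / diff(x[knots]))
}

# evaluate an LCM-derived step density at p (left-continuous)
oracle_step_eval <- function(knots, heights, p) {
  idx <- findInterval(p, knots, left.open = TRUE)
  heights[pmin(pmax(idx, 1), length(heights))]
}

# direct NB log-likelihood maximization over (b0, b1) for the two-group GLM
oracle_nb_glm_lfc <- function(counts, factors, x, alpha) {
  nll <- function(beta) {
    mu <- factors * exp(beta[1] + beta[2] * x)
    -sum(dnbinom(counts, size = 1 / alpha, mu = mu, log = TRUE))
  }
  start <- c(log(mean(counts / factors) + 0.5), 0)
  fit <- optim(start, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  fit$par[2] / log(2)
}

expect_profdiff_error <- function(expr, class) {
  expect_error(expr, class = class)
}
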