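#' Robust mean across biological replicates
#'
#' Huber M-estimate of location: starting at the median, values are
#' winsorized at `m +/- k * s` (with `s = 1.4826 * mad`, the scaled median
#' absolute deviation) and averaged, iterating to convergence. If the scale is
#' zero the median is returned. Down-weights a single aberrant replicate
#' without discarding it entirely.
#'
#' @param values Non-empty numeric vector (one value per replicate).
#' @param k Huber tuning constant (default 1.345, 95% efficiency at the
#'   normal).
#' @return The robust location estimate.
#' @export
robust_position_mean <- function(values, k = 1.345) {
  if (length(values) == 0) {
    pd_abort("robust mean of an empty vector", "profdiff_value_error")
  }
  s <- mad(values)
  if (s == 0) return(median(values))
  m <- median(values)
  for (it in 1:100) {
    w <- pmin(pmax(values, m - k * s), m + k * s)
    m_new <- mean(w)
    if (abs(m_new - m) < 1e-8) return(m_new)
    m <- m_new
  }
  m
}

#' Running-mean smoothing of a profile
#'
#' Centered moving average with windows that shrink symmetrically at the
#' edges, so the output has the same length as the input and constants are
#' preserved everywhere.
#'
#' @param values Position-ordered numeric vector.
#' @param window Odd positive window width (default 51), `<= length(values)`.
#' @return The smoothed vector.
#' @export
smooth_profile <- function(values, window = 51) {
  n <- length(values)
  if (window < 1 || window %% 2 == 0) {
    pd_abort("window must be a positive odd integer",
             "profdiff_validation_error")
  }
  if (window > n) {
    pd_abort("window exceeds profile length", "profdiff_validation_error")
  }
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, values))
  out <- numeric(n)
  for (i in seq_len(n)) {
    hh <- min(h, i - 1L, n - i)
    out[i] <- (cs[i + hh + 1] - cs[i - hh]) / (2 * hh + 1)
  }
  out
}

#' Per-position enrichment plot data
#'
#' The displayed enrichment is the robust mean over replicates of
#' `chip / (scaled input + pseudocount)` per position and condition: the
#' Input-relative signal the tests operate on.
#'
#' @param dataset A `profdiff_dataset`.
#' @param results Optional `profdiff_results` carrying `local_fdr`.
#' @param cutoff Local-fdr cutoff for the `significant` flag (default 0.2).
#' @param window Smoothing window (odd; default 51).
#' @param pseudocount Added to the scaled Input in the ratio.
#' @param k Huber tuning constant for the replicate mean.
#' @return A tibble with columns `position`, `condition`, `enrichment`,
#'   `smoothed`, `significant`.
#' @export
profile_plot_data <- function(dataset, results = NULL, cutoff = 0.2,
                              window = 51, pseudocount = 1, k = 1.345) {
  scaled_input <- vapply(
    seq_len(ncol(dataset$chip)),
    function(j) scale_input_to_chip(dataset$input[, j], dataset$chip[, j]),
    numeric(nrow(dataset$chip))
  )
  ratio <- dataset$chip / (scaled_input + pseudocount)
  cond <- as.character(dataset$annotation$condition)
  window <- min(window, length(dataset$positions))
  if (window %% 2 == 0) window <- window - 1

  out <- map(unique(cond), function(cc) {
    sub <- ratio[, cond == cc, drop = FALSE]
    enr <- unname(apply(sub, 1, robust_position_mean, k = k))
    tibble(
      position = dataset$positions,
      condition = cc,
      enrichment = enr,
      smoothed = smooth_profile(enr, window)
    )
  }) |> bind_rows()

  sig <- tibble(position = dataset$positions, significant = FALSE)
  if (!is.null(results) && nrow(results) > 0) {
    if (!"local_fdr" %in% names(results)) {
      pd_abort("results lack a local_fdr column", "profdiff_validation_error")
    }
    sig <- tibble(
      position = results$position,
      significant = !is.na(results$local_fdr) & results$local_fdr < cutoff
    )
  }
  left_join(out, sig, by = "position") |>
    mutate(significant = !is.na(.data$significant) & .data$significant)
}

# internal: shared ggplot skeleton
enrichment_ggplot <- function(data, y, highlight) {
  gg <- ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$position, y = .data[[y]],
                 colour = .data$condition)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to anchor (bp)",
                  y = "enrichment (ChIP / scaled Input)",
                  colour = "condition") +
    ggplot2::theme_minimal()
  if (highlight && any(data$significant)) {
    gg <- gg + ggplot2::geom_point(
      data = dplyr::filter(data, .data$significant),
      ggplot2::aes(x = .data$position, y = .data[[y]]),
      inherit.aes = FALSE, colour = "black", size = 0.6
    )
  }
  gg
}

# internal: render to PNG and SVG next to `out`
write_plot_files <- function(gg, out) {
  base <- sub("\\.(png|svg)$", "", out)
  paths <- paste0(base, c(".png", ".svg"))
  for (pth in paths) {
    ok <- tryCatch({
      ggplot2::ggsave(pth, gg, width = 7, height = 4, dpi = 150)
      TRUE
    }, error = function(e) FALSE)
    if (!ok && grepl("\\.png$", pth)) {
      pd_abort(paste0("cannot write plot file: ", pth), "profdiff_io_error")
    }
  }
  paths[file.exists(paths)]
}

#' Plot smoothed enrichment profiles per condition
#'
#' @inheritParams profile_plot_data
#' @param out Image path (`.png`; an `.svg` sibling is written too).
#' @return The plot-data tibble, invisibly, with attribute `files`.
#' @export
plot_profiles <- function(dataset, results = NULL, cutoff = 0.2, out,
                          window = 51, pseudocount = 1) {
  data <- profile_plot_data(dataset, results, cutoff, window, pseudocount)
  gg <- enrichment_ggplot(data, "smoothed", highlight = FALSE)
  files <- write_plot_files(gg, out)
  attr(data, "files") <- files
  invisible(data)
}

#' Plot unsmoothed profiles with significant positions highlighted
#'
#' @inheritParams profile_plot_data
#' @param out Image path (`.png`; an `.svg` sibling is written too).
#' @return The plot-data tibble, invisibly, with attribute `files`.
#' @export
plot_significance <- function(results, dataset, cutoff = 0.2, out,
                              pseudocount = 1) {
  if (is.null(results) || !"local_fdr" %in% names(results)) {
    pd_abort("results with a local_fdr column are required",
             "profdiff_validation_error")
  }
  data <- profile_plot_data(dataset, results, cutoff, window = 1,
                            pseudocount = pseudocount)
  gg <- enrichment_ggplot(data, "enrichment", highlight = TRUE)
  files <- write_plot_files(gg, out)
  attr(data, "files") <- files
  invisible(data)
}

#' Autoplot a results table over its dataset
#'
#' @param object A `profdiff_results` object.
#' @param dataset The `profdiff_dataset` the results came from.
#' @param kind `"profiles"` (smoothed) or `"significance"` (unsmoothed with
#'   highlighted calls).
#' @param cutoff Local-fdr cutoff (default 0.2).
#' @param window Smoothing window for `kind = "profiles"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot profdiff_results
#' @export
autoplot.profdiff_results <- function(object, dataset,
                                      kind = c("significance", "profiles"),
                                      cutoff = 0.2, window = 51, ...) {
  kind <- match.arg(kind)
  if (kind == "profiles") {
    data <- profile_plot_data(dataset, object, cutoff, window)
    enrichment_ggplot(data, "smoothed", highlight = FALSE)
  } else {
    data <- profile_plot_data(dataset, object, cutoff, window = 1)
    enrichment_ggplot(data, "enrichment", highlight = TRUE)
  }
}
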