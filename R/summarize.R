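#' Drop features with very low total counts
#'
#' Features whose total count over all positions falls below `min_total` are
#' removed before summarization; they contribute mostly zeros and would drag
#' the trimmed mean toward 0. Feature order is preserved.
#'
#' @param table A `profdiff_counts` tibble.
#' @param min_total Non-negative integer threshold on the per-feature total.
#' @return The filtered `profdiff_counts` tibble.
#' @export
filter_low_count_features <- function(table, min_total = 1) {
  totals <- rowSums(counts_matrix(table))
  keep <- totals >= min_total
  if (!any(keep)) {
    pd_abort(
      sprintf("no features left at min_total = %s; lower the threshold",
              format(min_total)),
      "profdiff_empty_result_error"
    )
  }
  out <- table[keep, ]
  attr(out, "positions") <- counts_positions(table)
  class(out) <- class(table)
  out
}

#' Symmetrically trimmed mean
#'
#' Drops `floor(trim * n)` values from each tail after sorting and averages
#' the rest; robust against the heavy right tail typical of feature counts.
#'
#' @param values Non-empty numeric vector.
#' @param trim Fraction in `[0, 0.5)` to drop from each tail.
#' @return The trimmed mean as a single number.
#' @export
trimmed_mean <- function(values, trim = 0.15) {
  n <- length(values)
  if (n == 0) pd_abort("trimmed_mean of an empty vector", "profdiff_value_error")
  if (trim < 0 || trim >= 0.5) {
    pd_abort("trim must be in [0, 0.5)", "profdiff_validation_error")
  }
  k <- floor(trim * n)
  if (k == 0) return(mean(values))
  mean(sort(values)[(k + 1):(n - k)])
}

#' Summarize a feature count table into a raw metafeature profile
#'
#' The single-sample summarization: low-count features are filtered out, a
#' trimmed mean of the retained counts is taken at every position, and the
#' positionwise means are multiplied by the number of retained features. With
#' `trim = 0` and `min_total = 0` this is exactly the column sum.
#'
#' @param table A `profdiff_counts` tibble.
#' @param min_total Feature-total filter threshold (default 1: drop all-zero
#'   features only).
#' @param trim Trim fraction per tail (default 0.15).
#' @return A tibble with columns `position` and `value`, carrying an
#'   `n_retained` attribute (features surviving the filter).
#' @export
summarize_counts_per_position <- function(table, min_total = 1, trim = 0.15) {
  filtered <- filter_low_count_features(table, min_total)
  m <- counts_matrix(filtered)
  n_retained <- nrow(m)
  k <- floor(trim * n_retained)
  # sum-based form so that trim = 0 reproduces the column sum exactly
  values <- apply(m, 2, function(col) {
    kept <- if (k > 0) sort(col)[(k + 1):(n_retained - k)] else col
    sum(kept) * n_retained / length(kept)
  })
  out <- tibble(position = counts_positions(filtered),
                value = unname(values))
  attr(out, "n_retained") <- n_retained
  out
}
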