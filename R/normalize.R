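#' Match an Input profile's library size to its ChIP counterpart
#'
#' Rescales the Input metafeature profile so its total equals the total of
#' the paired ChIP profile. This removes the global sequencing-depth
#' difference between the two libraries; what remains in the scaled Input is
#' the position-specific bias (chromatin solubility, enzyme accessibility,
#' PCR amplification) shared with the ChIP sample.
#'
#' @param input_profile,chip_profile Non-negative numeric vectors of equal
#'   length (counts per position).
#' @return The scaled Input vector; its sum equals `sum(chip_profile)`.
#' @export
scale_input_to_chip <- function(input_profile, chip_profile) {
  if (length(input_profile) != length(chip_profile)) {
    pd_abort("Input and ChIP profiles must have the same length",
             "profdiff_dimension_error")
  }
  total_in <- sum(input_profile)
  if (total_in <= 0) {
    pd_abort("Input profile has zero total count; cannot scale",
             "profdiff_normalization_error")
  }
  input_profile * (sum(chip_profile) / total_in)
}

#' Build position-specific normalization factors from scaled Input profiles
#'
#' The scaled Input counts, made strictly positive by a pseudocount, are the
#' per-position, per-sample normalization factors of the count model. With
#' `center = TRUE` (default) each position's row of factors is divided by its
#' geometric mean, so factors carry only relative within-position information
#' and do not distort the count scale entering dispersion estimation — the
#' standard contract for normalization factors in NB count models.
#'
#' @param scaled_inputs Positions x samples matrix of scaled Input values.
#' @param pseudocount Non-negative value added before use (default 1);
#'   required > 0 wherever the scaled Input has zeros.
#' @param center Logical; apply row-wise geometric-mean centering.
#' @return A positions x samples matrix of strictly positive factors with
#'   attribute `centered`.
#' @export
build_normalization_factors <- function(scaled_inputs, pseudocount = 1,
                                        center = TRUE) {
  m <- as.matrix(scaled_inputs)
  if (any(!is.finite(m))) {
    pd_abort("scaled Input values must all be finite",
             "profdiff_validation_error")
  }
  factors <- m + pseudocount
  if (any(factors <= 0)) {
    pd_abort(
      "normalization factors must be strictly positive; use pseudocount > 0",
      "profdiff_positivity_error"
    )
  }
  if (center) {
    gm <- exp(rowMeans(log(factors)))
    factors <- factors / gm
  }
  attr(factors, "centered") <- center
  factors
}

# internal: scale every sample's Input to its own ChIP and build the factors
dataset_normalization_factors <- function(dataset, pseudocount = 1,
                                          center = TRUE) {
  scaled <- vapply(
    seq_len(ncol(dataset$chip)),
    function(j) scale_input_to_chip(dataset$input[, j], dataset$chip[, j]),
    numeric(nrow(dataset$chip))
  )
  colnames(scaled) <- colnames(dataset$chip)
  build_normalization_factors(scaled, pseudocount = pseudocount,
                              center = center)
}
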