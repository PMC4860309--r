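#' Configuration for a synthetic profile experiment
#'
#' Describes replicated ChIP/Input metafeature counts around an anchor with a
#' known region of true differential enrichment. Input counts are NB with mean
#' `baseline * input_bias`; ChIP counts are NB with that mean times
#' `2^effect_lfc` inside the effect window for the non-reference condition.
#' Variance is `mu + alpha * mu^2`, matching the testing model exactly.
#'
#' @param n_positions Number of positions; the axis is centered on 0
#'   (`upstream = floor((n-1)/2)`).
#' @param samples_per_condition Replicates per condition (two conditions,
#'   `control` as reference and `treatment`).
#' @param baseline Either a single positive mean or a full per-position
#'   vector; default a flat 50 plus a Gaussian-shaped peak can be requested
#'   via `peak_height`/`peak_width` (centered at position 0).
#' @param peak_height,peak_width Optional peak added to a scalar baseline
#'   (height in counts at the summit, width = SD in bp); 0 disables.
#' @param input_bias Per-position multiplicative bias shared by ChIP and
#'   Input (scalar or vector; default 1).
#' @param dispersion NB dispersion alpha (> 0).
#' @param effect_window Integer vector `c(start, end)` in relative
#'   coordinates, or `NULL` for a null experiment.
#' @param effect_lfc True log2 fold change inside the window.
#' @param n_features Features for per-feature table output.
#' @param shared_input Use one Input draw per condition for all its samples
#'   (mirrors designs with a single whole-cell-extract Input).
#' @param seed Mandatory integer seed.
#' @return A `profdiff_sim_config` list.
#' @export
simulation_config <- function(n_positions = 500, samples_per_condition = 3,
                              baseline = 50, peak_height = 0, peak_width = 50,
                              input_bias = 1, dispersion = 0.1,
                              effect_window = NULL, effect_lfc = 0,
                              n_features = 100, shared_input = FALSE,
                              seed) {
  if (missing(seed)) pd_abort("seed is mandatory", "profdiff_config_error")
  upstream <- (n_positions - 1L) %/% 2L
  positions <- seq.int(-upstream, n_positions - upstream - 1L)
  base <- if (length(baseline) == 1) {
    baseline + peak_height * exp(-positions^2 / (2 * peak_width^2))
  } else baseline
  bias <- if (length(input_bias) == 1) rep(input_bias, n_positions) else
    input_bias
  if (length(base) != n_positions || length(bias) != n_positions) {
    pd_abort("baseline/input_bias must be scalar or length n_positions",
             "profdiff_config_error")
  }
  if (any(base * bias <= 0)) {
    pd_abort("all simulated means must be positive", "profdiff_config_error")
  }
  if (!is.null(effect_window)) {
    if (length(effect_window) != 2 || effect_window[1] > effect_window[2] ||
        effect_window[1] < min(positions) ||
        effect_window[2] > max(positions)) {
      pd_abort("effect_window must be c(start, end) within the position range",
               "profdiff_config_error")
    }
  }
  structure(
    list(
      positions = positions, upstream = upstream,
      downstream = max(positions),
      samples_per_condition = samples_per_condition,
      baseline = base, input_bias = bias, dispersion = dispersion,
      effect_window = effect_window, effect_lfc = effect_lfc,
      n_features = n_features, shared_input = shared_input,
      seed = as.integer(seed)
    ),
    class = "profdiff_sim_config"
  )
}

#' Simulate a replicated ChIP/Input profile dataset with known truth
#'
#' @param config A `profdiff_sim_config` (see [simulation_config()]).
#' @return A list of class `profdiff_simulation`: `dataset` (a
#'   `profdiff_dataset`), `truth` (tibble with `position`, `differential`,
#'   `true_lfc`), and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "profdiff_sim_config"))
  set.seed(config$seed)
  n_pos <- length(config$positions)
  reps <- config$samples_per_condition
  conditions <- rep(c("control", "treatment"), each = reps)
  sample_ids <- paste0(conditions, "_", rep(seq_len(reps), 2))

  effect <- rep(1, n_pos)
  in_window <- rep(FALSE, n_pos)
  if (!is.null(config$effect_window)) {
    in_window <- config$positions >= config$effect_window[1] &
      config$positions <= config$effect_window[2]
    effect[in_window] <- 2^config$effect_lfc
  }

  mu_input <- config$baseline * config$input_bias
  size <- 1 / config$dispersion
  draw <- function(mu) rnbinom(n_pos, size = size, mu = mu)

  input <- matrix(0L, n_pos, 2 * reps)
  chip <- matrix(0L, n_pos, 2 * reps)
  for (j in seq_len(2 * reps)) {
    mu_chip <- mu_input * (if (conditions[j] == "treatment") effect else 1)
    chip[, j] <- draw(mu_chip)
    if (!config$shared_input || j %% reps == 1 || reps == 1) {
      input_j <- draw(mu_input)
    }
    input[, j] <- input_j
  }
  colnames(chip) <- colnames(input) <- sample_ids

  ann <- validate_sample_annotation(tibble(
    sample_id = sample_ids,
    condition = conditions,
    chip_source = paste0(sample_ids, "_chip.txt"),
    input_source = paste0(sample_ids, "_input.txt"),
    upstream = config$upstream,
    downstream = config$downstream
  ))
  structure(
    list(
      dataset = assemble_dataset(ann, chip, input),
      truth = tibble(
        position = config$positions,
        differential = in_window & config$effect_lfc != 0,
        true_lfc = ifelse(in_window, config$effect_lfc, 0)
      ),
      config = config
    ),
    class = "profdiff_simulation"
  )
}

#' Simulate per-feature count tables
#'
#' Distributes each sample's expected per-position count over features via
#' feature-specific lognormal weights (so feature totals are heavy-tailed, as
#' in real data) and draws NB counts per feature and position. Summing over
#' features recovers the metafeature-level expectation in distribution.
#'
#' @param config A `profdiff_sim_config`.
#' @return A list with `chip_tables` and `input_tables` (named lists of
#'   `profdiff_counts`, one per sample), `annotation`, `truth`, and `config`.
#' @export
simulate_feature_tables <- function(config) {
  stopifnot(inherits(config, "profdiff_sim_config"))
  if (config$n_features < 1) {
    pd_abort("n_features must be >= 1", "profdiff_config_error")
  }
  set.seed(config$seed)
  n_pos <- length(config$positions)
  reps <- config$samples_per_condition
  conditions <- rep(c("control", "treatment"), each = reps)
  sample_ids <- paste0(conditions, "_", rep(seq_len(reps), 2))

  w <- rlnorm(config$n_features, meanlog = 0, sdlog = 1)
  w <- w / sum(w)
  feature_ids <- sprintf("feature_%03d", seq_len(config$n_features))

  effect <- rep(1, n_pos)
  if (!is.null(config$effect_window)) {
    idx <- config$positions >= config$effect_window[1] &
      config$positions <= config$effect_window[2]
    effect[idx] <- 2^config$effect_lfc
  }
  mu_input <- config$baseline * config$input_bias
  size <- 1 / config$dispersion

  draw_table <- function(mu_pos) {
    m <- matrix(
      rnbinom(config$n_features * n_pos, size = size,
              mu = outer(w * config$n_features, mu_pos / config$n_features)),
      nrow = config$n_features
    )
    feature_count_table(feature_ids, m, config$upstream, config$downstream)
  }

  chip_tables <- setNames(vector("list", length(sample_ids)), sample_ids)
  input_tables <- chip_tables
  for (j in seq_along(sample_ids)) {
    mu_chip <- mu_input * (if (conditions[j] == "treatment") effect else 1)
    chip_tables[[j]] <- draw_table(mu_chip)
    input_tables[[j]] <- draw_table(mu_input)
  }

  ann <- validate_sample_annotation(tibble(
    sample_id = sample_ids, condition = conditions,
    chip_source = paste0(sample_ids, "_chip.txt"),
    input_source = paste0(sample_ids, "_input.txt"),
    upstream = config$upstream, downstream = config$downstream
  ))
  list(chip_tables = chip_tables, input_tables = input_tables,
       annotation = ann,
       truth = simulate_dataset(config)$truth, config = config)
}

#' Score test results against simulation truth
#'
#' @param results A `profdiff_results` table with `local_fdr`.
#' @param truth Truth tibble from [simulate_dataset()] (columns `position`,
#'   `differential`).
#' @param cutoff Local-fdr cutoff defining the called set (default 0.2).
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `empirical_fdr`
#'   (`fp / max(1, fp + tp)`), `power`.
#' @export
evaluate_against_truth <- function(results, truth, cutoff = 0.2) {
  if (!identical(as.integer(results$position), as.integer(truth$position))) {
    pd_abort("results and truth position axes differ",
             "profdiff_validation_error")
  }
  called <- !is.na(results$local_fdr) & results$local_fdr < cutoff
  tp <- sum(called & truth$differential)
  fp <- sum(called & !truth$differential)
  fn <- sum(!called & truth$differential)
  tn <- sum(!called & !truth$differential)
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    empirical_fdr = fp / max(1, fp + tp),
    power = if (tp + fn > 0) tp / (tp + fn) else NA_real_
  )
}

#' Write simulated data as importable fixture files
#'
#' Writes the annotation CSV, per-sample feature count tables (ChIP and
#' Input), and the truth table into a directory, so simulated data exercises
#' the full import path.
#'
#' @param sim Output of [simulate_feature_tables()].
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
write_simulated_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- as_tibble(sim$annotation)
  ann$condition <- as.character(ann$condition)
  for (id in ann$sample_id) {
    write_feature_count_table(sim$chip_tables[[id]],
                              file.path(dir, paste0(id, "_chip.txt")))
    write_feature_count_table(sim$input_tables[[id]],
                              file.path(dir, paste0(id, "_input.txt")))
  }
  readr::write_csv(ann, file.path(dir, "annotation.csv"), progress = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
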