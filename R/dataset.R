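#' Assemble a metafeature profile dataset
#'
#' Bundles paired ChIP and Input metafeature profiles (positions x samples)
#' with their sample annotation. This is the unit the testing pipeline
#' operates on. Non-integer profile values are rounded half-up to integers,
#' since the downstream count model requires integer observations.
#'
#' @param annotation A `profdiff_annotation` (see [read_sample_annotation()]).
#' @param chip,input Named lists (or matrices with sample columns) of
#'   per-sample position vectors on the annotation's position axis; list names
#'   or column names must match `annotation$sample_id` where present.
#' @return An object of class `profdiff_dataset`: list with elements
#'   `chip` and `input` (positions x samples integer matrices), `positions`,
#'   and `annotation`.
#' @export
assemble_dataset <- function(annotation, chip, input) {
  annotation <- validate_sample_annotation(annotation)
  positions <- annotation_positions(annotation)
  chip <- profiles_to_matrix(chip, positions, annotation$sample_id, "chip")
  input <- profiles_to_matrix(input, positions, annotation$sample_id, "input")
  structure(
    list(chip = chip, input = input, positions = positions,
         annotation = annotation),
    class = "profdiff_dataset"
  )
}

# internal: coerce per-sample profiles to an integer positions x samples matrix
profiles_to_matrix <- function(profiles, positions, sample_ids, what) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    lens <- lengths(profiles)
    bad <- which(lens != length(positions))
    if (length(bad) > 0) {
      nm <- names(profiles)[bad[1]] %||% as.character(bad[1])
      pd_abort(
        sprintf("%s profile for sample '%s' has %d positions; expected %d",
                what, nm, lens[bad[1]], length(positions)),
        "profdiff_dimension_error"
      )
    }
    m <- do.call(cbind, profiles)
  } else {
    m <- as.matrix(profiles)
    if (nrow(m) != length(positions)) {
      pd_abort(
        sprintf("%s matrix has %d rows; expected %d positions",
                what, nrow(m), length(positions)),
        "profdiff_dimension_error"
      )
    }
  }
  if (ncol(m) != length(sample_ids)) {
    pd_abort(
      sprintf("%s data has %d samples; annotation has %d",
              what, ncol(m), length(sample_ids)),
      "profdiff_dimension_error"
    )
  }
  if (!is.null(colnames(m))) m <- m[, sample_ids, drop = FALSE]
  if (any(!is.finite(m)) || any(m < 0)) {
    pd_abort(paste0(what, " profiles must be finite and non-negative"),
             "profdiff_validation_error")
  }
  # round half-up (not R's round-half-even): the count model needs integers
  matrix(as.integer(floor(m + 0.5)), nrow = nrow(m),
         dimnames = list(as.character(positions), sample_ids))
}

#' Import a full dataset from a sample annotation
#'
#' Reads the per-sample ChIP and Input tables named in the annotation,
#' summarizes feature-level tables into metafeature profiles, and assembles
#' the dataset. Files ending in the matrix dialect (single profile column) are
#' detected by shape: a table with exactly the window's position columns and
#' multiple feature rows is summarized; use `format = "matrices"` to read
#' positions x 1 profile files directly.
#'
#' @param annotation A `profdiff_annotation`, or path to the annotation CSV.
#' @param format `"feature-tables"` (summarize per-feature counts) or
#'   `"matrices"` (files already hold one metafeature profile per sample:
#'   two columns, position and value, tab-separated).
#' @param min_total,trim Summarization parameters, see
#'   [summarize_counts_per_position()].
#' @param base_dir Directory against which relative source paths are resolved.
#' @return A `profdiff_dataset`; attribute `import_report` holds per-sample
#'   retained-feature counts for feature-table imports.
#' @export
import_dataset <- function(annotation, format = c("feature-tables", "matrices"),
                           min_total = 1, trim = 0.15, base_dir = ".") {
  format <- match.arg(format)
  if (is.character(annotation)) {
    annotation <- read_sample_annotation(annotation)
  }
  annotation <- validate_sample_annotation(annotation)
  up <- annotation$upstream[1]
  down <- annotation$downstream[1]
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base_dir, p))

  read_one <- function(path) {
    if (format == "matrices") {
      prof <- readr::read_tsv(resolve(path), show_col_types = FALSE,
                              progress = FALSE)
      list(values = prof[[2]], n_retained = NA_integer_)
    } else {
      tbl <- read_feature_count_table(resolve(path), up, down)
      prof <- summarize_counts_per_position(tbl, min_total = min_total,
                                            trim = trim)
      list(values = prof$value, n_retained = attr(prof, "n_retained"))
    }
  }

  chip <- map(annotation$chip_source, read_one)
  input <- map(annotation$input_source, read_one)
  ds <- assemble_dataset(
    annotation,
    setNames(map(chip, "values"), annotation$sample_id),
    setNames(map(input, "values"), annotation$sample_id)
  )
  attr(ds, "import_report") <- tibble(
    sample_id = annotation$sample_id,
    chip_features_retained = map_int(chip, "n_retained"),
    input_features_retained = map_int(input, "n_retained")
  )
  ds
}

#' @export
print.profdiff_dataset <- function(x, ...) {
  cat("<profdiff_dataset>\n")
  cat(sprintf("  %d positions (%d to %d), %d samples\n",
              length(x$positions), min(x$positions), max(x$positions),
              ncol(x$chip)))
  cat("  conditions:",
      paste(sprintf("%s (n=%d)", levels(x$annotation$condition),
                    table(x$annotation$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a profile dataset into long form
#'
#' @param x A `profdiff_dataset`.
#' @param ... Unused.
#' @return A tibble with columns `position`, `sample_id`, `condition`,
#'   `chip`, `input`.
#' @method tidy profdiff_dataset
#' @export
tidy.profdiff_dataset <- function(x, ...) {
  long <- function(m, name) {
    as_tibble(m, .name_repair = "minimal") |>
      mutate(position = x$positions) |>
      tidyr::pivot_longer(-"position", names_to = "sample_id",
                          values_to = name)
  }
  long(x$chip, "chip") |>
    left_join(long(x$input, "input"), by = c("position", "sample_id")) |>
    left_join(select(as_tibble(x$annotation), "sample_id", "condition"),
              by = "sample_id") |>
    select("position", "sample_id", "condition", "chip", "input")
}

#' Write a dataset to a plain-text archive directory
#'
#' The archive is a directory of tab-separated matrices (`chip.tsv`,
#' `input.tsv`), the annotation CSV, and a JSON manifest — diff-able and
#' language-neutral.
#'
#' @param dataset A `profdiff_dataset`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mat <- function(m, f) {
    readr::write_tsv(
      bind_cols(tibble(position = dataset$positions),
                as_tibble(m, .name_repair = "minimal")),
      file.path(dir, f), progress = FALSE
    )
  }
  write_mat(dataset$chip, "chip.tsv")
  write_mat(dataset$input, "input.tsv")
  ann <- as_tibble(dataset$annotation)
  ann$condition <- as.character(ann$condition)
  readr::write_csv(ann, file.path(dir, "annotation.csv"), progress = FALSE)
  manifest <- list(
    format = "profdiff-dataset",
    version = 1L,
    n_positions = length(dataset$positions),
    n_samples = ncol(dataset$chip),
    files = list(chip = "chip.tsv", input = "input.tsv",
                 annotation = "annotation.csv")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset archive written by [write_dataset()]
#'
#' @param dir Archive directory.
#' @return A `profdiff_dataset`.
#' @export
read_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    pd_abort(paste0("not a dataset archive (no manifest.json): ", dir),
             "profdiff_io_error")
  }
  manifest <- jsonlite::read_json(manifest_path)
  ann <- read_sample_annotation(file.path(dir, manifest$files$annotation))
  read_mat <- function(f) {
    tbl <- readr::read_tsv(file.path(dir, f), show_col_types = FALSE,
                           progress = FALSE)
    as.matrix(tbl[-1])
  }
  assemble_dataset(ann, read_mat(manifest$files$chip),
                   read_mat(manifest$files$input))
}
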