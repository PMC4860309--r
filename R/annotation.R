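#' Read and validate a sample annotation table
#'
#' The annotation table drives an analysis: one row per sample, giving the
#' experimental condition, the paths of the ChIP and Input count tables, and
#' the extent of the window around the anchor (upstream/downstream, in bp).
#' The window must be identical across samples because all profiles share one
#' relative-position axis.
#'
#' @param path Path to a CSV file with columns `sample_id`, `condition`,
#'   `chip_source`, `input_source`, `upstream`, `downstream`.
#' @return A tibble of class `profdiff_annotation` with the columns above;
#'   `upstream`/`downstream` are integers and `condition` is a factor.
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "sample_id,condition,chip_source,input_source,upstream,downstream",
#'   "wt_1,wt,chip1.txt,input1.txt,1000,1500",
#'   "mut_1,mut,chip2.txt,input2.txt,1000,1500"
#' ), csv)
#' read_sample_annotation(csv)
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) {
    pd_abort(paste0("annotation file not found: ", path), "profdiff_io_error")
  }
  ann <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_annotation(ann)
}

#' Validate an in-memory sample annotation
#'
#' @param annotation A data frame with the annotation columns (see
#'   [read_sample_annotation()]).
#' @return The validated annotation as a `profdiff_annotation` tibble.
#' @export
validate_sample_annotation <- function(annotation) {
  required <- c("sample_id", "condition", "chip_source", "input_source",
                "upstream", "downstream")
  missing <- setdiff(required, names(annotation))
  if (length(missing) > 0) {
    pd_abort(
      paste0("annotation is missing required column(s): ",
             paste(missing, collapse = ", ")),
      "profdiff_schema_error"
    )
  }
  ann <- as_tibble(annotation)
  ann$sample_id <- as.character(ann$sample_id)
  if (anyDuplicated(ann$sample_id) > 0) {
    dup <- unique(ann$sample_id[duplicated(ann$sample_id)])
    pd_abort(
      paste0("duplicate sample_id value(s): ", paste(dup, collapse = ", ")),
      "profdiff_validation_error"
    )
  }
  up <- suppressWarnings(as.integer(ann$upstream))
  down <- suppressWarnings(as.integer(ann$downstream))
  if (anyNA(up) || anyNA(down) || any(up < 0) || any(down < 0)) {
    pd_abort("upstream/downstream must be non-negative integers",
             "profdiff_validation_error")
  }
  if (length(unique(up)) != 1 || length(unique(down)) != 1) {
    pd_abort(
      "upstream and downstream must be identical across all samples",
      "profdiff_validation_error"
    )
  }
  ann$upstream <- up
  ann$downstream <- down
  ann$condition <- factor(as.character(ann$condition))
  class(ann) <- c("profdiff_annotation", class(ann))
  ann
}

# internal: the shared relative-position axis of an annotation set
annotation_positions <- function(annotation) {
  seq.int(-annotation$upstream[1], annotation$downstream[1])
}

# internal: require exactly two condition levels before testing
check_two_conditions <- function(condition) {
  lev <- levels(factor(condition))
  if (length(lev) < 2) {
    pd_abort("at least two distinct conditions are required for testing",
             "profdiff_design_error")
  }
  if (length(lev) > 2) {
    pd_abort(
      paste0("only two-condition designs are supported; got levels: ",
             paste(lev, collapse = ", ")),
      "profdiff_design_error"
    )
  }
  lev
}
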