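#' Read a per-feature count table
#'
#' Count tables are tab-separated text: the first column holds feature
#' identifiers (genes, transcripts), the remaining columns hold the counts at
#' each position relative to the anchor, from `-upstream` to `+downstream`
#' inclusive. A header row of relative positions is accepted but not required;
#' the declared window defines the position axis either way.
#'
#' @param path Path to the tab-separated file.
#' @param upstream,downstream Non-negative integers; the window extent in bp.
#' @param header Logical; does the file carry a header row of positions?
#' @return A tibble of class `profdiff_counts`: column `feature` plus one
#'   integer column per relative position (names are the positions).
#' @export
read_feature_count_table <- function(path, upstream, downstream,
                                     header = TRUE) {
  if (!file.exists(path)) {
    pd_abort(paste0("count table not found: ", path), "profdiff_io_error")
  }
  raw <- readr::read_tsv(path, col_names = header, show_col_types = FALSE,
                         progress = FALSE)
  # first column is the feature id whatever its header says
  raw[[1]] <- as.character(raw[[1]])
  feature_count_table(raw[[1]], as.matrix(raw[-1]), upstream, downstream)
}

#' Construct a feature count table from a matrix
#'
#' @param feature_ids Character vector of unique feature identifiers.
#' @param counts Numeric matrix, features in rows and relative positions in
#'   columns, length `upstream + downstream + 1`.
#' @param upstream,downstream Window extent in bp.
#' @return A `profdiff_counts` tibble.
#' @export
feature_count_table <- function(feature_ids, counts, upstream, downstream) {
  upstream <- as.integer(upstream)
  downstream <- as.integer(downstream)
  positions <- seq.int(-upstream, downstream)
  counts <- as.matrix(counts)
  if (ncol(counts) != length(positions)) {
    pd_abort(
      sprintf(
        "count table has %d position columns but the declared window (-%d..+%d) needs %d",
        ncol(counts), upstream, downstream, length(positions)
      ),
      "profdiff_dimension_error"
    )
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    pd_abort(
      sprintf(
        "counts must be non-negative integers; first offending cell at feature row %d, position %d",
        bad[1, 1], positions[bad[1, 2]]
      ),
      "profdiff_parse_error"
    )
  }
  storage.mode(counts) <- "integer"
  tbl <- as_tibble(counts, .name_repair = "minimal")
  names(tbl) <- as.character(positions)
  tbl <- bind_cols(tibble(feature = as.character(feature_ids)), tbl)
  attr(tbl, "positions") <- positions
  class(tbl) <- c("profdiff_counts", class(tbl))
  tbl
}

#' Write a feature count table to tab-separated text
#'
#' Inverse of [read_feature_count_table()]: header row of relative positions,
#' first column `feature`.
#'
#' @param table A `profdiff_counts` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_count_table <- function(table, path) {
  readr::write_tsv(as_tibble(unclass_counts(table)), path, progress = FALSE)
  invisible(path)
}

# internal: position axis of a count table
counts_positions <- function(table) {
  pos <- attr(table, "positions")
  if (is.null(pos)) pos <- as.integer(names(table)[-1])
  pos
}

# internal: counts as a plain matrix (features x positions)
counts_matrix <- function(table) {
  m <- as.matrix(table[-1])
  rownames(m) <- table$feature
  m
}

unclass_counts <- function(table) {
  class(table) <- setdiff(class(table), "profdiff_counts")
  table
}
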