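#' Midpoint of a DNA fragment
#'
#' Profiles are built from the middle position of the genomic interval a
#' sequenced fragment delimits. For even-length fragments the lower of the two
#' central bases is used (integer division), so the result is deterministic.
#'
#' @param start,end 1-based inclusive fragment coordinates, `end >= start`.
#'   Vectorized.
#' @return Integer midpoint(s), `floor((start + end) / 2)`.
#' @examples
#' fragment_midpoint(100, 299) # 199
#' @export
fragment_midpoint <- function(start, end) {
  if (any(end < start)) {
    pd_abort("invalid fragment: end < start", "profdiff_validation_error")
  }
  as.integer((as.numeric(start) + as.numeric(end)) %/% 2)
}

#' Position of a midpoint relative to an anchor
#'
#' Strand-aware transform into the profile coordinate system: position 0 is
#' the anchor base itself, positive positions run downstream in the anchor's
#' orientation. Midpoints outside `[-upstream, downstream]` give `NA`.
#'
#' @param midpoint 1-based genomic coordinate(s) of fragment midpoints.
#' @param anchor_pos 1-based anchor coordinate (e.g. the TSS base).
#' @param strand `"+"` or `"-"`.
#' @param upstream,downstream Window extent in bp.
#' @return Integer relative position(s), `NA` when out of window.
#' @export
relative_position <- function(midpoint, anchor_pos, strand, upstream,
                              downstream) {
  rel <- ifelse(strand == "-", anchor_pos - midpoint, midpoint - anchor_pos)
  rel <- as.integer(rel)
  rel[rel < -upstream | rel > downstream] <- NA_integer_
  rel
}

#' Extract anchor coordinates from a GFF/GTF annotation
#'
#' Anchors are the strand-aware 5' ends of records of a chosen feature type
#' (the TSS, for `type = "gene"` in most annotations).
#'
#' @param path GFF3 or GTF file.
#' @param feature_type Records whose `type` matches are used (default
#'   `"gene"`).
#' @param id_attribute Attribute column used as the feature identifier;
#'   tried in order until one exists (default `ID`, then `gene_id`, `Name`).
#' @return A tibble with columns `feature_id`, `chrom`, `position`, `strand`.
#' @export
read_anchors_gff <- function(path, feature_type = "gene",
                             id_attribute = c("ID", "gene_id", "Name")) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    pd_abort("rtracklayer is required for GFF import", "profdiff_io_error")
  }
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[as.character(gr$type) %in% feature_type]
  }
  if (length(gr) == 0) {
    pd_abort(paste0("no records of type ", feature_type, " in ", path),
             "profdiff_validation_error")
  }
  meta <- S4Vectors::mcols(gr)
  id_col <- id_attribute[id_attribute %in% names(meta)][1]
  ids <- if (!is.na(id_col)) as.character(meta[[id_col]]) else
    paste0("anchor_", seq_along(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  anchors <- tibble(
    feature_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    position = ifelse(strand == "-", BiocGenerics::end(gr),
                      BiocGenerics::start(gr)),
    strand = strand
  )
  validate_anchors(anchors)
}

#' Validate an anchor table
#'
#' @param anchors Data frame with columns `feature_id`, `chrom`, `position`,
#'   `strand`.
#' @return The validated anchor tibble.
#' @export
validate_anchors <- function(anchors) {
  required <- c("feature_id", "chrom", "position", "strand")
  missing <- setdiff(required, names(anchors))
  if (length(missing) > 0) {
    pd_abort(paste0("anchor table missing column(s): ",
                    paste(missing, collapse = ", ")),
             "profdiff_schema_error")
  }
  anchors <- as_tibble(anchors)
  if (any(anchors$position < 1)) {
    pd_abort("anchor positions must be >= 1", "profdiff_validation_error")
  }
  if (!all(anchors$strand %in% c("+", "-"))) {
    pd_abort("anchor strand must be '+' or '-'", "profdiff_validation_error")
  }
  if (anyDuplicated(anchors$feature_id) > 0) {
    pd_abort("anchor feature_id values must be unique",
             "profdiff_validation_error")
  }
  anchors
}

#' Count fragment midpoints around anchors from SAM/BAM alignments
#'
#' Builds the per-feature count table: one row per anchor, one column per
#' relative position, each cell the number of fragments whose midpoint falls
#' at that position of that anchor's window. In `paired` mode the fragment is
#' the interval spanned by a properly paired read pair, taken once per pair
#' from the alignment record with positive template length. In `single` mode
#' each read is extended from its 5' end by `fragment_length` in read
#' orientation and the midpoint of that extension is used.
#'
#' Records that are unmapped, secondary, supplementary, duplicate-flagged, or
#' below `min_mapq` are skipped (configurable via `min_mapq`). A fragment
#' falling inside the windows of several anchors is counted once per window.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param anchors Anchor tibble (see [read_anchors_gff()]).
#' @param upstream,downstream Window extent in bp.
#' @param mode `"paired"` or `"single"`.
#' @param fragment_length Positive integer, used only in single mode.
#' @param min_mapq Minimum mapping quality (default 10).
#' @return A `profdiff_counts` tibble with attributes `n_kept` and
#'   `n_skipped` recording the fragment bookkeeping.
#' @export
count_fragment_midpoints <- function(path, anchors, upstream, downstream,
                                     mode = c("paired", "single"),
                                     fragment_length = NULL, min_mapq = 10) {
  mode <- match.arg(mode)
  if (mode == "single" &&
      (is.null(fragment_length) || fragment_length < 1)) {
    pd_abort("single mode requires a positive fragment_length",
             "profdiff_validation_error")
  }
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE)) {
    pd_abort("Rsamtools and GenomicRanges are required for SAM/BAM import",
             "profdiff_io_error")
  }
  anchors <- validate_anchors(anchors)

  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  rec <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("flag", "rname", "strand", "pos", "qwidth", "isize", "mapq")
    )
  )[[1]]

  flag <- rec$flag
  n_total <- length(flag)
  mapq <- rec$mapq
  mapq[is.na(mapq)] <- 0L
  quality_ok <- !bitwAnd(flag, 4L) &    # mapped
    !bitwAnd(flag, 256L) &              # not secondary
    !bitwAnd(flag, 2048L) &             # not supplementary
    !bitwAnd(flag, 1024L) &             # not duplicate
    mapq >= min_mapq & !is.na(rec$pos)

  if (mode == "paired") {
    # one record per fragment: the proper-pair mate with positive TLEN; the
    # negative-TLEN mate of a usable pair is consumed, not skipped
    paired_ok <- bitwAnd(flag, 1L) > 0 & bitwAnd(flag, 2L) > 0 &
      !is.na(rec$isize)
    keep <- quality_ok & paired_ok & rec$isize > 0
    n_skipped <- sum(!quality_ok | !paired_ok)
    frag_start <- rec$pos[keep]
    frag_end <- frag_start + rec$isize[keep] - 1L
  } else {
    keep <- quality_ok & !bitwAnd(flag, 1L)
    n_skipped <- sum(!keep)
    minus <- as.character(rec$strand[keep]) == "-"
    read_start <- rec$pos[keep]
    read_end <- read_start + rec$qwidth[keep] - 1L
    frag_start <- ifelse(minus, read_end - fragment_length + 1L, read_start)
    frag_end <- frag_start + fragment_length - 1L
  }
  chrom <- as.character(rec$rname)[keep]
  n_candidate <- sum(keep)

  positions <- seq.int(-upstream, downstream)
  mat <- matrix(0L, nrow = nrow(anchors), ncol = length(positions))
  n_kept <- 0L
  if (n_candidate > 0) {
    mid <- fragment_midpoint(pmax(frag_start, 1L), frag_end)
    mids <- GenomicRanges::GRanges(chrom, IRanges::IRanges(mid, width = 1))
    win_start <- ifelse(anchors$strand == "-",
                        anchors$position - downstream,
                        anchors$position - upstream)
    win <- GenomicRanges::GRanges(
      anchors$chrom,
      IRanges::IRanges(pmax(win_start, 1L), width = upstream + downstream + 1L)
    )
    hits <- GenomicRanges::findOverlaps(mids, win, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    if (length(qi) > 0) {
      rel <- relative_position(mid[qi], anchors$position[si],
                               anchors$strand[si], upstream, downstream)
      ok <- !is.na(rel)
      idx <- cbind(si[ok], rel[ok] + upstream + 1L)
      for (k in seq_len(nrow(idx))) {
        mat[idx[k, 1], idx[k, 2]] <- mat[idx[k, 1], idx[k, 2]] + 1L
      }
      n_kept <- sum(ok)
    }
  }
  if (n_candidate == 0) {
    rlang::warn("no usable alignments; count table is empty")
  }

  tbl <- feature_count_table(anchors$feature_id, mat, upstream, downstream)
  attr(tbl, "n_kept") <- n_kept
  attr(tbl, "n_skipped") <- n_skipped
  tbl
}
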