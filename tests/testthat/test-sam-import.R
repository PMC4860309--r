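# Fragment-midpoint counting on miniature in-code SAM fixtures. Coordinates
# are 1-based inclusive; midpoints of even-length fragments round down.

sam_header <- "@HD\tVN:1.6\tSO:coordinate\n@SQ\tSN:chrI\tLN:100000"

sam_pair <- function(qname, pos, tlen, mapq = 60, flag1 = 99, flag2 = 147) {
  mpos <- pos + tlen - 50
  c(
    paste(qname, flag1, "chrI", pos, mapq, "50M", "=", mpos, tlen,
          strrep("A", 50), "*", sep = "\t"),
    paste(qname, flag2, "chrI", mpos, mapq, "50M", "=", pos, -tlen,
          strrep("A", 50), "*", sep = "\t")
  )
}

sam_single <- function(qname, pos, flag = 0, mapq = 60) {
  paste(qname, flag, "chrI", pos, mapq, "50M", "*", 0, 0,
        strrep("A", 50), "*", sep = "\t")
}

write_sam <- function(lines) {
  path <- withr::local_tempfile(fileext = ".sam", .local_envir = parent.frame())
  writeLines(c(sam_header, lines), path)
  path
}

anchor <- function(pos, strand = "+", id = "g1") {
  tibble::tibble(feature_id = id, chrom = "chrI", position = pos,
                 strand = strand)
}

test_that("fragment midpoints use floor on even-length fragments", {
  expect_identical(fragment_midpoint(100, 299), 199L)
  expect_identical(fragment_midpoint(50, 50), 50L)
  expect_identical(fragment_midpoint(10, 11), 10L)
  expect_error(fragment_midpoint(20, 10), class = "profdiff_validation_error")
})

test_that("relative positions are strand-aware and window-bounded", {
  expect_identical(relative_position(900, 1000, "+", 1000, 1500), -100L)
  expect_identical(relative_position(900, 1000, "-", 1000, 1500), 100L)
  expect_true(is.na(relative_position(5000, 1000, "+", 1000, 1500)))
  expect_identical(relative_position(1000, 1000, "-", 10, 10), 0L)
})

test_that("paired-end fragments are counted once at their midpoint", {
  sam <- write_sam(sam_pair("frag1", 100, 200))
  tbl <- count_fragment_midpoints(sam, anchor(150), 200, 200, mode = "paired")
  m <- profdiff:::counts_matrix(tbl)
  expect_equal(sum(m), 1)
  expect_equal(unname(m[1, as.character(49)]), 1) # midpoint 199, anchor 150
  expect_equal(attr(tbl, "n_kept"), 1L)
})

test_that("minus-strand anchors mirror the relative position", {
  sam <- write_sam(sam_pair("frag1", 100, 200))
  tbl <- count_fragment_midpoints(sam, anchor(150, "-"), 200, 200,
                                  mode = "paired")
  m <- profdiff:::counts_matrix(tbl)
  expect_equal(unname(m[1, as.character(-49)]), 1)
})

test_that("strand reversal with mirrored fragments preserves the table", {
  # odd-length fragments so the midpoint is exact under mirroring
  a <- 500
  starts <- c(401, 433, 480, 555)
  len <- 151
  fwd <- write_sam(unlist(lapply(seq_along(starts), function(i)
    sam_pair(paste0("f", i), starts[i], len))))
  ends <- starts + len - 1
  mirrored_starts <- 2 * a - ends
  rev <- write_sam(unlist(lapply(seq_along(starts), function(i)
    sam_pair(paste0("r", i), mirrored_starts[i], len))))
  t_fwd <- count_fragment_midpoints(fwd, anchor(a, "+"), 300, 300,
                                    mode = "paired")
  t_rev <- count_fragment_midpoints(rev, anchor(a, "-"), 300, 300,
                                    mode = "paired")
  expect_identical(profdiff:::counts_matrix(t_fwd),
                   profdiff:::counts_matrix(t_rev))
})

test_that("counting conserves mass against the kept-fragment counter", {
  set.seed(11)
  starts <- sample(200:1800, 30)
  sam <- write_sam(unlist(lapply(seq_along(starts), function(i)
    sam_pair(paste0("p", i), starts[i], 120))))
  tbl <- count_fragment_midpoints(sam, anchor(1000), 400, 400,
                                  mode = "paired")
  expect_equal(sum(profdiff:::counts_matrix(tbl)), attr(tbl, "n_kept"))
  # fragments whose midpoint is outside the window are skipped, not lost
  mids <- floor((2 * starts + 119) / 2)
  expect_equal(attr(tbl, "n_kept"), sum(abs(mids - 1000) <= 400))
})

test_that("single-end reads are extended from their 5' end", {
  sam <- write_sam(c(sam_single("s_plus", 100, flag = 0),
                     sam_single("s_minus", 100, flag = 16)))
  tbl <- count_fragment_midpoints(sam, anchor(100), 200, 200,
                                  mode = "single", fragment_length = 100)
  m <- profdiff:::counts_matrix(tbl)
  # + read: fragment [100,199], midpoint 149 -> rel +49
  expect_equal(unname(m[1, as.character(49)]), 1)
  # - read: 3' end 149, fragment [50,149], midpoint 99 -> rel -1
  expect_equal(unname(m[1, as.character(-1)]), 1)
  expect_error(
    count_fragment_midpoints(sam, anchor(100), 200, 200, mode = "single"),
    class = "profdiff_validation_error"
  )
})

test_that("filtered and unmapped records are skipped, empty input warns", {
  lines <- c(
    sam_pair("ok", 100, 200),
    sam_pair("dup", 100, 200, flag1 = 1123, flag2 = 1171),   # duplicate flag
    sam_pair("lowq", 100, 200, mapq = 5)                     # below mapq 10
  )
  tbl <- count_fragment_midpoints(write_sam(lines), anchor(150), 200, 200,
                                  mode = "paired")
  expect_equal(sum(profdiff:::counts_matrix(tbl)), 1)
  expect_equal(attr(tbl, "n_skipped"), 4L)

  empty <- write_sam(character(0))
  expect_warning(
    tbl0 <- count_fragment_midpoints(empty, anchor(150), 50, 50,
                                     mode = "paired"),
    "empty"
  )
  expect_equal(sum(profdiff:::counts_matrix(tbl0)), 0)
  expect_equal(nrow(tbl0), 1)
})

test_that("anchors come from the strand-aware 5' ends of GFF genes", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrI\ttest\tgene\t1000\t2000\t.\t+\t.\tID=gA",
    "chrI\ttest\tgene\t3000\t4000\t.\t-\t.\tID=gB",
    "chrI\ttest\texon\t1000\t1100\t.\t+\t.\tID=eA"
  ), gff)
  anchors <- read_anchors_gff(gff, feature_type = "gene")
  expect_equal(nrow(anchors), 2)
  expect_equal(anchors$position[anchors$feature_id == "gA"], 1000)
  expect_equal(anchors$position[anchors$feature_id == "gB"], 4000)
  expect_identical(anchors$strand, c("+", "-"))
})
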