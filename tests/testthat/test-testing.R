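# End-to-end behaviour of the testing pipeline on simulated datasets.

test_that("null simulations give calibrated p-values", {
  cfg <- simulation_config(n_positions = 600, samples_per_condition = 3,
                           baseline = 50, dispersion = 0.1, seed = 61)
  res <- run_testing(simulate_dataset(cfg)$dataset, theta = 0)
  expect_lt(abs(mean(res$p_value < 0.05) - 0.05), 0.03)
  expect_gt(attr(res, "eta0"), 0.85)
  expect_equal(nrow(res), 600)
})

test_that("a strong differential window dominates the smallest p-values", {
  cfg <- simulation_config(n_positions = 800, samples_per_condition = 5,
                           baseline = 100, dispersion = 0.05,
                           effect_window = c(0, 199), effect_lfc = 1.5,
                           seed = 62)
  sim <- simulate_dataset(cfg)
  res <- run_testing(sim$dataset, theta = 0.5)
  in_window <- sim$truth$differential
  ranks <- rank(res$p_value)
  expect_lt(median(ranks[in_window]), 300)
  # the most significant calls are mostly inside the window
  top <- order(res$p_value)[1:100]
  expect_gt(mean(in_window[top]), 0.7)
})

test_that("results expose tidy/glance views and a writable table", {
  cfg <- simulation_config(n_positions = 120, samples_per_condition = 2,
                           baseline = 40, dispersion = 0.1, seed = 63)
  res <- run_testing(simulate_dataset(cfg)$dataset)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("position", "base_mean", "log2fc", "se", "stat",
                     "p_value", "local_fdr", "dispersion"))
  gl <- glance(res, cutoff = 0.2)
  expect_equal(gl$n_positions, 120)
  expect_true(gl$eta0 > 0 && gl$eta0 <= 1)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$p_value, res$p_value, tolerance = 1e-12)
})

test_that("degenerate all-zero positions are reported with p = 1", {
  set.seed(64)
  chip <- matrix(rpois(50 * 4, 30), 50, 4)
  input <- matrix(rpois(50 * 4, 30) + 1L, 50, 4)
  chip[7, ] <- 0L
  ds <- make_dataset(chip, input, n_per_cond = 2)
  expect_warning(
    res <- run_testing(ds, theta = 0, compute_local_fdr = FALSE),
    "median"
  ) # 49 usable positions triggers the flat-trend fallback
  expect_equal(res$p_value[7], 1)
  expect_equal(res$log2fc[7], 0)
})

test_that("invalid designs and inputs are rejected", {
  set.seed(65)
  m <- matrix(rpois(40, 20), 10, 4)
  ann <- make_annotation(4, upstream = 4, downstream = 5,
                         conditions = "only")
  ds <- assemble_dataset(ann, m, m)
  expect_error(run_testing(ds), class = "profdiff_design_error")
  expect_error(run_testing(list()), class = "profdiff_validation_error")
  ds2 <- make_dataset(m, m, n_per_cond = 2)
  expect_error(run_testing(ds2, theta = -1),
               class = "profdiff_validation_error")
  expect_error(run_testing(ds2, reference = "nope"),
               class = "profdiff_design_error")
})

test_that("reference relevelling flips the sign of the contrast", {
  cfg <- simulation_config(n_positions = 100, samples_per_condition = 3,
                           baseline = 80, dispersion = 0.05,
                           effect_window = c(0, 40), effect_lfc = 1,
                           seed = 66)
  ds <- simulate_dataset(cfg)$dataset
  res_fwd <- run_testing(ds, theta = 0, compute_local_fdr = FALSE)
  res_rev <- run_testing(ds, theta = 0, reference = "treatment",
                         compute_local_fdr = FALSE)
  expect_equal(res_fwd$log2fc, -res_rev$log2fc, tolerance = 1e-6)
})

test_that("per-position fits agree with an independent NB testing engine", {
  # DESeq2 fits the same model (NB GLM, natural-log link, normalization
  # factors); with dispersions fixed to ours, the MLE fold changes and Wald
  # p-values must coincide position by position.
  suppressPackageStartupMessages(requireNamespace("DESeq2"))
  cfg <- simulation_config(n_positions = 80, samples_per_condition = 3,
                           baseline = 100, dispersion = 0.1,
                           effect_window = c(0, 30), effect_lfc = 1.2,
                           seed = 67)
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  res <- run_testing(ds, theta = 0, compute_local_fdr = FALSE)
  factors <- profdiff:::dataset_normalization_factors(ds)

  counts <- ds$chip
  rownames(counts) <- paste0("pos", seq_len(nrow(counts)))
  coldata <- data.frame(
    condition = factor(ds$annotation$condition,
                       levels = c("control", "treatment"))
  )
  dds <- DESeq2::DESeqDataSetFromMatrix(counts, coldata, ~condition)
  rownames(factors) <- rownames(counts)
  DESeq2::normalizationFactors(dds) <- factors
  DESeq2::dispersions(dds) <- res$dispersion
  dds <- DESeq2::nbinomWaldTest(dds)
  dres <- DESeq2::results(dds)

  ok <- is.finite(dres$log2FoldChange) & res$se < 10
  expect_gt(mean(ok), 0.9)
  expect_equal(res$log2fc[ok], dres$log2FoldChange[ok], tolerance = 1e-4)
  expect_equal(res$se[ok], dres$lfcSE[ok], tolerance = 0.02)
  expect_equal(res$p_value[ok], dres$pvalue[ok], tolerance = 0.01)
})
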