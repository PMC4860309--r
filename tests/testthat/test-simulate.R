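test_that("the generator is deterministic and marks truth exactly", {
  cfg <- simulation_config(n_positions = 100, samples_per_condition = 2,
                           baseline = 30, dispersion = 0.1,
                           effect_window = c(10, 39), effect_lfc = 1,
                           seed = 81)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$dataset$chip, s2$dataset$chip)
  expect_identical(s1$dataset$input, s2$dataset$input)
  expect_identical(which(s1$truth$differential),
                   which(s1$truth$position >= 10 & s1$truth$position <= 39))

  null_cfg <- simulation_config(n_positions = 50, samples_per_condition = 2,
                                baseline = 30, dispersion = 0.1, seed = 82)
  expect_false(any(simulate_dataset(null_cfg)$truth$differential))
})

test_that("NB draws have the requested mean-variance relationship", {
  set.seed(83)
  n <- 1e5
  for (a in c(0.01, 0.1, 0.5)) {
    mu <- 100
    y <- rnbinom(n, size = 1 / a, mu = mu)
    expect_equal(mean(y), mu, tolerance = 0.02 * mu)
    expect_equal(var(y), mu + a * mu^2, tolerance = 0.02 * (mu + a * mu^2))
  }
})

test_that("the generator hits its nominal effect size", {
  cfg <- simulation_config(n_positions = 300, samples_per_condition = 10,
                           baseline = 200, dispersion = 0.05,
                           effect_window = c(0, 99), effect_lfc = 2,
                           seed = 84)
  sim <- simulate_dataset(cfg)
  cond <- sim$dataset$annotation$condition
  m_t <- rowMeans(sim$dataset$chip[, cond == "treatment"])
  m_c <- rowMeans(sim$dataset$chip[, cond == "control"])
  lr <- log2(m_t / m_c)
  expect_lt(abs(median(lr[sim$truth$differential]) - 2), 0.2)
  expect_lt(abs(median(lr[!sim$truth$differential])), 0.2)
})

test_that("feature tables collapse to metafeature draws", {
  cfg1 <- simulation_config(n_positions = 40, samples_per_condition = 2,
                            baseline = 50, dispersion = 0.1, n_features = 1,
                            seed = 85)
  ft <- simulate_feature_tables(cfg1)
  tbl <- ft$chip_tables[[1]]
  expect_equal(nrow(tbl), 1)
  expect_length(profdiff:::counts_positions(tbl), 40)

  # summarizing with no trimming and no filter is exactly the column sum
  cfg <- simulation_config(n_positions = 30, samples_per_condition = 2,
                           baseline = 80, dispersion = 0.1, n_features = 25,
                           seed = 86)
  ft <- simulate_feature_tables(cfg)
  for (tblj in ft$chip_tables) {
    prof <- summarize_counts_per_position(tblj, min_total = 0, trim = 0)
    expect_equal(prof$value,
                 unname(colSums(profdiff:::counts_matrix(tblj))))
  }
})

test_that("trimming stabilizes summaries of heavy-tailed feature weights", {
  vars <- vapply(c(FALSE, TRUE), function(do_trim) {
    profs <- vapply(1:30, function(s) {
      cfg <- simulation_config(n_positions = 20, samples_per_condition = 1,
                               baseline = 100, dispersion = 0.3,
                               n_features = 40, seed = 900 + s)
      ft <- simulate_feature_tables(cfg)
      summarize_counts_per_position(ft$chip_tables[[1]], min_total = 0,
                                    trim = if (do_trim) 0.15 else 0)$value
    }, numeric(20))
    median(apply(profs, 1, var))
  }, 0)
  expect_lt(vars[2], vars[1])
})

test_that("truth scoring counts the confusion table correctly", {
  truth <- tibble::tibble(position = 1:10,
                          differential = c(rep(TRUE, 4), rep(FALSE, 6)))
  res <- tibble::tibble(position = 1:10,
                        local_fdr = c(0.01, 0.01, 0.5, 0.01, 0.9, 0.05,
                                      rep(0.9, 4)))
  ev <- evaluate_against_truth(res, truth, cutoff = 0.2)
  expect_equal(ev$tp, 3)
  expect_equal(ev$fp, 1)
  expect_equal(ev$fn, 1)
  expect_equal(ev$tn, 5)
  expect_equal(ev$empirical_fdr, 1 / 4)
  expect_equal(ev$power, 3 / 4)

  none <- evaluate_against_truth(
    tibble::tibble(position = 1:10, local_fdr = 1), truth, 0.2
  )
  expect_equal(none$tp + none$fp, 0)
  expect_equal(none$power, 0)

  expect_error(
    evaluate_against_truth(
      tibble::tibble(position = 2:11, local_fdr = 1), truth, 0.2
    ),
    class = "profdiff_validation_error"
  )
})

test_that("config validation rejects bad windows and missing seeds", {
  expect_error(simulation_config(n_positions = 100), "seed")
  expect_error(
    simulation_config(n_positions = 100, effect_window = c(90, 200),
                      seed = 1),
    class = "profdiff_config_error"
  )
  expect_error(
    simulation_config(n_positions = 50, baseline = 0, seed = 1),
    class = "profdiff_config_error"
  )
})

test_that("a shared Input repeats one draw within each condition", {
  cfg <- simulation_config(n_positions = 60, samples_per_condition = 3,
                           baseline = 50, dispersion = 0.1,
                           shared_input = TRUE, seed = 87)
  sim <- simulate_dataset(cfg)
  inp <- sim$dataset$input
  expect_identical(inp[, 1], inp[, 2])
  expect_identical(inp[, 1], inp[, 3])
  expect_false(identical(inp[, 1], inp[, 4]))
  expect_identical(inp[, 4], inp[, 5])
})
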