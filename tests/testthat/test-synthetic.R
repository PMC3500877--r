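test_that("zero noise reproduces the simulation exactly at all times", {
  cfg <- synthetic_config(1, times = c(0, 2, 10, 24), noise_cv = 0,
                          seed = 5)
  g <- generate_dataset(cfg)
  sim <- simulate_model(1, times = c(0, 2, 10, 24))
  for (i in seq_len(nrow(g$dataset))) {
    row <- g$dataset[i, ]
    expect_equal(row$value_fold,
                 fold_change_at(sim, paste0(row$gene, "_", row$level),
                                row$time_h),
                 tolerance = 1e-10)
  }
  expect_equal(unique(g$dataset$value_fold[g$dataset$time_h == 0]), 1)
})

test_that("generation is byte-identical for identical seeds", {
  cfg <- synthetic_config(2, noise_cv = 0.1, seed = 99)
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  expect_identical(g1$dataset, g2$dataset)
  g3 <- generate_dataset(synthetic_config(2, noise_cv = 0.1, seed = 100))
  expect_false(identical(g1$dataset, g3$dataset))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- runif(1)
  set.seed(1234)
  invisible(generate_dataset(synthetic_config(1, seed = 7)))
  expect_identical(runif(1), before)
})

test_that("replicate noise has the configured coefficient of variation", {
  cfg <- synthetic_config(3, times = c(0, 5), n_replicates = 1000,
                          noise_cv = 0.1, seed = 31)
  d <- generate_dataset(cfg)$dataset
  v <- d$value_fold[d$gene == "GR" & d$level == "mrna" & d$time_h == 5]
  expect_length(v, 1000)
  expect_lt(abs(sd(v) / mean(v) - 0.1) / 0.1, 0.10)
})

test_that("replicate means converge to the noiseless trajectory", {
  cfg <- synthetic_config(3, times = c(0, 5), n_replicates = 1000,
                          noise_cv = 0.1, seed = 32)
  d <- generate_dataset(cfg)$dataset
  sim <- simulate_model(3, times = c(0, 5))
  v <- d$value_fold[d$gene == "GR" & d$level == "mrna" & d$time_h == 5]
  target <- fold_change_at(sim, "GR_mrna", 5)
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - target), 3 * se)
})

test_that("every generated dataset passes schema validation", {
  for (id in 1:6) {
    g <- generate_dataset(synthetic_config(id, noise_cv = 0.2,
                                           seed = id))
    expect_s3_class(as_timecourse(g$dataset), "gr_dataset")
    # latent species never appear among observables
    expect_false("X" %in% g$dataset$gene)
  }
})

test_that("invalid configurations are rejected up front", {
  expect_error(synthetic_config(1, times = c(2, 10)), "include 0")
  expect_error(synthetic_config(1, noise_cv = -0.1), "noise_cv")
  expect_error(synthetic_config(1, n_replicates = 0), "n_replicates")
  bad <- default_params(build_model(1)); bad["dm_GR"] <- 5
  expect_error(synthetic_config(1, true_params = bad), "bounds")
})

test_that("write_synthetic emits the dataset and a truth record", {
  g <- generate_dataset(synthetic_config(5, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_synthetic(g, path)
  back <- read_timecourse(path)
  expect_equal(nrow(back), nrow(g$dataset))
  truth <- jsonlite::fromJSON(paste0(path, ".truth.json"))
  expect_equal(truth$model_id, 5)
  expect_equal(truth$seed, 3)
})
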