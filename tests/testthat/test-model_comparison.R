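test_that("classify_trend recognises exact family members and guards input", {
  t4 <- c(0, 2, 10, 24)
  expect_identical(classify_trend(t4, 2 * t4 + 1), "linear")
  expect_identical(classify_trend(t4, 3 * log(1 + t4) + 1), "logarithmic")
  expect_identical(classify_trend(t4, 5 * t4), "linear")  # tie rule unused
  expect_error(classify_trend(t4, rep(2, 4)), "constant")
  expect_error(classify_trend(c(0, 2, 10), c(1, 2, 3)), ">= 4")
})

test_that("classify_trend is invariant to positive affine rescaling", {
  set.seed(21)
  t <- seq(0, 24, length.out = 9)
  for (i in 1:20) {
    y <- cumsum(abs(rnorm(9))) + runif(1)
    lab <- classify_trend(t, y)
    a <- runif(1, 0.1, 50); b <- runif(1, -5, 5)
    expect_identical(classify_trend(t, a * y + b), lab)
  }
})

test_that("comparison ranks the generating topology first on its own data", {
  truth <- draw_truth(build_model(5), seed = 13)
  d <- generate_dataset(synthetic_config(5, truth, times = c(0, 2, 10, 24),
                                         noise_cv = 0, seed = 13))$dataset
  cmp <- compare_models(d, c(5, 6), n_starts = 6, seed = 1)
  expect_equal(cmp$table$model_id[1], 5)
  expect_lt(cmp$table$total_epsilon[1], 1e-6)
  expect_named(cmp$table, c("rank", "model_id", "name", "total_epsilon",
                            "failed"))
  expect_true(all(c("model_id", "observable", "epsilon") %in%
                    names(cmp$by_observable)))
})

test_that("duplicate candidates tie and degenerate input is rejected", {
  truth <- draw_truth(build_model(5), seed = 14)
  d <- generate_dataset(synthetic_config(5, truth, noise_cv = 0,
                                         seed = 14))$dataset
  cmp <- compare_models(d, c(5, 5), n_starts = 3, seed = 2)
  expect_equal(cmp$table$total_epsilon[1], cmp$table$total_epsilon[2],
               tolerance = 1e-9)
  expect_error(compare_models(d, 5), "at least 2")
})

test_that("trend_of labels a simulated observable", {
  lab <- trend_of(1, species = "cJun_protein")
  expect_true(lab %in% c("linear", "logarithmic"))
})
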