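test_that("residual_epsilon implements the normalized least-squares form", {
  expect_equal(residual_epsilon(c(2, 3), c(1, 2)), 0.625)
  expect_equal(residual_epsilon(1, 2), 0.25)
  expect_equal(residual_epsilon(c(1.3, 0.2, 7), c(1.3, 0.2, 7)), 0)
  expect_error(residual_epsilon(c(1, 2), c(1, 0)), "near-zero")
  expect_error(residual_epsilon(1:3, 1:2), "equal length")
  # agreement with an independently coded loop
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    y <- runif(n, 0.1, 5); Y <- runif(n, 0.1, 5)
    expect_equal(residual_epsilon(y, Y), eps_brute(y, Y), tolerance = 1e-14)
  }
})

test_that("stage 1 recovers GR rates from noiseless autoregulation data", {
  m <- build_model(3)
  for (s in 1:3) {
    truth <- random_params(m, seed = 300 + s,
                           which = c("dm_GR", "dp_GR", "a_GR_GR"))
    d <- generate_dataset(synthetic_config(3, truth, times = c(0, 2, 10, 24),
                                           noise_cv = 0, seed = s))$dataset
    s1 <- fit_stage1_gr(m, d, n_starts = 6, seed = s)
    for (nm in c("dm_GR", "dp_GR", "a_GR_GR"))
      expect_lt(abs(s1$params[nm] - truth[nm]) / truth[nm], 0.05)
  }
})

test_that("flat GR series are flagged non-identifiable, not fitted", {
  # Models 5-6 have nothing upstream of GR: its observables are
  # structurally flat and carry no information about GR rates
  d <- generate_dataset(synthetic_config(5, noise_cv = 0))$dataset
  s1 <- fit_stage1_gr(build_model(5), d, n_starts = 4, seed = 1)
  expect_true(length(s1$nonidentifiable) > 0)
  expect_equal(unname(s1$params["dm_GR"]),
               unname(default_params(build_model(5))["dm_GR"]))
})

test_that("stage 1 demands GR observables", {
  d <- generate_dataset(synthetic_config(5, noise_cv = 0))$dataset
  d_noGR <- d[d$gene != "GR", ]
  expect_error(fit_stage1_gr(build_model(5), d_noGR, n_starts = 2),
               "GR")
})

test_that("estimated rates always respect the [0.01, 1] bounds", {
  for (s in 1:5) {
    truth <- draw_truth(build_model(5), seed = 500 + s)
    d <- generate_dataset(synthetic_config(5, truth, noise_cv = 0.3,
                                           seed = s))$dataset
    fit <- fit_model(5, d, n_starts = 3, seed = s)
    expect_true(all(fit$params >= 0.01 - 1e-12 & fit$params <= 1 + 1e-12))
  }
})

test_that("a model refits its own noiseless data essentially exactly", {
  m <- build_model(2)
  truth <- draw_truth(m, seed = 77)
  d <- generate_dataset(synthetic_config(2, truth, times = c(0, 2, 10, 24),
                                         noise_cv = 0, seed = 77))$dataset
  fit <- fit_model(m, d, n_starts = 8, seed = 1)
  expect_lt(fit$total_epsilon, 1e-3)
  expect_named(fit$epsilon_by_observable)
  expect_true(all(fit$epsilon_by_observable >= 0))
})

test_that("an underdetermined series is interpolated to epsilon zero", {
  # one observable, one post-baseline point: always fittable exactly
  m <- build_model(5)
  d <- data.frame(gene = "Erg", level = "mrna", time_h = c(0, 2),
                  replicate = 1L, value_fold = c(1, 1.4))
  s1 <- default_params(m)[c("dm_GR", "dp_GR")]
  fit <- fit_stage2(m, s1, as_timecourse(d), n_starts = 6, seed = 2)
  expect_lt(fit$epsilon_by_observable[["Erg_mrna"]], 1e-8)
})

test_that("fits are deterministic given the seed", {
  truth <- draw_truth(build_model(5), seed = 8)
  d <- generate_dataset(synthetic_config(5, truth, noise_cv = 0.1,
                                         seed = 8))$dataset
  f1 <- fit_model(5, d, n_starts = 4, seed = 3)
  f2 <- fit_model(5, d, n_starts = 4, seed = 3)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$epsilon_by_observable, f2$epsilon_by_observable)
})

test_that("the fit report is valid JSON carrying the run provenance", {
  truth <- draw_truth(build_model(5), seed = 4)
  d <- generate_dataset(synthetic_config(5, truth, noise_cv = 0,
                                         seed = 4))$dataset
  fit <- fit_model(5, d, n_starts = 2, seed = 1)
  rep <- jsonlite::fromJSON(fit_report(fit))
  expect_equal(rep$model_id, 5)
  expect_equal(rep$bounds, c(0.01, 1))
  expect_equal(rep$seed, 1)
  expect_true(is.numeric(rep$total_epsilon))
})
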