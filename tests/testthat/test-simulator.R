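test_that("without stimulus every observable stays flat at 1", {
  for (id in 1:6) {
    sim <- simulate_model(id, stimulus_on = FALSE, times = seq(0, 48, 1))
    expect_equal(max(abs(sim$trajectories - 1)), 0, tolerance = 1e-9,
                 info = paste("model", id))
  }
})

test_that("integration matches the matrix-exponential closed form", {
  # all repression-free topologies are linear systems with an exact solution
  times <- c(0, 0.5, 2, 7, 10, 24, 48)
  for (id in c(1, 2, 3, 5, 6)) {
    m <- build_model(id)
    p <- random_params(m, seed = 40 + id)
    sim <- simulate_model(m, p, times = times)
    expect_equal(sim$trajectories, oracle_linear_traj(m, p, times),
                 tolerance = 1e-7, info = paste("model", id))
  }
})

test_that("saturating activation keeps Model 5 trajectories non-decreasing", {
  m <- build_model(5)
  p <- default_params(m)
  p["a_GR_Erg"] <- 1
  sim <- simulate_model(m, p, times = seq(0, 24, by = 0.25))
  for (sp in c("GR_mrna", "GR_protein", "Erg_mrna", "Erg_protein"))
    expect_gte(min(diff(sim$trajectories[, sp])), -1e-8)
})

test_that("stronger stimulus activation never lowers a downstream response", {
  for (id in c(1, 5)) {
    m <- build_model(id)
    prev <- NULL
    for (k in c(0.1, 0.3, 0.5)) {
      sim <- simulate_model(m, times = seq(0, 24, 0.5), k_act = k)
      if (!is.null(prev))
        expect_gte(min(sim$trajectories - prev), -1e-8)
      prev <- sim$trajectories
    }
  }
})

test_that("fold_change_at anchors at 1, interpolates linearly, and guards", {
  sim <- simulate_model(1, times = seq(0, 24, 0.5))
  for (sp in colnames(sim$trajectories))
    expect_equal(fold_change_at(sim, sp, 0), 1)

  flat <- simulate_model(1, stimulus_on = FALSE, times = seq(0, 24, 0.5))
  expect_equal(fold_change_at(flat, "Bim_protein", 12), 1)

  # midpoint of a hand-made segment: 2.0 at 10 h, 4.0 at 14 h -> 3.0 at 12 h
  fake <- sim
  fake$times <- c(0, 10, 14)
  fake$trajectories <- matrix(c(1, 2, 4), 3, 1,
                              dimnames = list(NULL, "Bim_protein"))
  expect_equal(fold_change_at(fake, "Bim_protein", 12), 3)

  expect_error(fold_change_at(sim, "nope_protein", 1), "unknown species")
  expect_error(fold_change_at(sim, "Bim_protein", 99), "out of")
})

test_that("halving the output grid leaves interpolated values unchanged", {
  m <- build_model(2)
  p <- random_params(m, seed = 9)
  # at shared grid nodes the integrator itself must be grid-independent
  coarse <- simulate_model(m, p, times = seq(0, 24, 0.2))
  fine <- simulate_model(m, p, times = seq(0, 24, 0.1))
  shared <- seq(1, length(fine$times), by = 2)
  expect_equal(fine$trajectories[shared, ], coarse$trajectories,
               tolerance = 1e-7)
  # off-node queries converge once the grid resolves the curvature
  c2 <- simulate_model(m, p, times = seq(0, 24, 0.025))
  f2 <- simulate_model(m, p, times = seq(0, 24, 0.0125))
  q <- c(1.3, 7.7, 15.1, 23.9)
  for (sp in c("cJun_mrna", "Bim_protein"))
    expect_equal(fold_change_at(c2, sp, q), fold_change_at(f2, sp, q),
                 tolerance = 1e-6)
})

test_that("trajectory export is tidy time/species/level_fold text", {
  sim <- simulate_model(5, times = seq(0, 10, 1))
  df <- as.data.frame(sim)
  expect_named(df, c("time_h", "species", "level_fold"))
  expect_equal(nrow(df), length(sim$times) * ncol(sim$trajectories))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectories(sim, path)
  back <- read.delim(path)
  expect_equal(back$level_fold, df$level_fold)
})

test_that("invalid time grids are rejected", {
  expect_error(simulate_model(1, times = c(1, 2, 3)), "start at 0")
  expect_error(simulate_model(1, times = c(0, 2, 2)), "ascending")
})
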