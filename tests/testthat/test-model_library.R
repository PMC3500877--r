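test_that("the catalogue wires the six topologies as documented", {
  m1 <- build_model(1)
  expect_s3_class(m1, "gr_model")
  expect_setequal(paste(m1$edges$source, m1$edges$target),
                  c("GR GR", "GR cJun", "cJun Bim"))
  expect_true(m1$gr_autoregulation)
  expect_length(m1$latent_species, 0)

  m2 <- build_model(2)
  expect_identical(m2$latent_species, "X")
  expect_true(all(c("GR X", "X cJun", "cJun Bim") %in%
                    paste(m2$edges$source, m2$edges$target)))

  for (id in 1:6) {
    m <- build_model(id)
    expect_identical(m$model_id, id)
    expect_identical(m$cell_line,
                     if (id <= 4) "C7_sensitive" else "C1_resistant")
    expect_identical(m$gr_autoregulation, id <= 4)
    expect_length(m$latent_species, if (id %in% c(2, 6)) 1 else 0)
    # every edge endpoint is a declared gene
    expect_true(all(c(m$edges$source, m$edges$target) %in% m$genes))
    # latent models carry exactly one extra species pair
    expect_identical(build_model(id)$genes,
                     build_model(MODEL_NAMES[id])$genes)
  }
  expect_length(setdiff(build_model(2)$genes, build_model(1)$genes), 1)
  expect_length(setdiff(build_model(6)$genes, build_model(5)$genes), 1)
})

test_that("unknown model ids are rejected, not defaulted", {
  expect_error(build_model(7), "unknown model")
  expect_error(build_model(0), "unknown model")
  expect_error(build_model("no_such_model"), "unknown model")
})

test_that("Model 4 edge signs are configurable with the documented default", {
  m4 <- build_model(4)
  erg_gr <- m4$edges[m4$edges$source == "Erg" & m4$edges$target == "GR", ]
  gr_erg <- m4$edges[m4$edges$source == "GR" & m4$edges$target == "Erg", ]
  expect_identical(erg_gr$sign, "activation")
  expect_identical(gr_erg$sign, "repression")
  alt <- build_model(4, erg_gr_sign = "repression",
                     gr_erg_sign = "activation")
  expect_identical(alt$edges$sign[alt$edges$source == "Erg"], "repression")
})

test_that("half-life conversion is ln(2)/t_half with a guarded domain", {
  expect_equal(half_life_to_rate(log(2)), 1)
  expect_equal(half_life_to_rate(2), log(2) / 2)
  expect_error(half_life_to_rate(0), "positive")
  expect_error(half_life_to_rate(-3), "positive")
})

test_that("the balanced baseline is an exact fixed point without stimulus", {
  for (id in 1:6) {
    d <- odes(build_model(id), D = 0)
    expect_equal(max(abs(d)), 0, info = paste("model", id))
  }
})

test_that("mass-action terms have the expected signs and magnitudes", {
  # single unregulated gene: s = dm (balanced) so at mrna = 1 the
  # derivative vanishes and at mrna = 2 it is -dm * 1
  m3 <- build_model(3)
  p <- default_params(m3)
  p["dm_Erg"] <- 0.1
  st <- grkin:::initial_state(m3)
  expect_equal(odes(m3, p, st, D = 0)[["Erg_mrna"]], 0)
  st["Erg_mrna"] <- 2
  expect_equal(odes(m3, p, st, D = 0)[["Erg_mrna"]], -0.1)

  # direct activation: with active GR present, target mRNA is produced
  m1 <- build_model(1)
  st1 <- grkin:::initial_state(m1)
  st1["GRa"] <- 0.5
  expect_gt(odes(m1, default_params(m1), st1, D = 1)[["cJun_mrna"]], 0)

  expect_error(odes(m1, state = st1 - 2), "negative")
})

test_that("baseline-infeasible rate sets are rejected", {
  m1 <- build_model(1)
  p <- default_params(m1)
  p["a_cJun_Bim"] <- 0.9   # exceeds dm_Bim = 0.2 at unit baseline
  expect_error(resolve_rates(m1, p), "exceeds")
  expect_error(simulate_model(m1, p), "exceeds")
  # clamped variant is the documented soft fallback
  expect_silent(resolve_rates(m1, p, clamp_basal = TRUE))
})

test_that("simulated trajectories stay non-negative for random rate sets", {
  for (id in 1:6) {
    for (s in 1:5) {
      p <- random_params(build_model(id), seed = 100 * id + s)
      sim <- simulate_model(id, p, times = seq(0, 48, by = 2))
      expect_gte(min(sim$states), 0)
    }
  }
})
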