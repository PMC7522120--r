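test_that("synthetic_config validates", {
  expect_error(synthetic_config(noise_sd = -1), "non-negative")
  expect_equal(synthetic_config(7)$seed, 7L)
})

test_that("generators are seed-reproducible and seeds differ", {
  g1 <- gen_binding_assay(synthetic_config(3))
  g2 <- gen_binding_assay(synthetic_config(3))
  g3 <- gen_binding_assay(synthetic_config(4))
  expect_equal(g1$observations, g2$observations)
  expect_false(identical(g1$observations$bound, g3$observations$bound))

  c1 <- gen_microtumor_cohort(synthetic_config(3))
  c2 <- gen_microtumor_cohort(synthetic_config(3))
  expect_equal(c1$observations, c2$observations)

  t1 <- gen_therapy_outcomes(synthetic_config(3))
  t2 <- gen_therapy_outcomes(synthetic_config(3))
  expect_equal(t1$observations$A$tumor_free, t2$observations$A$tumor_free)

  b1 <- gen_biodistribution(synthetic_config(3))
  b2 <- gen_biodistribution(synthetic_config(3))
  expect_equal(b1$observations, b2$observations)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  x_ref <- runif(3)
  set.seed(123)
  invisible(gen_microtumor_cohort(synthetic_config(9)))
  expect_identical(runif(3), x_ref)
})

test_that("zero noise returns the forward-simulated truth", {
  g <- gen_binding_assay(synthetic_config(5, noise_sd = 0))
  expect_equal(g$observations$bound, g$truth$bound)
  co <- gen_microtumor_cohort(synthetic_config(5, noise_sd = 0))
  expect_equal(co$observations$activity_Bq, co$truth$activity_Bq)
  r <- uptake_regression(co$observations$cells, co$observations$activity_Bq)
  expect_equal(r$r_squared, 1, tolerance = 1e-6)
})

test_that("microtumor cohort matches the documented size distribution", {
  co <- gen_microtumor_cohort(synthetic_config(1), n = 1000)
  r <- co$observations$radius_um
  expect_true(all(r >= 19 & r <= 82))
  expect_gt(mean(r), 41)
  expect_lt(mean(r), 47)
  ## cell counts span roughly 5-400 and follow r^3 at the packing density
  expect_lte(min(co$observations$cells), 10)
  expect_gte(max(co$observations$cells), 300)
  expect_equal(co$observations$cells,
               round(1.74e-4 * 4 / 3 * pi * r^3))
})

test_that("therapy outcome generator respects degenerate probabilities", {
  res <- gen_therapy_outcomes(synthetic_config(2),
                              sizes = c(A = 10, B = 10),
                              cure_prob = c(A = 1, B = 0))
  expect_equal(res$observations$A$tumor_free, 10)
  expect_equal(res$observations$B$tumor_free, 0)
  ## all death days within the window
  days <- res$observations$B$events$day
  expect_true(all(days >= 90 & days <= 154))
})

test_that("therapy generator has power to separate A from B", {
  ## moderate replicate count to keep runtime low; the separation is strong
  rej <- vapply(1:60, function(s) {
    o <- gen_therapy_outcomes(synthetic_config(s))$observations
    fisher_exact(o$A, o$B)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.95)
})

test_that("biodistribution shapes: free astatide thyroid rises, blood falls", {
  b <- gen_biodistribution(synthetic_config(6))
  cur <- b$truth$curves$free_astatide
  expect_gt(cur$thyroid$pct_ia_g[4], cur$thyroid$pct_ia_g[1])
  expect_gt(cur$stomach$pct_ia_g[4], cur$stomach$pct_ia_g[1])
  expect_lt(cur$blood$pct_ia_g[4], cur$blood$pct_ia_g[1])
  ## three tracers present
  expect_setequal(unique(b$observations$tracer),
                  c("mab_211At", "free_astatide", "control_igg"))
})

test_that("zero-noise biodistribution recovers the analytic organ integral", {
  b <- gen_biodistribution(synthetic_config(8, noise_sd = 0))
  cur <- b$truth$curves$mab_211At$blood
  ## analytic residence for A1 e^{-k1 t} with physical decay on top
  sch <- at211_scheme()
  lam <- decay_constant(sch) * 3600
  p <- b$truth$templates$mab_211At$blood
  exact <- p[["A1"]] / 100 / (p[["k1"]] + lam)
  res <- residence_time_and_organ_dose(cur$time_h, cur$pct_ia_g / 100,
                                       1, 1, sch)
  expect_equal(res$residence_time_h, exact, tolerance = 0.03)
})

test_that("uptake regression succeeds on most default cohorts", {
  ok <- vapply(1:20, function(s) {
    co <- gen_microtumor_cohort(synthetic_config(s))
    uptake_regression(co$observations$cells,
                      co$observations$activity_Bq)$r_squared >= 0.95
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})
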