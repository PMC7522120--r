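test_that("binding components and models validate", {
  expect_error(binding_component(0, 1e-3, 1e5), "strictly positive")
  expect_error(binding_component(1e5, -1, 1e5), "strictly positive")
  cm <- binding_component(5.06e5, 5.61e-3, 3e5)
  expect_equal(cm$Kd, 5.61e-3 / 5.06e5)
  m <- farletuzumab_model()
  expect_equal(m$total_sites, 6e5)
  expect_equal(m$components[[2]]$Kd * 1e9, 2.23, tolerance = 0.01)
  expect_error(binding_model(list(1)), "binding_component")
})

test_that("assay protocols validate their events", {
  expect_error(assay_protocol(1e6, 2, 0.4,
    data.frame(time_h = 1, action = "explode", value = 1)), "unknown")
  expect_error(assay_protocol(1e6, 2, 0.4,
    data.frame(time_h = 1, action = "wash", value = 2)), "fraction")
  expect_error(assay_protocol(1e6, 2, 0.4,
    data.frame(time_h = 1, action = "dilute", value = 0)), "positive")
  p <- cell_binding_protocol(1)
  expect_s3_class(p, "assay_protocol")
  expect_true("measure" %in% p$events$action)
})

test_that("ODE steady state matches the algebraic equilibrium oracle", {
  m <- simple_model()
  eq <- equilibrium_binding(m, 0.4, cells = 2e6, volume_mL = 2)
  p <- assay_protocol(2e6, 2, 0.4, t_end_h = 30)
  tc <- simulate_assay(p, m, dt_h = 0.1)
  expect_equal(tc$bound_total[nrow(tc)], eq$bound_total, tolerance = 1e-3)
  expect_equal(tc$free_M[nrow(tc)], eq$free_M, tolerance = 1e-3)
  ## no-depletion closed form
  eq0 <- equilibrium_binding(m, 0.4, cells = 0)
  L0 <- 0.4e-6 / 150000 * 1000
  expect_equal(eq0$bound_total, 2e5 * L0 / (L0 + m$components[[1]]$Kd),
               tolerance = 1e-9)
})

test_that("mass balance is conserved through washes and dilutions", {
  ev <- data.frame(time_h = c(1, 1.5, 2),
                   action = c("wash", "dilute", "measure"),
                   value = c(0.9, 4, NA))
  tc <- simulate_assay(assay_protocol(2e6, 2, 0.4, ev))
  expect_lt(attr(tc, "mass_balance_drift"), 1e-6)
  expect_gt(attr(tc, "removed_molecules"), 0)
})

test_that("wash removes free ligand and bound decays at k_off afterwards", {
  m <- simple_model()
  ev <- data.frame(time_h = c(2, 3), action = c("wash", "measure"),
                   value = c(1, NA))
  tc <- simulate_assay(assay_protocol(2e6, 2, 0.4, ev), m, dt_h = 0.01)
  i_wash <- max(which(tc$time_h <= 2))
  after <- tc$time_h > 2 + 1e-9
  ## free stays low after a full wash (only dissociation-released ligand,
  ## which partially re-equilibrates)
  expect_lt(max(tc$free_M[after]), 0.1 * max(tc$free_M))
  ## bound follows exp(-k_off t) within a small rebinding correction
  b0 <- tc$bound_total[i_wash]
  b1 <- measured_bound(tc)
  expect_equal(b1 / b0, exp(-2e-3 * 3600), tolerance = 0.05)
})

test_that("canonical 1 h protocol lands in the expected range", {
  tc <- simulate_assay(cell_binding_protocol(1))
  b <- measured_bound(tc)
  expect_gt(b, 1e5)
  expect_lt(b, 2.5e5)
  ## longer incubation binds more
  b4 <- measured_bound(simulate_assay(cell_binding_protocol(4)))
  expect_gt(b4, b)
})

test_that("saturation curve plateaus near total sites", {
  m <- simple_model()
  sat <- saturation_curve(c(0.1, 1, 10, 100), m, incubation_h = 4)
  expect_true(all(diff(sat$bound_per_cell) > 0))
  expect_gt(sat$bound_per_cell[4], 0.95 * 2e5)
  expect_error(saturation_curve(c(-1, 1)), "positive")
})

test_that("labeling arithmetic", {
  ls <- labeling_spec()
  lf <- labeled_fraction(ls)
  expect_equal(lf$ratio, 46.614, tolerance = 1e-4)
  expect_equal(lf$fraction * lf$ratio, 1)
  ## numeric shorthand
  expect_equal(labeled_fraction(2.3)$ratio, lf$ratio)
  ## doubling the specific activity halves the ratio
  expect_equal(labeled_fraction(4.6)$ratio, lf$ratio / 2, tolerance = 1e-12)
  expect_error(labeling_spec(1e6), "theoretical maximum")
  expect_equal(labeled_fraction(labeling_spec(0))$fraction, 0)
})

test_that("IRF assay gives a substantial but sub-unity apparent fraction", {
  irf <- simulate_irf_assay()
  expect_gt(irf$irf, 0.3)
  expect_lt(irf$irf, 0.8)
  ## longer washing dissociates more: apparent IRF decreases
  irf_long <- simulate_irf_assay(wash_min = 40)
  expect_lt(irf_long$irf, irf$irf)
  expect_error(simulate_irf_assay(n_dilutions = 1), "4 dilution")
})
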