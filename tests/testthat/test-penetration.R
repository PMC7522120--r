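test_that("microtumor_spec validates and derives site concentrations", {
  expect_error(microtumor_spec(0), "positive")
  expect_error(microtumor_spec(50, void_fraction = 0), "void fraction")
  expect_error(microtumor_spec(50, void_fraction = 1.5), "void fraction")
  sp <- microtumor_spec(50)
  ## 1e-3 cells/um^3 x 3e5 sites/cell -> ~0.5 uM per component
  expect_equal(sp$c_sites_M, rep(4.9816e-7, 2), tolerance = 1e-4)
})

test_that("grid coarser than 2 um is refused", {
  sp <- microtumor_spec(50)
  expect_error(simulate_penetration(sp, 1e-9, dr = 5), "2 um")
})

test_that("closed-bath system conserves antibody", {
  sp <- microtumor_spec(30)
  f <- simulate_penetration(sp, 2.9e-9, 0, t_end_h = 24, dr = 2,
                            bath_volume_mL = 0.001)
  eps <- sp$void_fraction
  tumor_mol <- vapply(seq_along(f$times_h), function(i) {
    conc <- Reduce(`+`, lapply(f$b, function(m) m[i, ])) + eps * f$L[i, ]
    sum(conc * 4 * pi * f$radii_um^2 * f$dr) * 1e-15  # (mol/L) x L
  }, numeric(1))
  bath_mol <- f$bath_trace * 0.001e-3
  tot <- tumor_mol + bath_mol
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-8)
})

test_that("binding-site barrier confines early uptake to the periphery", {
  sp <- microtumor_spec(150)
  f <- simulate_penetration(sp, 2.9e-9, bath_lambda_s = 0, t_end_h = 6, dr = 2)
  b <- Reduce(`+`, lapply(f$b, function(m) m[nrow(m), ]))
  ## surface-to-center contrast of orders of magnitude at 6 h
  expect_gt(b[length(b)] / max(b[1], 1e-300), 1e3)
  ## bound profile increases monotonically toward the surface
  expect_true(all(diff(b) > -1e-15))
})

test_that("inert antibody reaches the free-diffusion limit", {
  sp <- microtumor_spec(30, model = inert_model())
  C0 <- 2.9e-9
  f <- simulate_penetration(sp, C0, 0, t_end_h = 1, dr = 1.5)
  ## D/eps-free diffusion time R^2/D = 90 s << 1 h: interstitium equilibrates
  expect_equal(as.numeric(f$L[nrow(f$L), 1]), C0, tolerance = 0.01)
})

test_that("cumulated decay density integrates the field correctly", {
  sp <- microtumor_spec(40)
  f <- simulate_penetration(sp, 2.9e-9, bath_lambda_s = 1.068e-4, dr = 2)
  d <- cumulated_decay_density(f)
  expect_equal(nrow(d), length(f$radii_um))
  expect_true(all(d$decays_per_um3 >= 0))
  expect_gt(max(d$decays_per_um3), 0)
  ## doubling the specific activity doubles the labeled fraction and the
  ## decay density (linear functional of the field)
  d2 <- cumulated_decay_density(f, labeling_spec(4.6))
  expect_equal(d2$decays_per_um3, 2 * d$decays_per_um3, tolerance = 1e-12)
})

test_that("per-cell uptake profiles are consistent", {
  sp <- microtumor_spec(40)
  f <- simulate_penetration(sp, 2.9e-9, 0, t_end_h = 12, dr = 2)
  prof <- bound_per_cell_profile(f)
  expect_equal(surface_uptake_per_cell(f), prof$bound_per_cell[nrow(prof)])
  ## per-cell bound cannot exceed total sites per cell
  expect_true(all(prof$bound_per_cell <= 6e5 * (1 + 1e-6)))
  ## total uptake at least the bound part implied by the profile
  tot <- total_uptake(f)
  bound_only <- sum(prof$bound_per_cell * sp$cell_density_per_um3 *
                      4 * pi * f$radii_um^2 * f$dr)
  expect_gt(tot, bound_only * 0.999)
  expect_lt(tot, bound_only * 1.2)
})
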