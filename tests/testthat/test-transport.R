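test_that("cell_geometry validates", {
  expect_s3_class(cell_geometry(), "cell_geometry")
  expect_error(cell_geometry(5, 7), "nucleus_radius")
  expect_error(cell_geometry(5, 0), "nucleus_radius")
})

test_that("sphere crossing chords are geometrically correct", {
  ## radial ray through the center: chord = 2R, entry at r - R
  cr <- atdosim:::.sphere_crossing(10, 1, 4)
  expect_equal(cr$s1, 6)
  expect_equal(cr$s2, 14)
  ## outward ray from outside: no crossing
  cr2 <- atdosim:::.sphere_crossing(10, -1, 4)
  expect_equal(cr2$s2 - cr2$s1, 0)
  ## rays from inside the sphere: entry clamped to 0; the inward ray
  ## (mu = 1) exits through the far side, the outward ray (mu = -1)
  ## through the near side
  cr3 <- atdosim:::.sphere_crossing(2, 1, 4)
  expect_equal(cr3$s1, 0)
  expect_equal(cr3$s2, 6)
  cr3b <- atdosim:::.sphere_crossing(2, -1, 4)
  expect_equal(cr3b$s2, 2)
  ## chord length never exceeds the diameter
  mu <- seq(-1, 1, length.out = 201)
  cr4 <- atdosim:::.sphere_crossing(rep(7.5, 201), mu, 5)
  expect_true(all(cr4$s2 - cr4$s1 <= 10 + 1e-12))
})

test_that("equilibrium dose closed form", {
  ## 1 decay/mL deposits Ebar locally in 1e-3 kg
  sch <- at211_scheme()
  expect_equal(equilibrium_dose(1, sch),
               6.78956 * 1.602176634e-13 / 1e-3, tolerance = 1e-6)
  expect_error(equilibrium_dose(-1, sch), "non-negative")
})

test_that("bath MC matches the homogeneous closed form within 3 SE", {
  cum <- 7.489e9
  mc <- dose_bath_to_nucleus(cum, n_histories = 2e5, seed = 42,
                             include_cell_volume = TRUE)
  expect_lt(abs(mc$dose_Gy - equilibrium_dose(cum)), 3 * mc$se_Gy)
  ## excluding the cell volume must lower the dose
  mc_ex <- dose_bath_to_nucleus(cum, n_histories = 2e5, seed = 42)
  expect_lt(mc_ex$dose_Gy, mc$dose_Gy)
})

test_that("MC estimators are seed-reproducible and preserve the RNG state", {
  set.seed(999)
  before <- .Random.seed
  a <- dose_bath_to_nucleus(1e9, n_histories = 1e4, seed = 3)
  expect_identical(.Random.seed, before)
  b <- dose_bath_to_nucleus(1e9, n_histories = 1e4, seed = 3)
  c_ <- dose_bath_to_nucleus(1e9, n_histories = 1e4, seed = 4)
  expect_identical(a$dose_Gy, b$dose_Gy)
  expect_false(identical(a$dose_Gy, c_$dose_Gy))
  expect_error(dose_bath_to_nucleus(1e9, n_histories = 100), "1e4")
})

test_that("surface S value agrees with the deterministic quadrature oracle", {
  q <- s_value_surface_quadrature()
  mc <- s_value_surface_to_nucleus(n_histories = 2e5, seed = 5)
  expect_lt(abs(mc$s_value_Gy - q), 3 * mc$se_Gy)
  expect_gt(q, 0)
})

test_that("sphere_source validates", {
  expect_error(sphere_source(-1), "positive")
  expect_error(sphere_source(50, radii = c(0, 50), density = c(-1, 1)),
               "non-negative")
  expect_error(sphere_source(50, radii = c(10, 50), density = c(1, 1)),
               "cover")
  expect_s3_class(sphere_source(50, c(0, 50), c(1, 1), 0), "sphere_source")
})

test_that("uniform-sphere profile approaches equilibrium dose at depth", {
  ## tumor much larger than the alpha range, uniform internal source, no
  ## bath: shells deeper than one range from the surface see the
  ## infinite-medium dose
  d <- 0.5                              # decays/um^3
  src <- sphere_source(160, c(0, 160), c(d, d), bath_conc = 0)
  prof <- dose_profile_sphere(src, shell_width = 5, n_histories = 2e5,
                              seed = 9)
  deep <- prof$r_hi <= 160 - 75
  eq <- equilibrium_dose(d * 1e12)
  expect_true(all(abs(prof$dose_Gy[deep] - eq) <
                    pmax(4 * prof$se_Gy[deep], 0.05 * eq)))
  ## surface shell sees roughly half the equilibrium dose
  expect_lt(prof$dose_Gy[nrow(prof)], 0.7 * eq)
  expect_gt(prof$dose_Gy[nrow(prof)], 0.3 * eq)
  ## attributes are consistent
  expect_equal(attr(prof, "min_dose_Gy"), min(prof$dose_Gy))
  expect_gt(attr(prof, "mean_dose_Gy"), 0)
})

test_that("bath-only profile deposits only within alpha reach of the surface", {
  src <- sphere_source(150, bath_conc = 1e9)
  prof <- dose_profile_sphere(src, shell_width = 5, n_histories = 5e4,
                              seed = 2)
  inner <- prof$r_hi <= 150 - 72
  expect_true(all(prof$dose_Gy[inner] == 0))
  expect_gt(prof$dose_Gy[nrow(prof)], 0)
})
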