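test_that("therapy_outcome validates", {
  expect_error(therapy_outcome("x", 10, 11), "0..n")
  expect_error(therapy_outcome("x", 2, 0,
    data.frame(day = c(10, 20, 30))), "more events")
  expect_error(therapy_outcome("x", 5, 0, data.frame(day = 200)),
               "censoring")
})

test_that("reference groups reproduce the printed tumor-free fractions", {
  gs <- ovarian_therapy_groups()
  pct <- vapply(gs, function(g) tumor_free_fraction(g)$percent, integer(1))
  expect_equal(unname(pct), c(91L, 14L, 9L, 12L))
  expect_equal(tumor_free_fraction(gs$A)$fraction, 20 / 22)
})

test_that("fisher_exact matches stats::fisher.test on random tables", {
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    a <- sample(0:n1, 1); c_ <- sample(0:n2, 1)
    g1 <- therapy_outcome("1", n1, a)
    g2 <- therapy_outcome("2", n2, c_)
    mine <- fisher_exact(g1, g2)$p_value
    ref <- stats::fisher.test(matrix(c(a, n1 - a, c_, n2 - c_), 2,
                                     byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("fisher_exact reproduces the printed comparisons", {
  gs <- ovarian_therapy_groups()
  expect_equal(fisher_exact(gs$A, gs$D)$p_value, 1.307e-4, tolerance = 1e-3)
  expect_lt(fisher_exact(gs$A, gs$B)$p_value, 1e-4)
  expect_lt(fisher_exact(gs$A, gs$C)$p_value, 1e-4)
})

test_that("logrank matches survival::survdiff", {
  skip_if_not_installed("survival")
  gs <- ovarian_therapy_groups()
  check <- function(g1, g2) {
    mine <- logrank(g1, g2)
    df <- rbind(cbind(atdosim:::.surv_rows(g1), grp = 1),
                cbind(atdosim:::.surv_rows(g2), grp = 2))
    ref <- survival::survdiff(survival::Surv(time, status) ~ grp, data = df)
    expect_equal(mine$chisq, ref$chisq, tolerance = 1e-9)
  }
  check(gs$A, gs$C)
  check(gs$A, gs$D)
  check(gs$B, gs$C)
  ## and on a random configuration with ties
  set.seed(7)
  g1 <- therapy_outcome("1", 12, 4,
    data.frame(day = sort(sample(90:150, 5, replace = TRUE))))
  g2 <- therapy_outcome("2", 9, 2,
    data.frame(day = sort(sample(90:150, 4, replace = TRUE))))
  check(g1, g2)
})

test_that("logrank handles the no-event degenerate case", {
  g1 <- therapy_outcome("1", 5, 5)
  g2 <- therapy_outcome("2", 5, 5)
  res <- logrank(g1, g2)
  expect_equal(res$p_value, 1)
})

test_that("dual-label decomposition inverts a known mixture", {
  eff <- matrix(c(0.40, 0.03, 0.06, 0.25), 2, byrow = TRUE)
  A_true <- c(150, 80)
  counts <- as.numeric(eff %*% A_true)
  expect_equal(decompose_dual_label(counts, eff), A_true, tolerance = 1e-9)
  ## with decay to counting time
  dec <- exp(-log(2) / c(7.21, 59.4) * 5)
  counts5 <- as.numeric(eff %*% (A_true * dec))
  expect_equal(decompose_dual_label(counts5, eff, t_h = 5), A_true,
               tolerance = 1e-9)
  expect_error(decompose_dual_label(c(1, 1),
    matrix(c(1, 1, 2, 2), 2, byrow = TRUE)), "singular")
})

test_that("residence time recovers the analytic mono-exponential integral", {
  sch <- at211_scheme()
  lam <- decay_constant(sch) * 3600
  t <- c(1, 3, 10, 22)
  ## organ holds a constant decay-corrected fraction f0
  f0 <- 0.05
  res <- residence_time_and_organ_dose(t, rep(f0, 4), 0.2, 7e5, sch)
  exact <- f0 / lam                      # ∫ f0 e^{-lam t} dt over [0, Inf)
  expect_equal(res$residence_time_h, exact, tolerance = 0.03)
  ## dose consistency: cumulated decays x mean alpha energy / mass
  expect_equal(res$dose_Gy,
               res$cumulated_Bq_s * mean_alpha_energy(sch) *
                 1.602176634e-13 / 2e-4, tolerance = 1e-9)
})

test_that("uptake regression recovers a noiseless linear relation", {
  cells <- c(5, 20, 50, 120, 300, 400)
  act <- 0.086 * cells
  r <- uptake_regression(cells, act)
  expect_equal(r$slope_Bq_per_cell, 0.086, tolerance = 1e-9)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  expect_true(r$ci[1] <= 0.086 && 0.086 <= r$ci[2])
  expect_error(uptake_regression(1:2, 1:2), ">= 3")
})
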