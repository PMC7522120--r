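## Seeded Monte-Carlo estimation of absorbed dose to cell nuclei and
## spherical microtumors from 211At decays in a surrounding bath, on the
## cell surface, or distributed radially inside a tumor.
##
## All estimators share the same track engine: decay positions are sampled
## from the source distribution, one alpha is emitted isotropically per
## decay with a branch-sampled energy, and energy is scored along a straight
## continuous-slowing-down track by residual-energy differencing at the
## target-boundary crossings. Geometry is concentric spheres, so positions
## can be placed on the z axis without loss of generality.

#' Concentric cell/nucleus geometry
#'
#' @param cell_radius cell radius in um (default 7.5, a typical epithelial
#'   tumor cell).
#' @param nucleus_radius nucleus radius in um (default 5), concentric with
#'   the cell; must not exceed the cell radius.
#' @return object of class `cell_geometry`.
#' @export
cell_geometry <- function(cell_radius = 7.5, nucleus_radius = 5) {
  if (!(nucleus_radius > 0 && nucleus_radius <= cell_radius))
    stop("need 0 < nucleus_radius <= cell_radius")
  structure(list(cell_radius = cell_radius, nucleus_radius = nucleus_radius),
            class = "cell_geometry")
}

## nucleus mass in kg (unit-density water)
.nucleus_mass_kg <- function(geom) 4 / 3 * pi * geom$nucleus_radius^3 * .UM3_TO_G / 1000

## Sample branch energies for n decays
.sample_energies <- function(n, scheme) {
  br <- scheme$branches
  idx <- sample.int(nrow(br), n, replace = TRUE, prob = br$prob)
  br$energy_MeV[idx]
}

## Chord of a ray (origin at z = r on the axis, direction cosine mu toward
## -z measured against the inward radial direction) through a concentric
## sphere of radius R: returns entry/exit path lengths (0 if no crossing).
## Vectorized over histories.
.sphere_crossing <- function(r, mu, R) {
  ## position p = (0,0,r); direction u with u_z = -mu (mu = cos of angle to
  ## the inward radial); p.u = -r*mu. |p|^2 = r^2.
  c_ <- -r * mu
  disc <- c_^2 - (r^2 - R^2)
  hit <- disc > 0
  sq <- sqrt(pmax(disc, 0))
  s1 <- pmax(-c_ - sq, 0)
  s2 <- pmax(-c_ + sq, 0)
  s1[!hit] <- 0; s2[!hit] <- 0
  list(s1 = s1, s2 = s2)
}

#' Equilibrium absorbed dose from a uniform cumulated decay concentration
#'
#' Closed-form infinite homogeneous-medium dose: every decay's alpha energy
#' is absorbed locally, so \eqn{D = \tilde{C} \bar{E}_\alpha / \rho}. Serves
#' as the analytic oracle for the Monte-Carlo bath estimator.
#'
#' @param cumulated_conc time-integrated decay concentration (decays/mL).
#' @param scheme a [decay_scheme()].
#' @return absorbed dose in Gy.
#' @export
equilibrium_dose <- function(cumulated_conc, scheme = at211_scheme()) {
  if (any(cumulated_conc < 0)) stop("cumulated concentration must be non-negative")
  ## decays/mL * MeV/decay * J/MeV / (1e-3 kg/mL)
  cumulated_conc * mean_alpha_energy(scheme) * .MEV_TO_J / 1e-3
}

#' Monte-Carlo nucleus dose for a cell in a uniform activity bath
#'
#' A single cell (water-equivalent, concentric nucleus) is immersed in an
#' effectively infinite uniform bath of cumulated decay concentration
#' `cumulated_conc`. Decays occur in the bath only (the cell volume is
#' excluded); positions are sampled in a shell reaching one maximum alpha
#' range (plus margin) beyond the cell, emission is isotropic, and energy
#' deposited in the nucleus is scored.
#'
#' @param cumulated_conc decays/mL in the bath.
#' @param geom a [cell_geometry()].
#' @param scheme a [decay_scheme()].
#' @param model a [stopping_power_water()] model.
#' @param n_histories number of decay histories (>= 1e4).
#' @param seed integer seed; identical seeds give bit-identical results.
#' @param include_cell_volume if TRUE the bath fills all space including the
#'   cell (homogeneous-medium limit used in validation).
#' @return list with `dose_Gy`, `se_Gy`, `n_histories`.
#' @export
dose_bath_to_nucleus <- function(cumulated_conc, geom = cell_geometry(),
                                 scheme = at211_scheme(),
                                 model = stopping_power_water(),
                                 n_histories = 1e5, seed = 1,
                                 include_cell_volume = FALSE) {
  if (cumulated_conc < 0) stop("cumulated concentration must be non-negative")
  if (n_histories < 1e4) stop("need at least 1e4 histories")
  e_top <- max(scheme$branches$energy_MeV)
  r_max <- csda_range(e_top, model)
  r_in <- if (include_cell_volume) 0 else geom$cell_radius
  r_out <- geom$cell_radius + r_max + 5
  if (r_out <= r_in) stop("sampling shell is empty")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  r <- (runif(n_histories, r_in^3, r_out^3))^(1 / 3)
  mu <- runif(n_histories, -1, 1)
  E0 <- .sample_energies(n_histories, scheme)
  cr <- .sphere_crossing(r, mu, geom$nucleus_radius)
  dep <- deposit_along_track(E0, cr$s1, cr$s2, model)

  v_shell_ml <- 4 / 3 * pi * (r_out^3 - r_in^3) / .UM3_PER_ML
  decays_total <- cumulated_conc * v_shell_ml
  scale <- decays_total / n_histories * .MEV_TO_J / .nucleus_mass_kg(geom)
  list(dose_Gy = sum(dep) * scale,
       se_Gy = sd(dep) * sqrt(n_histories) * scale,
       n_histories = n_histories)
}

#' Monte-Carlo S value, cell surface to nucleus
#'
#' Mean absorbed dose to the nucleus per decay uniformly distributed on the
#' cell surface with isotropic alpha emission.
#'
#' @inheritParams dose_bath_to_nucleus
#' @return list with `s_value_Gy` (Gy per decay), `se_Gy`, `n_histories`.
#' @export
s_value_surface_to_nucleus <- function(geom = cell_geometry(),
                                       scheme = at211_scheme(),
                                       model = stopping_power_water(),
                                       n_histories = 1e5, seed = 1) {
  if (n_histories < 1e4) stop("need at least 1e4 histories")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  mu <- runif(n_histories, -1, 1)
  E0 <- .sample_energies(n_histories, scheme)
  cr <- .sphere_crossing(rep(geom$cell_radius, n_histories), mu, geom$nucleus_radius)
  dep <- deposit_along_track(E0, cr$s1, cr$s2, model)
  scale <- .MEV_TO_J / .nucleus_mass_kg(geom)
  list(s_value_Gy = mean(dep) * scale,
       se_Gy = sd(dep) / sqrt(n_histories) * scale,
       n_histories = n_histories)
}

#' Deterministic quadrature oracle for the surface-to-nucleus S value
#'
#' Independent check of [s_value_surface_to_nucleus()]: integrates the
#' nucleus energy deposit over the emission direction cosine on a fine grid
#' (by spherical symmetry the emission point can be fixed).
#'
#' @inheritParams s_value_surface_to_nucleus
#' @param n_mu number of direction-cosine quadrature nodes.
#' @return S value in Gy per decay.
#' @export
s_value_surface_quadrature <- function(geom = cell_geometry(),
                                       scheme = at211_scheme(),
                                       model = stopping_power_water(),
                                       n_mu = 20001) {
  mu <- seq(-1, 1, length.out = n_mu)
  dep_for <- function(E0) {
    cr <- .sphere_crossing(rep(geom$cell_radius, n_mu), mu, geom$nucleus_radius)
    mean(deposit_along_track(E0, cr$s1, cr$s2, model))
  }
  br <- scheme$branches
  e_mean <- sum(br$prob * vapply(br$energy_MeV, dep_for, numeric(1)))
  e_mean * .MEV_TO_J / .nucleus_mass_kg(geom)
}

#' Radial source description for a spherical microtumor
#'
#' @param tumor_radius tumor radius in um.
#' @param radii radial grid (um) covering `[0, tumor_radius]` for the
#'   tumor-resident source density. May be NULL for a bath-only source.
#' @param density cumulated decay density on `radii` (decays/um^3),
#'   non-negative.
#' @param bath_conc cumulated decay concentration of the surrounding medium
#'   (decays/mL); the bath also fills the tumor interstitium only insofar as
#'   `density` says so (the two sources are independent).
#' @return object of class `sphere_source`.
#' @export
sphere_source <- function(tumor_radius, radii = NULL, density = NULL,
                          bath_conc = 0) {
  if (tumor_radius <= 0) stop("tumor radius must be positive")
  if (bath_conc < 0) stop("bath concentration must be non-negative")
  if (!is.null(radii)) {
    stopifnot(length(radii) == length(density))
    if (any(density < 0)) stop("densities must be non-negative")
    if (min(radii) > 1e-9 || max(radii) < tumor_radius - 1e-9)
      stop("radial grid must cover [0, tumor_radius]")
  }
  structure(list(tumor_radius = tumor_radius, radii = radii,
                 density = density, bath_conc = bath_conc),
            class = "sphere_source")
}

## Per-history cumulative energy within each scoring radius, chunked to
## bound memory. r, mu, E0: history vectors; edges: scoring sphere radii.
## Returns list(sum = per-edge energy sums, sumsq = per-edge sums of squares).
.score_cumulative <- function(r, mu, E0, edges, model, chunk = 50000L) {
  n <- length(r)
  k <- length(edges)
  tot <- numeric(k); totsq <- numeric(k)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    idx <- i:j
    dep <- matrix(0, length(idx), k)
    for (m in seq_len(k)) {
      cr <- .sphere_crossing(r[idx], mu[idx], edges[m])
      dep[, m] <- deposit_along_track(E0[idx], cr$s1, cr$s2, model)
    }
    tot <- tot + colSums(dep)
    ## shellwise deposit for variance: difference of cumulative columns
    sh <- dep - cbind(0, dep[, -k, drop = FALSE])
    totsq <- totsq + colSums(sh^2)
    i <- j + 1L
  }
  list(sum = tot, sumsq = totsq)
}

#' Monte-Carlo radial dose profile of a spherical microtumor
#'
#' Scores the absorbed dose in concentric shells of a spherical tumor from
#' two independent source terms: cumulated decays distributed radially
#' inside the tumor (typically the output of the penetration model) and a
#' uniform bath surrounding it. Shell doses are mass-weighted mean doses;
#' standard errors are propagated per source term.
#'
#' @param src a [sphere_source()].
#' @param shell_width radial scoring resolution in um (a warning is issued
#'   above 5 um, coarse relative to the alpha range).
#' @inheritParams dose_bath_to_nucleus
#' @return object of class `radial_dose_profile`: data.frame of shell
#'   mid-radii, dose (Gy) and Monte-Carlo standard error, with the
#'   mass-weighted mean and minimum shell dose as attributes.
#' @export
dose_profile_sphere <- function(src, shell_width = 5,
                                scheme = at211_scheme(),
                                model = stopping_power_water(),
                                n_histories = 1e5, seed = 1) {
  stopifnot(inherits(src, "sphere_source"))
  if (shell_width > 5 + 1e-9)
    warning("radial scoring coarser than 5 um is coarse relative to the alpha range")
  R_t <- src$tumor_radius
  edges <- seq(0, R_t, by = shell_width)
  if (abs(edges[length(edges)] - R_t) > 1e-9) edges <- c(edges, R_t)
  edges <- edges[-1]                       # scoring sphere radii
  k <- length(edges)
  shell_lo <- c(0, edges[-k])
  vol_um3 <- 4 / 3 * pi * (edges^3 - shell_lo^3)
  mass_kg <- vol_um3 * .UM3_TO_G / 1000

  e_top <- max(scheme$branches$energy_MeV)
  r_max <- csda_range(e_top, model)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  run_source <- function(sample_r, decays_total, n_hist) {
    if (decays_total <= 0 || n_hist == 0)
      return(list(dose = numeric(k), se = numeric(k)))
    r <- sample_r(n_hist)
    mu <- runif(n_hist, -1, 1)
    E0 <- .sample_energies(n_hist, scheme)
    sc <- .score_cumulative(r, mu, E0, edges, model)
    shell_sum <- diff(c(0, sc$sum))
    scale <- decays_total / n_hist * .MEV_TO_J
    mean_e <- shell_sum / n_hist
    var_e <- pmax(sc$sumsq / n_hist - mean_e^2, 0)
    list(dose = shell_sum * scale / mass_kg,
         se = sqrt(var_e / n_hist) * decays_total * .MEV_TO_J / mass_kg)
  }

  ## tumor-resident source: sample radius with prob ~ density(r) r^2
  tum <- list(dose = numeric(k), se = numeric(k)); n_tum_decays <- 0
  if (!is.null(src$radii) && any(src$density > 0)) {
    ## refine the radial grid so the piecewise-linear CDF inversion is
    ## accurate regardless of how coarse the supplied grid is
    rr <- seq(min(src$radii), max(src$radii), length.out = 2049)
    dd <- approx(src$radii, src$density, rr)$y
    w <- dd * rr^2
    ## total decays by trapezoid of 4 pi r^2 density
    n_tum_decays <- 4 * pi * sum(diff(rr) * (w[-1] + w[-length(w)]) / 2)
    cdf <- cumsum(c(0, diff(rr) * (w[-1] + w[-length(w)]) / 2))
    cdf <- cdf / cdf[length(cdf)]
    inv <- approxfun(cdf, rr, rule = 2)
    tum <- run_source(function(n) inv(runif(n)), n_tum_decays, n_histories)
  }

  ## bath source: uniform shell outside the tumor within alpha reach
  bath <- list(dose = numeric(k), se = numeric(k))
  if (src$bath_conc > 0) {
    r_out <- R_t + r_max + 5
    v_ml <- 4 / 3 * pi * (r_out^3 - R_t^3) / .UM3_PER_ML
    bath <- run_source(function(n) runif(n, R_t^3, r_out^3)^(1 / 3),
                       src$bath_conc * v_ml, n_histories)
  }

  dose <- tum$dose + bath$dose
  se <- sqrt(tum$se^2 + bath$se^2)
  prof <- data.frame(r_mid = (edges + shell_lo) / 2,
                     r_lo = shell_lo, r_hi = edges,
                     dose_Gy = dose, se_Gy = se)
  structure(prof,
            class = c("radial_dose_profile", "data.frame"),
            mean_dose_Gy = sum(dose * mass_kg) / sum(mass_kg),
            min_dose_Gy = min(dose),
            tumor_radius = R_t,
            tumor_decays = n_tum_decays)
}

#' @export
print.radial_dose_profile <- function(x, ...) {
  cat("Radial dose profile, tumor radius", attr(x, "tumor_radius"), "um\n")
  cat(sprintf("  mean dose %.2f Gy, minimum shell dose %.2f Gy\n",
              attr(x, "mean_dose_Gy"), attr(x, "min_dose_Gy")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.radial_dose_profile <- function(x, ...) {
  plot(x$r_mid, x$dose_Gy, type = "b", xlab = "radius (um)",
       ylab = "absorbed dose (Gy)", ...)
  invisible(x)
}

## RNG bookkeeping: MC helpers seed deterministically but must not clobber
## the caller's RNG stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
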