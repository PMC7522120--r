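## Reaction-diffusion model of radiolabeled-antibody penetration into
## spherical microtumors (the binding-site barrier). Free antibody diffuses
## through the accessible interstitial fraction and binds reversibly to
## immobile antigen; antigen density vastly exceeds the free antibody
## concentration, so penetration is retarded by orders of magnitude and
## bound antibody concentrates near the tumor surface.

#' Microtumor tissue specification
#'
#' @param radius_um tumor radius.
#' @param cell_density_per_um3 cells per um^3 of tissue (default 1e-3, i.e.
#'   1e6 cells/mm^3, tightly packed ~12 um cells).
#' @param void_fraction accessible interstitial volume fraction in (0, 1].
#' @param diffusivity_um2_s free-antibody interstitial diffusivity.
#' @param model a [binding_model()] supplying sites per cell.
#' @return object of class `microtumor_spec` with derived per-component
#'   site concentrations (mol/L of tissue).
#' @export
microtumor_spec <- function(radius_um, cell_density_per_um3 = 1e-3,
                            void_fraction = 0.2, diffusivity_um2_s = 10,
                            model = farletuzumab_model()) {
  if (radius_um <= 0) stop("radius must be positive")
  if (void_fraction <= 0 || void_fraction > 1) stop("void fraction must be in (0, 1]")
  sites <- vapply(model$components, `[[`, numeric(1), "sites_per_cell")
  c_sites_M <- cell_density_per_um3 * sites * 1e15 / .AVOGADRO
  structure(list(radius_um = radius_um,
                 cell_density_per_um3 = cell_density_per_um3,
                 void_fraction = void_fraction,
                 diffusivity_um2_s = diffusivity_um2_s,
                 model = model, c_sites_M = c_sites_M),
            class = "microtumor_spec")
}

#' Simulate antibody penetration into a spherical microtumor
#'
#' Solves the spherically symmetric reaction-diffusion system: free
#' antibody diffuses in the interstitium with the bath concentration as
#' the boundary value, and binds reversibly to each immobile antigen class.
#' Binding inside the tumor does not deplete an infinite bath (the default;
#' the cavity volume is much larger than the tumor); a finite
#' `bath_volume_mL` gives a closed system used for mass-conservation
#' checks.
#'
#' @param spec a [microtumor_spec()].
#' @param bath_conc_M initial bath antibody concentration (mol/L).
#' @param bath_lambda_s first-order decline rate of the bath antibody mass
#'   concentration (biological escape; physical decay of the label is
#'   applied later, in [cumulated_decay_density()]).
#' @param t_end_h simulated time.
#' @param dr radial grid spacing in um (must resolve <= 2 um).
#' @param nt_out number of stored time points.
#' @param bath_volume_mL finite bath volume for the closed-system variant
#'   (default `Inf`: prescribed bath).
#' @return object of class `radial_bound_field`: radii (cell centers),
#'   times, free-concentration matrix `L` (M, time x radius), per-component
#'   bound arrays `b` (mol/L of tissue), and the spec.
#' @export
simulate_penetration <- function(spec, bath_conc_M, bath_lambda_s = 0,
                                 t_end_h = 48, dr = 2, nt_out = 120,
                                 bath_volume_mL = Inf) {
  stopifnot(inherits(spec, "microtumor_spec"))
  if (dr > 2 + 1e-9) stop("radial grid must resolve <= 2 um")
  R <- spec$radius_um
  N <- max(3L, ceiling(R / dr))
  dr <- R / N
  r <- (seq_len(N) - 0.5) * dr
  r_face <- seq_len(N) * dr                 # outer face of each cell
  comps <- spec$model$components
  k <- length(comps)
  kon <- vapply(comps, `[[`, numeric(1), "k_on")
  koff <- vapply(comps, `[[`, numeric(1), "k_off")
  cs <- spec$c_sites_M
  D <- spec$diffusivity_um2_s
  eps <- spec$void_fraction
  closed <- is.finite(bath_volume_mL)
  stride <- k + 1

  iL <- (seq_len(N) - 1) * stride + 1
  ib <- lapply(seq_len(k), function(i) iL + i)
  ## geometric factors for the conservative spherical Laplacian
  a_out_full <- c(r_face[-N]^2, 0) / (r^2 * dr^2)   # faces 1..N-1; boundary handled below
  a_in <- c(0, r_face[-N]^2) / (r^2 * dr^2)
  a_bnd <- r_face[N]^2 / (r[N]^2 * dr^2) * 2  # half-spacing to boundary value

  rhs <- function(t, y, parms) {
    L <- y[iL]
    Cb <- if (closed) y[length(y)] else bath_conc_M * exp(-bath_lambda_s * t)
    dif_up <- c(L[-1] - L[-N], 0)
    dif_dn <- c(0, L[-1] - L[-N])
    lap <- a_out_full * dif_up - a_in * dif_dn
    lap[N] <- lap[N] + a_bnd * (Cb - L[N])
    dy <- numeric(length(y))
    react <- 0
    for (i in seq_len(k)) {
      b <- y[ib[[i]]]
      db <- kon[i] * L * (cs[i] - b) - koff[i] * b
      dy[ib[[i]]] <- db
      react <- react + db
    }
    dy[iL] <- D * lap - react / eps
    if (closed) {
      ## M * um^3/s -> mol/s (1 um^3 = 1e-15 L), then back to M/s in the bath
      flux_mol_s <- eps * D * (Cb - L[N]) / (dr / 2) * 4 * pi * R^2 * 1e-15
      dy[length(y)] <- -flux_mol_s / (bath_volume_mL * 1e-3)
    }
    list(dy)
  }

  y0 <- numeric(N * stride + if (closed) 1 else 0)
  if (closed) y0[length(y0)] <- bath_conc_M
  times <- seq(0, t_end_h * 3600, length.out = nt_out)
  sol <- tryCatch(
    lsoda(y0, times, rhs, NULL, rtol = 1e-6, atol = 1e-15,
          jactype = "bandint", bandup = stride, banddown = stride),
    error = function(e) stop("penetration solver failure: ", conditionMessage(e)))
  if (nrow(sol) < length(times))
    stop("penetration solver did not reach t_end (instability despite refinement)")

  L_mat <- sol[, 1 + iL, drop = FALSE]
  b_arr <- lapply(seq_len(k), function(i) sol[, 1 + ib[[i]], drop = FALSE])
  structure(list(radii_um = r, times_h = times / 3600, L = L_mat, b = b_arr,
                 spec = spec, bath_conc_M = bath_conc_M,
                 bath_lambda_s = bath_lambda_s,
                 bath_trace = if (closed) sol[, ncol(sol)] else
                   bath_conc_M * exp(-bath_lambda_s * times),
                 bath_volume_mL = bath_volume_mL, dr = dr),
            class = "radial_bound_field")
}

#' @export
print.radial_bound_field <- function(x, ...) {
  cat(sprintf("Radial antibody field: tumor radius %.0f um, %d radial x %d time points\n",
              x$spec$radius_um, length(x$radii_um), length(x$times_h)))
  b_end <- Reduce(`+`, lapply(x$b, function(m) m[nrow(m), ]))
  cat(sprintf("  final bound at surface %.3g M, at center %.3g M (ratio %.3g)\n",
              b_end[length(b_end)], b_end[1],
              b_end[1] / max(b_end[length(b_end)], 1e-300)))
  invisible(x)
}

#' Cumulated decay density of a penetration field
#'
#' Converts the time-resolved antibody field into the radial density of
#' 211At decays occurring inside the tumor: bound plus interstitial free
#' antibody, weighted by the labeled fraction decaying physically
#' (\eqn{f_0 e^{-\lambda_p t}}), integrated over time (trapezoid plus an
#' analytic tail assuming the field keeps declining at the bath rate).
#'
#' @param field a `radial_bound_field`.
#' @param labeling a [labeling_spec()].
#' @param scheme a [decay_scheme()].
#' @return data.frame with `r_um` and `decays_per_um3`.
#' @export
cumulated_decay_density <- function(field, labeling = labeling_spec(),
                                    scheme = at211_scheme()) {
  lam_p <- decay_constant(scheme)
  f0 <- labeled_fraction(labeling)$fraction
  eps <- field$spec$void_fraction
  conc <- Reduce(`+`, field$b) + eps * field$L       # mol/L of tissue, t x r
  t_s <- field$times_h * 3600
  w <- lam_p * f0 * exp(-lam_p * t_s)
  integrand <- conc * w
  dt <- diff(t_s)
  cum <- colSums((integrand[-1, , drop = FALSE] +
                  integrand[-length(t_s), , drop = FALSE]) / 2 * dt)
  ## tail: field assumed to decline at the bath escape rate after t_end
  cum <- cum + integrand[length(t_s), ] / (lam_p + field$bath_lambda_s)
  decays_um3 <- cum * .AVOGADRO / 1e15               # mol/L -> molecules/um^3
  data.frame(r_um = field$radii_um, decays_per_um3 = decays_um3)
}

#' Bound antibodies per cell across the tumor radius
#'
#' @param field a `radial_bound_field`.
#' @param time_h evaluation time (defaults to the last stored time).
#' @return data.frame with `r_um` and `bound_per_cell`.
#' @export
bound_per_cell_profile <- function(field, time_h = NULL) {
  it <- if (is.null(time_h)) length(field$times_h) else
    which.min(abs(field$times_h - time_h))
  b <- Reduce(`+`, lapply(field$b, function(m) m[it, ]))
  per_um3 <- b * .AVOGADRO / 1e15
  data.frame(r_um = field$radii_um,
             bound_per_cell = per_um3 / field$spec$cell_density_per_um3)
}

#' Peripheral (surface-shell) uptake per cell
#'
#' Bound antibodies per cell in the outermost radial shell; for microtumors
#' up to a couple of cell layers this is the uptake of every cell, so total
#' uptake is proportional to cell number.
#'
#' @inheritParams bound_per_cell_profile
#' @return bound antibodies per cell at the tumor periphery.
#' @export
surface_uptake_per_cell <- function(field, time_h = NULL) {
  prof <- bound_per_cell_profile(field, time_h)
  prof$bound_per_cell[nrow(prof)]
}

#' Total antibody uptake of a microtumor
#'
#' Volume integral of bound plus interstitial free antibody at a given
#' time, in molecules.
#'
#' @inheritParams bound_per_cell_profile
#' @return total molecules in the tumor.
#' @export
total_uptake <- function(field, time_h = NULL) {
  it <- if (is.null(time_h)) length(field$times_h) else
    which.min(abs(field$times_h - time_h))
  conc <- Reduce(`+`, lapply(field$b, function(m) m[it, ])) +
    field$spec$void_fraction * field$L[it, ]
  per_um3 <- conc * .AVOGADRO / 1e15
  r <- field$radii_um; dr <- field$dr
  sum(per_um3 * 4 * pi * r^2 * dr)
}
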