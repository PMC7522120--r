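## Orchestration of pk + binding + penetration + transport: the
## single-cell dose pair (bath and surface-bound), microtumor dose
## profiles, and the sterilization diameter at the 10 Gy eradication
## threshold.

#' Therapy scenario bundle
#'
#' Collects the pharmacokinetics, binding model, labeling and cell
#' geometry describing one treatment scenario.
#'
#' @param pk a [compartment_pk()].
#' @param model a [binding_model()].
#' @param labeling a [labeling_spec()].
#' @param geom a [cell_geometry()].
#' @return object of class `therapy_scenario`.
#' @export
therapy_scenario <- function(pk, model = farletuzumab_model(),
                             labeling = labeling_spec(),
                             geom = cell_geometry()) {
  structure(list(pk = pk, model = model, labeling = labeling, geom = geom),
            class = "therapy_scenario")
}

#' @rdname therapy_scenario
#' @export
mouse_scenario <- function() therapy_scenario(mouse_ip_pk())

#' @rdname therapy_scenario
#' @export
patient_scenario <- function() therapy_scenario(patient_ip_pk())

#' @export
print.therapy_scenario <- function(x, ...) {
  print(x$pk)
  cat(sprintf("  antibody %.3g ug/mL at SA %.2g GBq/mg (1 labeled in %.1f)\n",
              antibody_concentration_M(x$pk, x$labeling) * x$labeling$molar_mass * 1e3,
              x$labeling$specific_activity_GBq_mg,
              labeled_fraction(x$labeling)$ratio))
  invisible(x)
}

#' Time-integrated surface decays per cell for a single suspended cell
#'
#' Runs the binding model for a single cell exposed to the scenario's
#' decaying bath (antibody mass concentration declining at the biological
#' escape rate, no depletion) and integrates the physical decays occurring
#' while bound: \eqn{N_s = \int \lambda_p f_0 B(t) e^{-\lambda_p t} dt},
#' where \eqn{f_0} is the labeled fraction at administration.
#'
#' @param scenario a [therapy_scenario()].
#' @param t_end_h integration horizon.
#' @return list with `decays` and the bound trajectory.
#' @export
surface_decays_per_cell <- function(scenario, t_end_h = 72) {
  pk <- scenario$pk
  model <- scenario$model
  C0 <- antibody_concentration_M(pk, scenario$labeling)
  lam_p <- pk$lambda_phys
  kon <- vapply(model$components, `[[`, numeric(1), "k_on")
  koff <- vapply(model$components, `[[`, numeric(1), "k_off")
  S <- vapply(model$components, `[[`, numeric(1), "sites_per_cell")
  rhs <- function(t, y, p) {
    L <- C0 * exp(-pk$lambda_bio * t)
    list(kon * L * (S - y) - koff * y)
  }
  t_s <- seq(0, t_end_h * 3600, by = 120)
  sol <- lsoda(rep(0, length(S)), t_s, rhs, NULL, rtol = 1e-8, atol = 1e-4)
  B <- rowSums(sol[, -1, drop = FALSE])
  f0 <- labeled_fraction(scenario$labeling)$fraction
  w <- lam_p * f0 * B * exp(-lam_p * t_s)
  decays <- sum((w[-1] + w[-length(w)]) / 2 * diff(t_s)) +
    w[length(w)] / (lam_p + pk$lambda_bio)     # analytic tail
  list(decays = decays, times_h = t_s / 3600, bound = B)
}

#' Single-cell absorbed dose under a therapy scenario
#'
#' The two dose contributions to the nucleus of a single cell suspended in
#' the peritoneal fluid: the bath dose (Monte-Carlo transport from the
#' cumulated decay concentration of the fluid) and the self dose from
#' antibody bound to the cell's own surface (time-integrated surface decays
#' times the Monte-Carlo surface-to-nucleus S value).
#'
#' @param scenario a [therapy_scenario()].
#' @param n_histories Monte-Carlo histories per estimator.
#' @param seed integer seed.
#' @param model_sp a [stopping_power_water()] model.
#' @return list with `bath_Gy`, `bound_Gy`, their standard errors,
#'   `surface_decays` and `s_value_Gy`.
#' @export
single_cell_dose <- function(scenario, n_histories = 2e5, seed = 1,
                             model_sp = stopping_power_water()) {
  cum <- cumulated_decays(scenario$pk)
  bath <- dose_bath_to_nucleus(cum, scenario$geom, scenario$pk$scheme,
                               model_sp, n_histories, seed)
  sv <- s_value_surface_to_nucleus(scenario$geom, scenario$pk$scheme,
                                   model_sp, n_histories, seed + 1)
  sd_ <- surface_decays_per_cell(scenario)
  list(bath_Gy = bath$dose_Gy, bath_se_Gy = bath$se_Gy,
       bound_Gy = sd_$decays * sv$s_value_Gy,
       bound_se_Gy = sd_$decays * sv$se_Gy,
       surface_decays = sd_$decays, s_value_Gy = sv$s_value_Gy)
}

#' Microtumor dose profile under a therapy scenario
#'
#' Combines the penetration model's cumulated-decay field (tumor-resident
#' source) with the scenario's bath source in the sphere transport
#' Monte-Carlo.
#'
#' @param diameter_um tumor diameter.
#' @param scenario a [therapy_scenario()].
#' @param source `"specific"` (binding antibody: penetration field plus
#'   bath) or `"bath_only"` (non-binding antibody: bath plus interstitial
#'   fluid activity at the accessible volume fraction).
#' @param n_histories,seed Monte-Carlo control.
#' @param shell_width scoring resolution (um).
#' @param dr penetration grid spacing (um).
#' @param spec optional [microtumor_spec()] template; its radius is
#'   replaced by `diameter_um / 2`.
#' @param model_sp a [stopping_power_water()] model.
#' @return a `radial_dose_profile` (see [dose_profile_sphere()]).
#' @export
microtumor_dose_profile <- function(diameter_um, scenario = mouse_scenario(),
                                    source = c("specific", "bath_only"),
                                    n_histories = 1e5, seed = 1,
                                    shell_width = 5, dr = 2, spec = NULL,
                                    model_sp = stopping_power_water()) {
  source <- match.arg(source)
  R <- diameter_um / 2
  if (is.null(spec)) {
    spec <- microtumor_spec(R, model = scenario$model)
  } else {
    spec$radius_um <- R
  }
  cum_bath <- cumulated_decays(scenario$pk)
  if (source == "specific") {
    C0 <- antibody_concentration_M(scenario$pk, scenario$labeling)
    field <- simulate_penetration(spec, C0, scenario$pk$lambda_bio, dr = dr)
    dens <- cumulated_decay_density(field, scenario$labeling, scenario$pk$scheme)
    src <- sphere_source(R, radii = c(0, dens$r_um, R),
                         density = c(dens$decays_per_um3[1], dens$decays_per_um3,
                                     dens$decays_per_um3[nrow(dens)]),
                         bath_conc = cum_bath)
  } else {
    ## non-binding antibody: fluid activity fills the interstitium freely
    interstitial <- cum_bath * spec$void_fraction / .UM3_PER_ML
    src <- sphere_source(R, radii = c(0, R),
                         density = rep(interstitial, 2),
                         bath_conc = cum_bath)
  }
  dose_profile_sphere(src, shell_width, scenario$pk$scheme, model_sp,
                      n_histories, seed)
}

#' Sterilization diameter at a dose threshold
#'
#' Scans tumor diameters and reports the largest whose summary absorbed
#' dose reaches the eradication threshold (default 10 Gy). Following the
#' microdosimetry model's output quantity, the summary is the
#' mass-weighted mean dose over the tumor ("mean absorbed dose to
#' microscopic tumors"); the conservative profile minimum is available via
#' `statistic = "min"`.
#'
#' @param scenario a [therapy_scenario()].
#' @param diameters_um diameters to scan.
#' @param threshold_Gy eradication threshold.
#' @param statistic `"mean"` (default) or `"min"` summary of the profile.
#' @param source passed to [microtumor_dose_profile()].
#' @param n_histories,seed,shell_width,dr,model_sp passed through.
#' @return list with `diameter_um` (largest diameter meeting the
#'   threshold; 0 with `crossed = FALSE` if none, and `boundary = TRUE` if
#'   every scanned diameter meets it), and the per-diameter summary doses.
#' @export
sterilization_diameter <- function(scenario = mouse_scenario(),
                                   diameters_um = seq(100, 400, by = 50),
                                   threshold_Gy = 10,
                                   statistic = c("mean", "min"),
                                   source = "specific",
                                   n_histories = 1e5, seed = 1,
                                   shell_width = 5, dr = 2,
                                   model_sp = stopping_power_water()) {
  statistic <- match.arg(statistic)
  if (threshold_Gy < 0) stop("threshold must be non-negative")
  diameters_um <- sort(diameters_um)
  dose <- vapply(seq_along(diameters_um), function(i) {
    prof <- microtumor_dose_profile(diameters_um[i], scenario, source,
                                    n_histories, seed + i, shell_width, dr,
                                    model_sp = model_sp)
    attr(prof, paste0(statistic, "_dose_Gy"))
  }, numeric(1))
  ok <- dose >= threshold_Gy
  if (!any(ok)) {
    res <- list(diameter_um = 0, crossed = FALSE, boundary = FALSE)
  } else {
    ## largest diameter meeting the threshold
    d_ok <- max(diameters_um[ok])
    res <- list(diameter_um = d_ok, crossed = TRUE,
                boundary = d_ok == max(diameters_um))
  }
  res$scan <- data.frame(diameter_um = diameters_um, dose_Gy = dose,
                         meets_threshold = ok)
  res$statistic <- statistic
  res
}
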