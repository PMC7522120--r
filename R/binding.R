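## Multi-component reversible antibody-antigen binding kinetics for
## suspension assays: shared free-ligand depletion, wash schedules,
## saturation analysis, radiolabeling arithmetic and the Lindmo
## immunoreactive-fraction assay.

#' A binding component (one antigen class)
#'
#' @param k_on association rate constant (M^-1 s^-1).
#' @param k_off dissociation rate constant (s^-1).
#' @param sites_per_cell number of antigens of this class per cell.
#' @return object of class `binding_component` with the implied `Kd`.
#' @export
binding_component <- function(k_on, k_off, sites_per_cell) {
  if (any(c(k_on, k_off, sites_per_cell) <= 0))
    stop("k_on, k_off and sites_per_cell must all be strictly positive")
  structure(list(k_on = k_on, k_off = k_off, sites_per_cell = sites_per_cell,
                 Kd = k_off / k_on),
            class = "binding_component")
}

#' Multi-component binding model
#'
#' @param components list of [binding_component()] objects.
#' @param molar_mass antibody molar mass in g/mol (default 150,000, IgG).
#' @return object of class `binding_model`.
#' @export
binding_model <- function(components, molar_mass = 150000) {
  stopifnot(length(components) >= 1,
            all(vapply(components, inherits, logical(1), "binding_component")))
  structure(list(components = components, molar_mass = molar_mass,
                 total_sites = sum(vapply(components, `[[`, numeric(1),
                                          "sites_per_cell"))),
            class = "binding_model")
}

#' Default two-component anti-FRA (farletuzumab) binding model
#'
#' The two kinetic classes describing farletuzumab binding to OVCAR-3 cells:
#' a fast component (k_on 5.06e5 M^-1 s^-1, k_off 5.61e-3 s^-1) and a slow
#' component (k_on 2.25e5 M^-1 s^-1, k_off 5.02e-4 s^-1), each carrying
#' 300,000 of the 600,000 available antigens per cell. Internalization is
#' not modeled.
#'
#' @return a [binding_model()].
#' @export
farletuzumab_model <- function() {
  binding_model(list(
    binding_component(5.06e5, 5.61e-3, 3e5),
    binding_component(2.25e5, 5.02e-4, 3e5)))
}

#' @export
print.binding_model <- function(x, ...) {
  cat("Binding model:", length(x$components), "component(s),",
      format(x$total_sites, big.mark = ","), "sites/cell, molar mass",
      x$molar_mass, "g/mol\n")
  for (cm in x$components)
    cat(sprintf("  k_on %.3g /M/s  k_off %.3g /s  Kd %.3g nM  sites %s\n",
                cm$k_on, cm$k_off, cm$Kd * 1e9,
                format(cm$sites_per_cell, big.mark = ",")))
  invisible(x)
}

#' Suspension assay protocol
#'
#' Describes a cell-suspension binding experiment: cell number, volume,
#' starting antibody concentration and a schedule of events. Events are
#' rows of a data.frame with columns `time_h`, `action` (one of `"wash"`,
#' `"dilute"`, `"measure"`) and `value` (wash: fraction of free ligand
#' removed; dilute: new volume in mL; measure: ignored).
#'
#' @param cells number of cells in the tube.
#' @param volume_mL suspension volume.
#' @param conc_ug_mL starting antibody concentration (ug/mL).
#' @param events event schedule data.frame (may be empty).
#' @param t_end_h end of simulation; defaults to the last event time (or
#'   24 h if no events).
#' @return object of class `assay_protocol`.
#' @export
assay_protocol <- function(cells, volume_mL, conc_ug_mL,
                           events = data.frame(time_h = numeric(),
                                               action = character(),
                                               value = numeric()),
                           t_end_h = NULL) {
  stopifnot(cells >= 0, volume_mL > 0, conc_ug_mL >= 0)
  if (nrow(events)) {
    stopifnot(all(c("time_h", "action", "value") %in% names(events)))
    if (!all(events$action %in% c("wash", "dilute", "measure")))
      stop("unknown event action")
    w <- events$action == "wash"
    if (any(events$value[w] < 0 | events$value[w] > 1))
      stop("wash fraction must be in [0, 1]")
    if (any(events$value[events$action == "dilute"] <= 0))
      stop("dilution volume must be positive")
    events <- events[order(events$time_h), , drop = FALSE]
  }
  if (is.null(t_end_h)) t_end_h <- if (nrow(events)) max(events$time_h) else 24
  structure(list(cells = cells, volume_mL = volume_mL,
                 conc_ug_mL = conc_ug_mL, events = events, t_end_h = t_end_h),
            class = "assay_protocol")
}

#' Canonical cell-binding measurement protocol
#'
#' The suspension protocol of the cell-binding time-course experiments:
#' 2e6 cells in 2 mL incubated with antibody, then the free ligand removed
#' and the pellet washed once more before counting. The washing procedure
#' takes bench time during which bound antibody dissociates; each wash
#' cycle is modeled as instantaneous free-ligand removal followed by
#' `wash_interval_min` minutes of handling, with the measurement after the
#' final interval (default: two cycles of 2 min, i.e. counting 4 min after
#' the incubation ends).
#'
#' @param incubation_h incubation time before the first wash.
#' @param conc_ug_mL antibody concentration (default 0.4 ug/mL, the
#'   clinically proposed intraperitoneal concentration).
#' @param cells,volume_mL suspension size.
#' @param wash_cycles number of wash cycles.
#' @param wash_interval_min handling time per cycle (minutes).
#' @return an [assay_protocol()] ending in a `measure` event.
#' @export
cell_binding_protocol <- function(incubation_h, conc_ug_mL = 0.4,
                                  cells = 2e6, volume_mL = 2,
                                  wash_cycles = 2, wash_interval_min = 2) {
  tw <- incubation_h + (seq_len(wash_cycles) - 1) * wash_interval_min / 60
  ev <- data.frame(time_h = c(tw, max(tw) + wash_interval_min / 60),
                   action = c(rep("wash", wash_cycles), "measure"),
                   value = c(rep(1, wash_cycles), NA))
  assay_protocol(cells, volume_mL, conc_ug_mL, ev)
}

## Right-hand side of the shared-depletion binding ODE.
## State: y = (L [M], B_1..B_k [bound per cell]).
## lambda_free: first-order loss rate applied to free ligand (in-vivo bath
## escape); cells_per_L couples per-cell binding back into the free pool.
.binding_rhs <- function(model, cells_per_L, lambda_free = 0) {
  kon <- vapply(model$components, `[[`, numeric(1), "k_on")
  koff <- vapply(model$components, `[[`, numeric(1), "k_off")
  S <- vapply(model$components, `[[`, numeric(1), "sites_per_cell")
  function(t, y, parms) {
    L <- y[1]; B <- y[-1]
    dB <- kon * L * (S - B) - koff * B
    dL <- -sum(dB) * cells_per_L / .AVOGADRO - lambda_free * L
    list(c(dL, dB))
  }
}

#' Simulate a suspension binding assay
#'
#' Integrates the multi-component reversible binding ODE with shared
#' free-ligand depletion through the protocol's event schedule. Wash events
#' instantaneously remove the stated fraction of free ligand; dilution
#' events change the volume (diluting free ligand, cells travel with the
#' pellet). Mass balance (free + bound + removed) is tracked and checked.
#'
#' @param protocol an [assay_protocol()].
#' @param model a [binding_model()].
#' @param dt_h output resolution in hours.
#' @return object of class `binding_timecourse`: data.frame with `time_h`,
#'   `free_M`, per-component `bound_1..k` and `bound_total` (per cell), with
#'   measurement rows flagged in the `measured` column; mass-balance drift
#'   and removed ligand are attributes.
#' @export
simulate_assay <- function(protocol, model = farletuzumab_model(), dt_h = 0.02) {
  stopifnot(inherits(protocol, "assay_protocol"), inherits(model, "binding_model"))
  k <- length(model$components)
  V_L <- protocol$volume_mL / 1000
  L0 <- protocol$conc_ug_mL * 1e-6 / model$molar_mass * 1000  # g/mL -> M
  total_molecules <- L0 * V_L * .AVOGADRO

  ev <- protocol$events
  breaks <- sort(unique(c(0, ev$time_h, protocol$t_end_h)))
  breaks <- breaks[breaks <= protocol$t_end_h + 1e-12]
  y <- c(L0, rep(0, k))
  removed <- 0
  out_all <- NULL
  measured_t <- numeric(0)

  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    if (t1 > t0 + 1e-12) {
      tt <- unique(c(seq(t0, t1, by = dt_h), t1))
      rhs <- .binding_rhs(model, protocol$cells / V_L)
      sol <- tryCatch(
        lsoda(y, tt * 3600, rhs, NULL, rtol = 1e-8, atol = 1e-12),
        error = function(e) stop("ODE solver failure: ", conditionMessage(e)))
      seg <- as.data.frame(sol)
      seg[[1]] <- seg[[1]] / 3600
      out_all <- rbind(out_all, seg)
      y <- as.numeric(sol[nrow(sol), -1])
    }
    ## apply events at t1
    here <- ev[abs(ev$time_h - t1) < 1e-12, , drop = FALSE]
    for (j in seq_len(nrow(here))) {
      a <- here$action[j]
      if (a == "wash") {
        frac <- here$value[j]
        removed <- removed + frac * y[1] * V_L * .AVOGADRO
        y[1] <- (1 - frac) * y[1]
      } else if (a == "dilute") {
        ## added medium carries no ligand: molecule counts are unchanged
        newV <- here$value[j] / 1000
        y[1] <- y[1] * V_L / newV
        V_L <- newV
      } else if (a == "measure") {
        measured_t <- c(measured_t, t1)
      }
    }
  }

  names(out_all) <- c("time_h", "free_M", paste0("bound_", seq_len(k)))
  out_all$bound_total <- rowSums(out_all[, paste0("bound_", seq_len(k)), drop = FALSE])
  out_all$measured <- out_all$time_h %in% measured_t
  out_all <- out_all[!duplicated(out_all$time_h, fromLast = TRUE), , drop = FALSE]

  ## mass balance check at end state (volume may have changed)
  final <- y[1] * V_L * .AVOGADRO + protocol$cells * sum(y[-1]) + removed
  drift <- if (total_molecules > 0) abs(final - total_molecules) / total_molecules else 0
  if (drift > 1e-6)
    warning(sprintf("mass-balance drift %.2e exceeds 1e-6", drift))
  structure(out_all, class = c("binding_timecourse", "data.frame"),
            model = model, protocol = protocol,
            removed_molecules = removed, mass_balance_drift = drift)
}

#' Bound antibodies per cell at the measurement event
#'
#' @param tc a `binding_timecourse` from [simulate_assay()].
#' @return bound antibodies per cell at the (last) `measure` event, or at
#'   the end of the simulation if the protocol has no measurement.
#' @export
measured_bound <- function(tc) {
  stopifnot(inherits(tc, "binding_timecourse"))
  rows <- which(tc$measured)
  if (!length(rows)) rows <- nrow(tc)
  tc$bound_total[max(rows)]
}

#' Algebraic depletion-corrected equilibrium binding
#'
#' Root of the shared-ligand equilibrium system: an independent oracle for
#' the ODE steady state.
#'
#' @param model a [binding_model()].
#' @param conc_ug_mL total antibody concentration.
#' @param cells,volume_mL suspension size (cells = 0 gives the no-depletion
#'   closed form `sites * C/(C + Kd)`).
#' @return list with equilibrium `free_M` and per-component and total bound
#'   per cell.
#' @export
equilibrium_binding <- function(model, conc_ug_mL, cells = 0, volume_mL = 1) {
  L0 <- conc_ug_mL * 1e-6 / model$molar_mass * 1000
  S <- vapply(model$components, `[[`, numeric(1), "sites_per_cell")
  Kd <- vapply(model$components, `[[`, numeric(1), "Kd")
  cpl <- cells / (volume_mL / 1000) / .AVOGADRO
  f <- function(L) L + cpl * sum(S * L / (L + Kd)) - L0
  Lst <- if (L0 == 0) 0 else uniroot(f, c(0, L0), tol = L0 * 1e-12)$root
  B <- S * Lst / (Lst + Kd)
  list(free_M = Lst, bound = B, bound_total = sum(B))
}

#' Saturation curve: bound per cell versus antibody concentration
#'
#' Simulates the saturation experiment: fixed incubation (default 2 h,
#' where the time course has plateaued) over a concentration series, bound
#' count read at the end of incubation. The plateau estimates the total
#' available antigens per cell.
#'
#' @param concentrations_ug_mL antibody concentrations.
#' @param model a [binding_model()].
#' @param cells,volume_mL suspension size.
#' @param incubation_h incubation time.
#' @return data.frame with `conc_ug_mL` and `bound_per_cell`.
#' @export
saturation_curve <- function(concentrations_ug_mL, model = farletuzumab_model(),
                             cells = 2e6, volume_mL = 2, incubation_h = 2) {
  if (any(concentrations_ug_mL <= 0)) stop("concentrations must be positive")
  bound <- vapply(concentrations_ug_mL, function(cc) {
    p <- assay_protocol(cells, volume_mL, cc, t_end_h = incubation_h)
    tc <- simulate_assay(p, model)
    tc$bound_total[nrow(tc)]
  }, numeric(1))
  data.frame(conc_ug_mL = concentrations_ug_mL, bound_per_cell = bound)
}

#' Radiolabeling specification
#'
#' @param specific_activity_GBq_mg specific activity of the labeled
#'   antibody preparation.
#' @param half_life_h radionuclide half-life (default 7.21 h, 211At).
#' @param molar_mass antibody molar mass (g/mol).
#' @return object of class `labeling_spec`.
#' @export
labeling_spec <- function(specific_activity_GBq_mg = 2.3, half_life_h = 7.21,
                          molar_mass = 150000) {
  lam <- log(2) / (half_life_h * 3600)
  sa_max <- lam * .AVOGADRO / molar_mass / 1e12   # GBq/mg if every molecule labeled
  if (specific_activity_GBq_mg < 0) stop("specific activity must be non-negative")
  if (specific_activity_GBq_mg > sa_max)
    stop(sprintf("specific activity exceeds the theoretical maximum %.1f GBq/mg", sa_max))
  structure(list(specific_activity_GBq_mg = specific_activity_GBq_mg,
                 half_life_h = half_life_h, molar_mass = molar_mass,
                 theoretical_max_GBq_mg = sa_max),
            class = "labeling_spec")
}

#' Labeled-antibody fraction implied by a specific activity
#'
#' Converts a specific activity into the ratio of total antibody molecules
#' to radiolabeled molecules: molecules per mg is `N_A / M`, radionuclide
#' atoms per mg is `SA / lambda`, and their quotient is the "1 in N"
#' labeling ratio.
#'
#' @param spec a [labeling_spec()] (or a specific activity in GBq/mg, in
#'   which case the remaining defaults of [labeling_spec()] apply).
#' @return list with `ratio` (antibodies per labeled antibody) and
#'   `fraction` (its reciprocal).
#' @export
labeled_fraction <- function(spec = labeling_spec()) {
  if (is.numeric(spec)) spec <- labeling_spec(spec)
  stopifnot(inherits(spec, "labeling_spec"))
  if (spec$specific_activity_GBq_mg == 0)
    return(list(ratio = Inf, fraction = 0))
  lam <- log(2) / (spec$half_life_h * 3600)
  molecules_per_mg <- .AVOGADRO / spec$molar_mass / 1000
  atoms_per_mg <- spec$specific_activity_GBq_mg * 1e9 / lam
  ratio <- molecules_per_mg / atoms_per_mg
  list(ratio = ratio, fraction = 1 / ratio)
}

#' Simulated Lindmo immunoreactive-fraction assay
#'
#' Forward-simulates the serial cell-dilution assay used to estimate the
#' immunoreactive fraction: a constant trace amount of labeled antibody is
#' incubated with a 1:2 dilution series of cells, the cells are pelleted
#' and washed, and the bound fraction is extrapolated to infinite antigen
#' excess by the double-inverse (1/bound vs 1/cells) linear fit. The pellet
#' washing takes bench time (two centrifugations plus handling) during
#' which reversibly bound antibody dissociates, so a preparation with a
#' fast-dissociating component yields an apparent IRF well below 1 even
#' when every molecule is immunoreactive.
#'
#' @param model a [binding_model()].
#' @param cells_per_mL_max top cell concentration of the series.
#' @param n_dilutions number of 1:2 dilution steps (>= 4 points total).
#' @param volume_mL assay volume.
#' @param tracer_ng amount of labeled antibody per tube.
#' @param association_h association time.
#' @param wash_min total wash/handling time between free-ligand removal and
#'   counting (default 15 min: two 5-min centrifugations plus handling).
#' @return list with `irf` (apparent immunoreactive fraction), the
#'   dilution-series data and the double-inverse fit.
#' @export
simulate_irf_assay <- function(model = farletuzumab_model(),
                               cells_per_mL_max = 5e6, n_dilutions = 6,
                               volume_mL = 0.5, tracer_ng = 2,
                               association_h = 3, wash_min = 15) {
  if (n_dilutions + 1 < 4) stop("need at least 4 dilution points")
  cells_series <- cells_per_mL_max * volume_mL / 2^(0:n_dilutions)
  conc <- tracer_ng * 1e-3 / volume_mL          # ug/mL
  koff <- vapply(model$components, `[[`, numeric(1), "k_off")
  bound_frac <- vapply(cells_series, function(nc) {
    p <- assay_protocol(nc, volume_mL, conc, t_end_h = association_h)
    tc <- simulate_assay(p, model, dt_h = 0.05)
    B <- as.numeric(tc[nrow(tc), paste0("bound_", seq_along(koff))])
    B_washed <- B * exp(-koff * wash_min * 60)  # free = 0 during washes
    total <- conc * 1e-6 * volume_mL / model$molar_mass * .AVOGADRO
    nc * sum(B_washed) / total
  }, numeric(1))
  fit <- lm(I(1 / bound_frac) ~ I(1 / cells_series))
  irf <- 1 / coef(fit)[[1]]
  list(irf = irf, cells = cells_series, bound_fraction = bound_frac, fit = fit)
}
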