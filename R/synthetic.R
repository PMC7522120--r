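## Seeded synthetic-data generators. Each generator returns a list with
## `observations` (what an experiment would yield), `truth` (the
## noise-free quantities and parameters used), and `config`, so that
## estimation routines can be validated against known ground truth.

#' Synthetic-generator configuration
#'
#' @param seed integer seed; every generator call is reproducible given
#'   the config.
#' @param noise_sd multiplicative (log-normal) measurement noise sd on
#'   counted quantities.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, noise_sd = 0.1) {
  if (noise_sd < 0) stop("noise sd must be non-negative")
  structure(list(seed = as.integer(seed), noise_sd = noise_sd),
            class = "synthetic_config")
}

#' Generate a synthetic binding-assay time course
#'
#' Simulates the canonical washed-pellet assay with a known binding model
#' and adds log-normal counting noise.
#'
#' @param config a [synthetic_config()].
#' @param model the true [binding_model()].
#' @param times_h incubation times sampled.
#' @param cells,volume_mL,conc_ug_mL,wash_release_min assay conditions
#'   (see [fit_binding_model()]).
#' @return list with `observations` (data.frame `time_h`, `bound`),
#'   `truth` (noise-free bound and the model), and `config`.
#' @export
gen_binding_assay <- function(config = synthetic_config(),
                              model = farletuzumab_model(),
                              times_h = c(0.25, 0.5, 1, 2, 4, 8, 16, 24),
                              cells = 2e6, volume_mL = 2, conc_ug_mL = 0.4,
                              wash_release_min = 4) {
  true_bound <- .predict_measured(model, times_h, cells, volume_mL,
                                  conc_ug_mL, wash_release_min)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  obs <- true_bound * rlnorm(length(times_h), 0, config$noise_sd)
  list(observations = data.frame(time_h = times_h, bound = obs),
       truth = list(bound = true_bound, model = model,
                    conditions = list(cells = cells, volume_mL = volume_mL,
                                      conc_ug_mL = conc_ug_mL,
                                      wash_release_min = wash_release_min)),
       config = config)
}

#' Generate a synthetic microtumor cohort
#'
#' Draws tumor radii from a truncated log-normal, converts radius to cell
#' number at a fixed packing density, and assigns measured activity
#' proportional to cell number (surface-bound uptake with full antibody
#' access) with log-normal noise.
#'
#' @param config a [synthetic_config()].
#' @param n number of microtumors.
#' @param radius_range_um truncation range of the radius distribution.
#' @param meanlog,sdlog log-normal radius parameters.
#' @param packing_cells_per_um3 cells per um^3 of tumor volume.
#' @param activity_per_cell_Bq true uptake slope.
#' @return list with `observations` (`radius_um`, `cells`, `activity_Bq`),
#'   `truth`, and `config`.
#' @export
gen_microtumor_cohort <- function(config = synthetic_config(), n = 40,
                                  radius_range_um = c(19, 82),
                                  meanlog = 3.699, sdlog = 0.4135,
                                  packing_cells_per_um3 = 1.74e-4,
                                  activity_per_cell_Bq = 0.086) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  radii <- numeric(0)
  while (length(radii) < n) {                    # rejection truncation
    cand <- rlnorm(2 * n, meanlog, sdlog)
    radii <- c(radii, cand[cand >= radius_range_um[1] &
                             cand <= radius_range_um[2]])
  }
  radii <- radii[seq_len(n)]
  cells <- round(packing_cells_per_um3 * 4 / 3 * pi * radii^3)
  act_true <- activity_per_cell_Bq * cells
  act_obs <- act_true * rlnorm(n, 0, config$noise_sd)
  list(observations = data.frame(radius_um = radii, cells = cells,
                                 activity_Bq = act_obs),
       truth = list(activity_Bq = act_true,
                    activity_per_cell_Bq = activity_per_cell_Bq,
                    packing_cells_per_um3 = packing_cells_per_um3),
       config = config)
}

#' Generate synthetic therapy outcomes
#'
#' Bernoulli tumor-free status per animal with group-specific cure
#' probabilities; tumor-bearing animals die before study end with
#' probability `death_prob`, at a day uniform over the follow-up window.
#'
#' @param config a [synthetic_config()].
#' @param sizes named group sizes.
#' @param cure_prob named tumor-free probabilities.
#' @param death_prob probability a tumor-bearing animal dies before the
#'   censoring day.
#' @param death_window_days days over which deaths occur.
#' @param censor_day end of follow-up.
#' @return list with `observations` (named list of [therapy_outcome()]),
#'   `truth` (the probabilities), and `config`.
#' @export
gen_therapy_outcomes <- function(config = synthetic_config(),
                                 sizes = c(A = 22, B = 22, C = 11, D = 8),
                                 cure_prob = c(A = 0.91, B = 0.14,
                                               C = 0.09, D = 0.12),
                                 death_prob = 0.35,
                                 death_window_days = c(90, 154),
                                 censor_day = 154) {
  stopifnot(identical(names(sizes), names(cure_prob)))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  groups <- lapply(names(sizes), function(g) {
    n <- sizes[[g]]
    tf <- rbinom(1, n, cure_prob[[g]])
    bearing <- n - tf
    deaths <- rbinom(1, bearing, death_prob)
    days <- if (deaths > 0)
      round(runif(deaths, death_window_days[1], death_window_days[2]))
    else numeric(0)
    therapy_outcome(g, n, tf, data.frame(day = sort(days),
                                         status = rep(1L, deaths)),
                    censor_day)
  })
  names(groups) <- names(sizes)
  list(observations = groups,
       truth = list(cure_prob = cure_prob, death_prob = death_prob),
       config = config)
}

## Bi-exponential organ templates, pct = A1 exp(-k1 t) + A2 exp(-k2 t);
## negative A2 with k2 > k1 gives a rising-then-falling (uptake) shape.
.biodist_templates <- function() {
  base <- list(
    blood   = c(A1 = 18, k1 = 0.05, A2 = 0,   k2 = 0),
    kidney  = c(A1 = 6,  k1 = 0.08, A2 = -4,  k2 = 0.9),
    liver   = c(A1 = 5,  k1 = 0.04, A2 = -2,  k2 = 0.7),
    thyroid = c(A1 = 4,  k1 = 0.02, A2 = -3.2, k2 = 0.25),
    stomach = c(A1 = 3,  k1 = 0.03, A2 = -2.4, k2 = 0.30),
    muscle  = c(A1 = 1.2, k1 = 0.05, A2 = -0.6, k2 = 1.0))
  free <- base
  ## free astatide: rapid blood clearance, strong halide-trapping organs
  free$blood <- c(A1 = 8, k1 = 0.4, A2 = 0, k2 = 0)
  free$thyroid <- c(A1 = 30, k1 = 0.02, A2 = -28, k2 = 0.25)
  free$stomach <- c(A1 = 12, k1 = 0.03, A2 = -10, k2 = 0.30)
  list(mab_211At = base, free_astatide = free, control_igg = base)
}

#' Generate synthetic biodistribution time courses
#'
#' Percent injected activity per gram for a set of organs and tracers at
#' fixed sampling times, from bi-exponential templates (an uptake and a
#' clearance phase; the free-astatide tracer has late-rising thyroid and
#' stomach curves), with log-normal noise per animal.
#'
#' @param config a [synthetic_config()].
#' @param times_h sampling times.
#' @param n_per_time animals per time point.
#' @param tracers tracer subset; defaults to all three built-in tracers.
#' @param organs organ subset; defaults to all built-in organs.
#' @return list with `observations` (long data.frame `tracer`, `organ`,
#'   `time_h`, `animal`, `pct_ia_g`), `truth` (template parameters and
#'   noise-free curves per tracer), and `config`.
#' @export
gen_biodistribution <- function(config = synthetic_config(),
                                times_h = c(1, 3, 10, 22), n_per_time = 4,
                                tracers = NULL, organs = NULL) {
  tmpl_all <- .biodist_templates()
  if (!is.null(tracers)) tmpl_all <- tmpl_all[tracers]
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  rows <- list()
  truth_curves <- list()
  for (tr in names(tmpl_all)) {
    tmpl <- tmpl_all[[tr]]
    if (!is.null(organs)) tmpl <- tmpl[organs]
    truth_curves[[tr]] <- list()
    for (org in names(tmpl)) {
      p <- tmpl[[org]]
      mu <- p["A1"] * exp(-p["k1"] * times_h) + p["A2"] * exp(-p["k2"] * times_h)
      mu <- pmax(mu, 1e-3)
      truth_curves[[tr]][[org]] <- data.frame(time_h = times_h,
                                              pct_ia_g = unname(mu))
      for (i in seq_along(times_h)) {
        obs <- mu[i] * rlnorm(n_per_time, 0, config$noise_sd)
        rows[[length(rows) + 1]] <-
          data.frame(tracer = tr, organ = org, time_h = times_h[i],
                     animal = seq_len(n_per_time), pct_ia_g = obs)
      }
    }
  }
  list(observations = do.call(rbind, rows),
       truth = list(templates = tmpl_all, curves = truth_curves),
       config = config)
}
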