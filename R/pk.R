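## Intraperitoneal activity-concentration kinetics. Both species are
## modeled mono-exponentially: the activity concentration in the cavity
## declines at the effective rate lambda_bio + lambda_phys. Only the
## cumulated (time-integrated) decay concentration is consumed downstream,
## which is exactly the quantity the mouse-to-patient equivalence design
## matches.

#' Intraperitoneal compartment pharmacokinetics
#'
#' @param species label, e.g. `"mouse"` or `"patient"`.
#' @param administered_kBq administered activity.
#' @param volume_mL cavity fluid volume.
#' @param lambda_bio biological escape rate of antibody from the cavity
#'   (s^-1, >= 0).
#' @param scheme a [decay_scheme()] supplying the physical decay rate.
#' @return object of class `compartment_pk`.
#' @export
compartment_pk <- function(species, administered_kBq, volume_mL,
                           lambda_bio = 0, scheme = at211_scheme()) {
  if (lambda_bio < 0) stop("biological escape rate must be non-negative")
  if (volume_mL <= 0) stop("cavity volume must be positive")
  lam_phys <- decay_constant(scheme)
  structure(list(species = species, administered_kBq = administered_kBq,
                 volume_mL = volume_mL, lambda_bio = lambda_bio,
                 lambda_phys = lam_phys,
                 lambda_eff = lambda_bio + lam_phys,
                 scheme = scheme),
            class = "compartment_pk")
}

#' Mouse intraperitoneal therapy scenario PK
#'
#' 700 kBq administered in 0.7 mL (1000 kBq/mL). The biological escape rate
#' is calibrated to four times the physical decay rate (biological
#' half-time ~1.80 h), so that the cumulated decay concentration equals
#' that of the 200 kBq/mL patient scenario and the mouse experiment is a
#' 5x-concentration surrogate for the clinical treatment.
#'
#' @param scheme a [decay_scheme()].
#' @return a [compartment_pk()].
#' @export
mouse_ip_pk <- function(scheme = at211_scheme()) {
  compartment_pk("mouse", 700, 0.7, lambda_bio = 4 * decay_constant(scheme),
                 scheme = scheme)
}

#' Patient intraperitoneal therapy scenario PK
#'
#' 300 MBq in 1.5 L of infusate (200 kBq/mL). Antibody escape from the
#' human cavity is slow against the 7.21 h physical half-life and is set
#' to zero: the activity concentration is eliminated by physical decay
#' only.
#'
#' @param scheme a [decay_scheme()].
#' @return a [compartment_pk()].
#' @export
patient_ip_pk <- function(scheme = at211_scheme()) {
  compartment_pk("patient", 3e5, 1500, lambda_bio = 0, scheme = scheme)
}

#' @export
print.compartment_pk <- function(x, ...) {
  cat(sprintf("Intraperitoneal PK [%s]: %.3g kBq in %.3g mL (C0 = %.3g kBq/mL)\n",
              x$species, x$administered_kBq, x$volume_mL,
              x$administered_kBq / x$volume_mL))
  cat(sprintf("  lambda_bio %.3g /s, lambda_phys %.3g /s (effective t1/2 %.2f h)\n",
              x$lambda_bio, x$lambda_phys, log(2) / x$lambda_eff / 3600))
  invisible(x)
}

#' Cavity activity concentration at time t
#'
#' \eqn{C(t) = (A_0/V) e^{-(\lambda_{bio}+\lambda_{phys}) t}}.
#'
#' @param t_h time after administration in hours (vectorized, >= 0).
#' @param pk a [compartment_pk()].
#' @return concentration in kBq/mL.
#' @export
ip_concentration <- function(t_h, pk) {
  if (any(t_h < 0)) stop("time must be non-negative")
  pk$administered_kBq / pk$volume_mL * exp(-pk$lambda_eff * t_h * 3600)
}

#' Cumulated decay concentration of a scenario
#'
#' Time-integral of the decay rate per unit volume,
#' \eqn{\tilde{C} = C_0 / \lambda_{eff}} for mono-exponential kinetics
#' (decays that physically occur in the cavity; antibody that escapes
#' biologically decays elsewhere).
#'
#' @param pk a [compartment_pk()].
#' @return decays per mL.
#' @export
cumulated_decays <- function(pk) {
  if (pk$lambda_eff <= 0) stop("effective rate must be positive (divergent integral)")
  pk$administered_kBq * 1000 / pk$volume_mL / pk$lambda_eff
}

#' Mouse-to-patient concentration translation factor
#'
#' The ratio of initial activity concentrations that makes the cumulated
#' decay concentrations of the two scenarios equal:
#' \eqn{\lambda_{eff}^{mouse} / \lambda_{eff}^{patient}}. With the default
#' calibrations this is 5, i.e. the mouse receives five times the clinical
#' concentration.
#'
#' @param mouse_pk,patient_pk [compartment_pk()] objects.
#' @return dimensionless concentration ratio.
#' @export
translation_factor <- function(mouse_pk = mouse_ip_pk(),
                               patient_pk = patient_ip_pk()) {
  mouse_pk$lambda_eff / patient_pk$lambda_eff
}

#' Antibody mass concentration of a scenario
#'
#' Initial antibody concentration implied by the administered activity and
#' the labeling specific activity, in molar units. Used to drive the
#' binding and penetration models.
#'
#' @param pk a [compartment_pk()].
#' @param labeling a [labeling_spec()].
#' @return molar concentration (M).
#' @export
antibody_concentration_M <- function(pk, labeling = labeling_spec()) {
  g_per_mL <- pk$administered_kBq * 1000 / pk$volume_mL /
    (labeling$specific_activity_GBq_mg * 1e12)
  g_per_mL * 1000 / labeling$molar_mass
}
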