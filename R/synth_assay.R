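#' Default impedance kinetic parameters
#'
#' TGF-beta1 stimulation produces a transient, dose-dependent cell-index
#' rise that declines again around 24 h after addition (contraction and
#' partial detachment of the differentiating cell layer).  The pulse is
#' `(1 - exp(-t/tau_rise)) * decay(t)` with a sigmoidal decay centred on
#' the decline onset; the amplitude is a Hill function of dose.  An
#' optional relaxation term (cytoskeletal relaxants) produces an immediate
#' impedance drop with a nadir at `relax_tau` hours.  Noise is AR(1).
#'
#' @param amax maximal normalized amplitude at saturating dose.
#' @param tgf_ec50 half-maximal TGF-beta1 dose (ng/ml).
#' @param hill_slope Hill slope of the dose-amplitude relation.
#' @param tau_rise rise time constant (h).
#' @param decline_onset time of half-decline (h), ~24 h by default.
#' @param tau_decline decline time constant (h).
#' @param relax_depth relaxation amplitude (0 disables the term).
#' @param relax_tau relaxation nadir time constant (h).
#' @param baseline_ci raw cell index at the reference time.
#' @param noise_sd AR(1) innovation SD (raw cell-index units).
#' @param noise_rho AR(1) correlation.
#' @return Parameter list for [simulate_impedance_trace()].
#' @export
kinetic_params <- function(amax = 0.6, tgf_ec50 = 0.5, hill_slope = 1,
                           tau_rise = 6, decline_onset = 24,
                           tau_decline = 3, relax_depth = 0,
                           relax_tau = 2.5, baseline_ci = 8,
                           noise_sd = 0.02, noise_rho = 0.8) {
  stopifnot(tau_rise > 0, tau_decline > 0, relax_tau > 0, amax >= 0)
  list(amax = amax, tgf_ec50 = tgf_ec50, hill_slope = hill_slope,
       tau_rise = tau_rise, decline_onset = decline_onset,
       tau_decline = tau_decline, relax_depth = relax_depth,
       relax_tau = relax_tau, baseline_ci = baseline_ci,
       noise_sd = noise_sd, noise_rho = noise_rho)
}

#' Deterministic impedance pulse shape
#'
#' Unit-amplitude transient: exponential rise times sigmoidal decline.
#'
#' @param t time (h).
#' @param kp [kinetic_params()] list.
#' @return Pulse value in `[0, 1]`.
#' @export
impedance_pulse <- function(t, kp = kinetic_params()) {
  (1 - exp(-pmax(t, 0) / kp$tau_rise)) /
    (1 + exp((t - kp$decline_onset) / kp$tau_decline))
}

#' Amplitude of the TGF-beta1 impedance response
#'
#' Hill function of dose, scaled down by the plated compound's fractional
#' inhibition.
#'
#' @inheritParams impedance_pulse
#' @param tgf_dose TGF-beta1 dose (ng/ml).
#' @param compound registry row (or list with `true_ic50_nM`, `efficacy`)
#'   or NULL.
#' @param conc compound concentration (nM).
#' @return Amplitude in normalized cell-index units.
#' @export
impedance_amplitude <- function(tgf_dose, kp = kinetic_params(),
                                compound = NULL, conc = 0) {
  inh <- if (is.null(compound)) 0 else
    compound_inhibition(conc, compound$true_ic50_nM, compound$efficacy)
  kp$amax * hill(tgf_dose, kp$tgf_ec50, kp$hill_slope) * (1 - inh)
}

#' Simulate a raw impedance trace
#'
#' `raw(t) = baseline_ci * (1 + A * pulse(t) - relax(t)) + AR(1) noise`,
#' with `A` from [impedance_amplitude()] and `relax(t) =
#' relax_depth * E(conc) * (t/relax_tau) * exp(1 - t/relax_tau)` (maximum
#' exactly at `relax_tau`).  After [preprocess_trace()] against a dose-0
#' baseline well, the noiseless 20 h readout equals `A * pulse(20)`.
#'
#' @inheritParams impedance_amplitude
#' @param times sampling times (h), sorted, covering 0 and >= 20 h.
#' @param seed integer seed for the AR(1) noise.
#' @param well well id.
#' @return A raw [impedance_trace()].
#' @examples
#' tr <- simulate_impedance_trace(5, times = seq(0, 48, 0.5), seed = 1)
#' @export
simulate_impedance_trace <- function(tgf_dose, compound = NULL, conc = 0,
                                     times = seq(0, 48, 0.25),
                                     kp = kinetic_params(), seed = 1L,
                                     well = "W01") {
  stopifnot(!is.unsorted(times, strictly = TRUE))
  if (min(times) > 0 || max(times) < 20) {
    stop("times must include 0 and reach at least 20 h")
  }
  A <- impedance_amplitude(tgf_dose, kp, compound, conc)
  relax_amp <- if (is.null(compound) || kp$relax_depth <= 0) 0 else
    kp$relax_depth * compound_inhibition(conc, compound$true_ic50_nM,
                                         compound$efficacy)
  signal <- 1 + A * impedance_pulse(times, kp) -
    relax_amp * (pmax(times, 0) / kp$relax_tau) *
      exp(1 - pmax(times, 0) / kp$relax_tau)
  noise <- if (kp$noise_sd > 0) {
    .with_seed(seed, {
      e <- numeric(length(times))
      e[1] <- rnorm(1, 0, kp$noise_sd)
      for (i in seq_along(times)[-1]) {
        e[i] <- kp$noise_rho * e[i - 1] +
          rnorm(1, 0, kp$noise_sd * sqrt(1 - kp$noise_rho^2))
      }
      e
    })
  } else numeric(length(times))
  impedance_trace(times, kp$baseline_ci * signal + noise, well = well,
                  state = "raw")
}

#' Default MRM peak-area generator parameters
#'
#' Tubulin area scales with cell number; ACTA (alpha-SMA) and COL1A1
#' ratios to tubulin follow `1 + (fold - 1) * Hill(dose; ec50)` (unit
#' slope), attenuated by the compound's inhibition; induction is ~3-fold
#' with EC50 0.07 ng/ml (ACTA) and 0.05 ng/ml (COL1A1).
#'
#' @return Parameter list for [simulate_msms_well()].
#' @export
msms_params <- function() {
  list(fold = 3, ec50_acta = 0.07, ec50_col1 = 0.05,
       baseline_ratio_acta = 0.25, baseline_ratio_col1 = 0.4,
       area_per_cell = 50, cv_tubulin = 0.1, cv_ratio = 0.08)
}

#' Simulate MRM peak areas for one well
#'
#' @inheritParams impedance_amplitude
#' @param n_cells cells in the well (> 0); the tubulin area is
#'   proportional to it.
#' @param mp [msms_params()] list.
#' @param noise logical; FALSE gives the deterministic expectation.
#' @param seed integer seed.
#' @param well well id.
#' @return One-row data.frame: `well`, `area_col1a1`, `area_acta`,
#'   `area_tba1a` (use [normalize_to_tubulin()] for ratios).
#' @export
simulate_msms_well <- function(tgf_dose, compound = NULL, conc = 0,
                               n_cells = 20000, mp = msms_params(),
                               noise = TRUE, seed = 1L, well = "W01") {
  if (n_cells <= 0) stop("n_cells must be > 0")
  inh <- if (is.null(compound)) 0 else
    compound_inhibition(conc, compound$true_ic50_nM, compound$efficacy)
  ind_acta <- 1 + (mp$fold - 1) * hill(tgf_dose, mp$ec50_acta) * (1 - inh)
  ind_col1 <- 1 + (mp$fold - 1) * hill(tgf_dose, mp$ec50_col1) * (1 - inh)
  .with_seed(seed, {
    jt <- function(cv) if (noise) rlnorm(1, -cv^2 / 2, cv) else 1
    tub <- mp$area_per_cell * n_cells * jt(mp$cv_tubulin)
    acta <- mp$baseline_ratio_acta * ind_acta * tub * jt(mp$cv_ratio)
    col1 <- mp$baseline_ratio_col1 * ind_col1 * tub * jt(mp$cv_ratio)
    data.frame(well = well, area_col1a1 = col1, area_acta = acta,
               area_tba1a = tub, stringsAsFactors = FALSE)
  })
}

#' Simulate the observed myofibroblast fraction of a well
#'
#' Well-level readout used for large simulated screens: the latent
#' fraction from [differentiation_fraction()] plus truncated Gaussian
#' well-to-well variability (default SD 0.025, i.e. 2.5 percent-effect
#' units on the control-anchored scale), optionally followed by binomial
#' sampling of `n_cells` classified cells.
#'
#' In `mode = "reversal"` the well is first differentiated by the
#' TGF-beta1 pulse alone (the state persists after washout), and the
#' compound then acts on the established state through its reversal IC50.
#'
#' @inheritParams differentiation_fraction
#' @param mode `"prevention"` or `"reversal"`.
#' @param fraction_sd well-to-well latent SD on the fraction scale.
#' @param n_cells number of cells sampled per well (NULL: no sampling).
#' @param seed integer seed.
#' @return Observed myofibroblast fraction in `[0, 1]`.
#' @export
simulate_well_fraction <- function(tgf_dose = 5, compound = NULL, conc = 0,
                                   mode = c("prevention", "reversal"),
                                   fraction_sd = 0.025, n_cells = NULL,
                                   seed = 1L) {
  mode <- match.arg(mode)
  f <- if (mode == "prevention") {
    differentiation_fraction(tgf_dose, compound, conc)
  } else {
    base <- differentiation_fraction(tgf_dose)   # established before washout
    f_min <- differentiation_fraction(0)
    rev_inh <- if (is.null(compound)) 0 else
      compound_inhibition(conc,
                          if (!is.null(compound$reversal_ic50_nM))
                            compound$reversal_ic50_nM else compound$true_ic50_nM,
                          compound$efficacy)
    f_min + (base - f_min) * (1 - rev_inh)
  }
  .with_seed(seed, {
    fobs <- .clamp(f + rnorm(1, 0, fraction_sd), 0, 1)
    if (!is.null(n_cells)) fobs <- rbinom(1, n_cells, fobs) / n_cells
    fobs
  })
}

#' Simulate the viability readout of a well
#'
#' Percent viability reduction relative to vehicle: toxic compounds reduce
#' viability along a unit-slope logistic of concentration (toxicity EC50
#' from the registry); non-toxic compounds fluctuate around zero.
#'
#' @param compound registry row or NULL.
#' @param conc concentration (nM).
#' @param noise_sd Gaussian readout SD (percent).
#' @param seed integer seed.
#' @return Percent viability reduction (can be slightly negative).
#' @export
simulate_viability_reduction <- function(compound = NULL, conc = 0,
                                         noise_sd = 3, seed = 1L) {
  red <- if (!is.null(compound) && isTRUE(compound$toxic)) {
    95 * conc / (conc + compound$tox_ec50_nM)
  } else 0
  .with_seed(seed, min(red + rnorm(1, 0, noise_sd), 100))
}
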