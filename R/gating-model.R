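#' Biophysical parameter set for one channel / beta-subunit combination
#'
#' Bundles everything the synthetic-current generator needs to emulate a
#' whole-cell Cav1.3 current: a Boltzmann activation curve, a linear ohmic
#' driving force, two independent inactivation gates with fixed amplitude
#' weights plus a non-inactivating plateau, voltage-dependent time constants
#' for activation/deactivation and inactivation/recovery, and an optional
#' "hook" (blocked-open pool reopening on repolarization).
#'
#' The gating architecture is deliberately minimal: one Hodgkin-Huxley
#' activation gate `m` and two inactivation gates `h_fast`, `h_slow` that
#' relax first-order toward shared voltage-dependent steady states. Total
#' availability is `frac_noninact + a_fast * h_fast + a_slow * h_slow`, so
#' the simulator-side amplitude weights must satisfy
#' `a_fast + a_slow + frac_noninact == 1`.
#'
#' @param label Channel/subunit label, e.g. `"WT+b3"`.
#' @param v05_act,k_act Half-maximal activation voltage (mV) and slope
#'   factor (mV, > 0) of the activation Boltzmann.
#' @param v_rev Extrapolated reversal potential (mV).
#' @param gmax_density Maximal conductance density (nS/pF, > 0).
#' @param tau_act Named list with `tau_peak` (ms), `v_peak` (mV), `sigma`
#'   (mV) and `floor` (ms) describing the bell-shaped activation time
#'   constant.
#' @param v05_inact,k_inact Half-maximal inactivation voltage (mV) and slope
#'   factor (mV, > 0) of the availability Boltzmann.
#' @param frac_noninact Non-inactivating fraction in `[0, 1]` (the plateau of
#'   the steady-state availability curve).
#' @param a_fast,a_slow Fractional amplitudes of the fast and slow
#'   inactivation gates; `a_fast + a_slow + frac_noninact` must equal 1
#'   (within 1e-9).
#' @param tau_inact_fast,tau_inact_slow Inactivation time constants (ms) at
#'   depolarized voltages.
#' @param tau_rec_fast,tau_rec_slow Recovery time constants (ms) at the
#'   holding potential.
#' @param tau_deact_ref Deactivation time constant (ms) at -69 mV; a mild
#'   exponential voltage dependence (e-fold per 35 mV) is applied around it.
#' @param hook Optional list `list(enabled, tau_unblock, blocked_frac)`
#'   describing a depolarization-occupied blocked-open pool that re-enters
#'   the open state with `tau_unblock` (ms) upon repolarization, producing a
#'   delayed tail-current peak. Disabled by default.
#'
#' @return An object of class `cav_gating_params`.
#' @seealso [preset_gating()] for the four shipped parameter sets,
#'   [steady_state_activation()], [steady_state_availability()].
#' @export
gating_params <- function(label,
                          v05_act, k_act, v_rev, gmax_density,
                          tau_act = list(tau_peak = 2, v_peak = -20,
                                         sigma = 20, floor = 0.3),
                          v05_inact, k_inact, frac_noninact,
                          a_fast, a_slow,
                          tau_inact_fast, tau_inact_slow,
                          tau_rec_fast, tau_rec_slow,
                          tau_deact_ref = 1,
                          hook = list(enabled = FALSE, tau_unblock = 0.3,
                                      blocked_frac = 0.4)) {
  stopifnot(is.character(label), length(label) == 1)
  p <- list(
    label = label,
    v05_act = as.numeric(v05_act), k_act = as.numeric(k_act),
    v_rev = as.numeric(v_rev), gmax_density = as.numeric(gmax_density),
    tau_act = utils::modifyList(
      list(tau_peak = 2, v_peak = -20, sigma = 20, floor = 0.3), tau_act),
    v05_inact = as.numeric(v05_inact), k_inact = as.numeric(k_inact),
    frac_noninact = as.numeric(frac_noninact),
    a_fast = as.numeric(a_fast), a_slow = as.numeric(a_slow),
    tau_inact_fast = as.numeric(tau_inact_fast),
    tau_inact_slow = as.numeric(tau_inact_slow),
    tau_rec_fast = as.numeric(tau_rec_fast),
    tau_rec_slow = as.numeric(tau_rec_slow),
    tau_deact_ref = as.numeric(tau_deact_ref),
    hook = utils::modifyList(
      list(enabled = FALSE, tau_unblock = 0.3, blocked_frac = 0.4), hook)
  )
  class(p) <- "cav_gating_params"
  validate_gating_params(p)
}

validate_gating_params <- function(p) {
  err <- function(msg) stop("invalid gating_params: ", msg, call. = FALSE)
  num_pos <- c("k_act", "k_inact", "gmax_density", "tau_inact_fast",
               "tau_inact_slow", "tau_rec_fast", "tau_rec_slow",
               "tau_deact_ref")
  for (f in num_pos) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0) err(paste(f, "must be > 0"))
  }
  for (f in c("tau_peak", "sigma", "floor")) {
    if (!is.finite(p$tau_act[[f]]) || p$tau_act[[f]] <= 0)
      err(paste("tau_act$", f, " must be > 0", sep = ""))
  }
  if (p$frac_noninact < 0 || p$frac_noninact > 1)
    err("frac_noninact must lie in [0, 1]")
  if (p$a_fast < 0 || p$a_slow < 0)
    err("amplitude weights must be non-negative")
  if (abs(p$a_fast + p$a_slow + p$frac_noninact - 1) > 1e-9)
    err("a_fast + a_slow + frac_noninact must equal 1 (within 1e-9)")
  if (isTRUE(p$hook$enabled)) {
    if (p$hook$tau_unblock <= 0) err("hook$tau_unblock must be > 0")
    if (p$hook$blocked_frac < 0 || p$hook$blocked_frac >= 1)
      err("hook$blocked_frac must lie in [0, 1)")
  }
  p
}

#' @export
print.cav_gating_params <- function(x, ...) {
  cat("<cav_gating_params> ", x$label, "\n", sep = "")
  cat(sprintf("  activation:   V0.5 = %.2f mV, k = %.2f mV, Vrev = %.2f mV, Gmax = %.3f nS/pF\n",
              x$v05_act, x$k_act, x$v_rev, x$gmax_density))
  cat(sprintf("  inactivation: V0.5 = %.2f mV, k = %.2f mV, non-inactivating = %.1f%%\n",
              x$v05_inact, x$k_inact, 100 * x$frac_noninact))
  cat(sprintf("  gates: a_fast = %.3f (tau %.1f/%.1f ms), a_slow = %.3f (tau %.1f/%.1f ms)\n",
              x$a_fast, x$tau_inact_fast, x$tau_rec_fast,
              x$a_slow, x$tau_inact_slow, x$tau_rec_slow))
  invisible(x)
}

#' Passive cell and recording-condition model
#'
#' @param capacitance_pF Whole-cell capacitance (pF, > 0).
#' @param leak_nS Ohmic leak conductance (nS, >= 0; leak reversal 0 mV).
#' @param noise_sd_pA Standard deviation of additive white current noise
#'   (pA, >= 0); 0 disables noise.
#' @param rundown_pct_per_min Linear run-down of the channel current, in
#'   percent of the initial peak per minute (typically <= 0).
#' @param seed Integer seed for the per-cell noise stream.
#' @return An object of class `cav_cell_model`.
#' @export
cell_model <- function(capacitance_pF = 20, leak_nS = 0.5, noise_sd_pA = 5,
                       rundown_pct_per_min = 0, seed = 1L) {
  stopifnot(is.finite(capacitance_pF), capacitance_pF > 0,
            is.finite(leak_nS), leak_nS >= 0,
            is.finite(noise_sd_pA), noise_sd_pA >= 0)
  structure(list(capacitance_pF = as.numeric(capacitance_pF),
                 leak_nS = as.numeric(leak_nS),
                 noise_sd_pA = as.numeric(noise_sd_pA),
                 rundown_pct_per_min = as.numeric(rundown_pct_per_min),
                 seed = as.integer(seed)),
            class = "cav_cell_model")
}

#' Drug (dihydropyridine-like) block model
#'
#' Concentration-dependent block follows a Hill curve with slope fixed at 1
#' (fractional block `c / (c + IC50)` at equilibrium) and first-order
#' equilibration after each concentration step.
#'
#' @param ic50_nM Half-maximal inhibitory concentration (nM, > 0).
#' @param hill_slope Hill coefficient; fixed at 1.
#' @param equilibration_tau_s Time constant (s) of block equilibration after
#'   a concentration change.
#' @return An object of class `cav_drug_model`.
#' @export
drug_model <- function(ic50_nM, hill_slope = 1, equilibration_tau_s = 8) {
  stopifnot(is.finite(ic50_nM), ic50_nM > 0, hill_slope == 1,
            equilibration_tau_s > 0)
  structure(list(ic50_nM = as.numeric(ic50_nM), hill_slope = 1,
                 equilibration_tau_s = as.numeric(equilibration_tau_s)),
            class = "cav_drug_model")
}

#' Steady-state activation (Boltzmann)
#'
#' `1 / (1 + exp(-(V - V0.5,act) / k_act))`, the open probability of the
#' activation gate at steady state.
#'
#' @param v Membrane voltage(s), mV.
#' @param params A [gating_params()] object.
#' @return Activation in `(0, 1)`, same length as `v`.
#' @export
steady_state_activation <- function(v, params) {
  stats::plogis((v - params$v05_act) / params$k_act)
}

#' Steady-state availability (modified Boltzmann)
#'
#' `I_ni + (1 - I_ni) / (1 + exp((V - V0.5,inact) / k_inact))`: the fraction
#' of channels available after full equilibration at voltage `v`, decreasing
#' from 1 toward the non-inactivating plateau `I_ni = frac_noninact`.
#'
#' @inheritParams steady_state_activation
#' @return Availability in `[frac_noninact, 1]`.
#' @export
steady_state_availability <- function(v, params) {
  params$frac_noninact +
    (1 - params$frac_noninact) * h_inf_gate(v, params)
}

# Fully-inactivating per-gate steady state (shared by both h gates); the
# plateau enters through the amplitude weights, not the gate itself.
h_inf_gate <- function(v, params) {
  stats::plogis(-(v - params$v05_inact) / params$k_inact)
}

# Activation/deactivation time constant (ms). Bell-shaped (Gaussian in V)
# around v_peak on the depolarized side; on the hyperpolarized side it
# relaxes logistically (midpoint -40 mV, 4 mV width) into the deactivation
# branch tau_deact_ref * exp((V + 69)/35).
tau_m <- function(v, params) {
  tp <- params$tau_act
  bell <- tp$floor + (tp$tau_peak - tp$floor) *
    exp(-((v - tp$v_peak) / tp$sigma)^2)
  deact <- params$tau_deact_ref * exp((v + 69) / 35)
  w <- stats::plogis((v + 40) / 4)
  (1 - w) * deact + w * bell
}

# Inactivation-gate time constant (ms): logistic interpolation between the
# recovery value (hyperpolarized) and the decay value (depolarized),
# centered at -50 mV with 5 mV width. The two regimes are measured
# separately in the two-pulse and 5-s protocols; the transition is a
# modeling choice.
tau_h <- function(v, tau_rec, tau_inact) {
  w <- stats::plogis((v + 50) / 5)
  tau_rec + (tau_inact - tau_rec) * w
}

# Hook pool steady state: fraction of open channels occupying the
# non-conducting blocked-open pool during depolarization.
b_inf <- function(v, params) {
  if (!isTRUE(params$hook$enabled)) return(rep(0, length(v)))
  params$hook$blocked_frac * steady_state_activation(v, params)
}
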