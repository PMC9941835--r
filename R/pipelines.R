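#' End-to-end current-voltage analysis
#'
#' Simulates an I-V family for a parameter set (test sweep plus the four
#' P/4 leak sub-sweeps per test potential), performs online P/4 leak
#' subtraction, extracts peak inward current densities over the whole
#' 25-ms pulse, and fits the ohmic-driving-force Boltzmann with
#' [fit_iv()].
#'
#' @param params A [gating_params()] object.
#' @param cell A [cell_model()].
#' @param family An I-V `cav_protocol_family` (default [build_iv_family()]).
#' @return A `cav_iv_fit`; the peak table is attached as `$peaks`.
#' @export
analyze_iv <- function(params, cell, family = build_iv_family()) {
  peaks <- iv_peaks(params, cell, family)
  fit <- fit_iv(peaks)
  fit$peaks <- peaks
  fit
}

#' @rdname analyze_iv
#' @return `iv_peaks()`: tibble with `v_mV`, `amplitude_pA`,
#'   `density_pA_pF`, `t_peak_ms` (one row per test potential, P/4
#'   leak-subtracted).
#' @export
iv_peaks <- function(params, cell, family = build_iv_family()) {
  purrr::map2_dfr(family$protocols, family$varied, function(prot, v) {
    test <- simulate_sweep(prot, params, cell, seed_offset = round(v))
    leak <- purrr::imap(p4_leak_pulses(prot)$protocols, function(p, k) {
      simulate_sweep(p, params, cell, seed_offset = round(v) + 1000L + k)
    })
    corrected <- p4_subtract(test, leak)
    dplyr::bind_cols(tibble::tibble(v_mV = v),
                     peak_current(corrected, window = pulse_window(test),
                                  polarity = "absolute"))
  })
}

#' End-to-end steady-state inactivation analysis
#'
#' Simulates the two-pulse SSI family (control pulse, 5-s conditioning,
#' test pulse), removes linear leak offline -- the leak line `I = a + g V`
#' is estimated once per family, pooled over the holding and conditioning
#' segments of the channel-free hyperpolarized sweeps (conditioning <=
#' `subthreshold_mV`) -- computes the test/control peak-amplitude ratio per
#' conditioning voltage, and fits the modified Boltzmann with [fit_ssi()].
#'
#' @inheritParams analyze_iv
#' @param family An SSI `cav_protocol_family`; by default built at the
#'   parameter set's Vmax.
#' @param subthreshold_mV Conditioning voltages at or below this are used
#'   for the pooled leak estimate.
#' @return A `cav_ssi_fit`; the ratio table is attached as `$ratios`.
#' @export
analyze_ssi <- function(params, cell, family = NULL,
                        subthreshold_mV = -69) {
  if (is.null(family)) family <- build_ssi_family(v_test = v_max(params))
  bundle <- simulate_family(family, params, cell)
  ratios <- ssi_ratios(bundle, family, subthreshold_mV = subthreshold_mV)
  fit <- fit_ssi(ratios)
  fit$ratios <- ratios
  fit
}

#' @rdname analyze_ssi
#' @param bundle A `cav_bundle` of SSI sweeps (simulated or read from
#'   disk).
#' @param measure `"late"` (default): amplitudes are isochronal means over
#'   the final 5 ms of each pulse, so the activation-gate state cancels in
#'   the ratio (after a depolarized conditioning step the activation gate
#'   is still open at test-pulse onset, which inflates an onset-peak
#'   measurement). `"peak"`: classical peak-amplitude read-out.
#' @return `ssi_ratios()`: tibble with `v_mV` (conditioning voltage),
#'   `peak_control_pA`, `peak_test_pA`, `ratio`.
#' @export
ssi_ratios <- function(bundle, family, subthreshold_mV = -69,
                       measure = c("late", "peak")) {
  measure <- match.arg(measure)
  segs <- family$protocols[[1]]
  dt <- 1000 / attr(segs, "sampling_rate_hz")
  bounds <- cumsum(segs$duration_ms)
  # windows open on the left: the sample at a segment boundary belongs to
  # the preceding segment
  ctrl_win <- c(bounds[1] + dt / 2, bounds[2])
  cond_win <- c(bounds[3] + dt / 2, bounds[4])
  test_win <- c(bounds[4] + dt / 2, bounds[5])
  hold_win <- c(0, bounds[1])

  sub <- which(family$varied <= subthreshold_mV)
  already <- !is.null(attr(bundle$sweeps[[1]], "meta")$leak_subtracted)
  leak <- if (already || length(sub) == 0) NULL else {
    # pool late-holding and late-conditioning samples of channel-free sweeps
    wins <- list(c(hold_win[2] * 0.5, hold_win[2]),
                 c(cond_win[2] - 0.2 * diff(cond_win), cond_win[2]))
    tryCatch(estimate_leak(bundle$sweeps[sub], wins),
             error = function(e) NULL)
  }
  amp <- function(s2, win) {
    if (measure == "peak") return(peak_current(s2, window = win)$amplitude_pA)
    idx <- window_index(s2, c(win[2] - 5, win[2]))
    mean(s2$i_pA[idx])
  }
  purrr::map2_dfr(bundle$sweeps, family$varied, function(s, v) {
    s2 <- if (!is.null(leak)) offline_linear_subtract(s, leak = leak) else
      offline_linear_subtract_quiet(s)
    pc <- amp(s2, ctrl_win)
    pt <- amp(s2, test_win)
    tibble::tibble(v_mV = v, peak_control_pA = pc, peak_test_pA = pt,
                   ratio = pt / pc)
  })
}

#' End-to-end inactivation time-course analysis
#'
#' Simulates a 5-s depolarization to Vmax, baseline-subtracts, and returns
#' both the remaining-current fractions at the prespecified time points and
#' the exponential decay fit (auto model selection).
#'
#' @inheritParams analyze_iv
#' @param v_test Depolarization potential; default [v_max()].
#' @param times Time points for [remaining_fractions()], ms after the peak.
#' @return A list with `decay_fit` (`cav_decay_fit`) and `r_values`
#'   (tibble).
#' @export
analyze_decay <- function(params, cell, v_test = v_max(params),
                          times = c(50, 100, 250, 500, 1000, 5000)) {
  prot <- build_inact5s_protocol(v_test)
  sweep <- simulate_sweep(prot, params, cell)
  sweep <- offline_linear_subtract_quiet(sweep)
  decay <- extract_decay(sweep)
  list(decay_fit = fit_decay(decay, model = "auto"),
       r_values = remaining_fractions(decay, times = times))
}

#' End-to-end recovery-from-inactivation analysis
#'
#' Simulates the two-pulse recovery family (2-s prepulse, variable gap,
#' 25-ms test pulse; 10 kHz), computes fractional recovery as the
#' test-pulse peak normalized to the prepulse peak, and fits the double
#' exponential with [fit_recovery()].
#'
#' @inheritParams analyze_iv
#' @param family A recovery `cav_protocol_family`; by default built at the
#'   parameter set's Vmax.
#' @return A `cav_recovery_fit`; the fraction table is attached as
#'   `$fractions`.
#' @export
analyze_recovery <- function(params, cell, family = NULL) {
  if (is.null(family)) family <- build_recovery_family(v_test = v_max(params))
  bundle <- simulate_family(family, params, cell)
  fractions <- recovery_fractions(bundle, family)
  fit <- fit_recovery(fractions)
  fit$fractions <- fractions
  fit
}

#' @rdname analyze_recovery
#' @param bundle A `cav_bundle` of recovery sweeps.
#' @return `recovery_fractions()`: tibble with `gap_s`, `peak_pre_pA`,
#'   `peak_test_pA`, `fraction`.
#' @export
recovery_fractions <- function(bundle, family) {
  purrr::pmap_dfr(
    list(bundle$sweeps, family$protocols, family$varied),
    function(s, prot, gap) {
      bounds <- cumsum(prot$duration_ms)
      dt <- 1000 / attr(s, "sampling_rate_hz")
      s2 <- offline_linear_subtract_quiet(s)
      pre <- peak_current(s2, window = c(bounds[1] + dt / 2, bounds[2]))
      tst <- peak_current(s2, window = c(bounds[3] + dt / 2, bounds[4]))
      tibble::tibble(gap_s = gap, peak_pre_pA = pre$amplitude_pA,
                     peak_test_pA = tst$amplitude_pA,
                     fraction = tst$amplitude_pA / pre$amplitude_pA)
    })
}

#' End-to-end tail-current analysis
#'
#' Simulates the tail family (10-ms step to the reversal potential, 20-ms
#' repolarizations) with online P/4 leak subtraction and runs
#' [analyze_tail()] on each repolarization.
#'
#' @inheritParams analyze_iv
#' @param family A tail `cav_protocol_family`; by default built at the
#'   parameter set's reversal potential.
#' @return Tibble with one row per repolarization voltage: `v_repol`,
#'   `tau_deact_ms`, `normalized_integral_ms`, `hook_present`,
#'   `hook_delay_ms`.
#' @export
analyze_tail_family <- function(params, cell, family = NULL) {
  if (is.null(family)) family <- build_tail_family(v_rev = params$v_rev)
  purrr::map2_dfr(family$protocols, family$varied, function(prot, v) {
    test <- simulate_sweep(prot, params, cell, seed_offset = round(v))
    leak <- purrr::imap(p4_leak_pulses(prot)$protocols, function(p, k) {
      simulate_sweep(p, params, cell, seed_offset = round(v) + 2000L + k)
    })
    corrected <- p4_subtract(test, leak)
    tl <- analyze_tail(corrected)
    tibble::tibble(v_repol = v, tau_deact_ms = tl$params$tau_deact,
                   normalized_integral_ms = tl$params$normalized_integral,
                   hook_present = tl$hook_present,
                   hook_delay_ms = tl$params$hook_delay_ms)
  })
}

#' End-to-end concentration-inhibition (IC50) analysis
#'
#' Simulates a drug-free control train and a drug-application train at
#' Vmax (100-ms pulses, 0.1 Hz), fits the linear run-down on the control
#' peaks, corrects the drug-run peaks for run-down, averages the
#' steady-state inhibition per concentration, and fits the fixed-asymptote
#' Hill curve with [fit_dose_response()].
#'
#' @inheritParams analyze_iv
#' @param drug A [drug_model()].
#' @param test_conc_nM Test concentrations, nM, applied cumulatively.
#' @param n_control,n_per_conc Sweeps in the initial drug-free phase and
#'   per concentration.
#' @param full_block_nM Final saturating concentration (nM) confirming full
#'   block; excluded from the Hill fit.
#' @param n_last Sweeps averaged for the steady-state inhibition.
#' @return A `cav_dose_fit`; the corrected per-sweep series is attached as
#'   `$series` and the per-concentration inhibition as `$steady_state`.
#' @export
analyze_dose <- function(params, cell, drug,
                         test_conc_nM = c(30, 300),
                         n_control = 5, n_per_conc = 12,
                         full_block_nM = 3000, n_last = 3) {
  stopifnot(inherits(drug, "cav_drug_model"))
  schedule <- tibble::tibble(
    conc_nM = c(0, test_conc_nM, full_block_nM),
    n_sweeps = c(n_control, rep(n_per_conc, length(test_conc_nM)),
                 n_per_conc))
  control <- simulate_pharmacology_run(params, cell, drug = NULL,
                                       schedule = tibble::tibble(
                                         conc_nM = 0,
                                         n_sweeps = sum(schedule$n_sweeps)))
  rundown <- fit_rundown(pharm_peaks(control))
  drug_run <- simulate_pharmacology_run(params, cell, drug = drug,
                                        schedule = schedule)
  series <- rundown_correct(pharm_peaks(drug_run), rundown)
  ss <- steady_state_inhibition(series, n_last = n_last,
                                drop_full_block = full_block_nM)
  fit <- fit_dose_response(ss)
  fit$series <- series
  fit$steady_state <- ss
  fit$rundown <- rundown
  fit
}
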