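#' Square-segment voltage-command protocol
#'
#' A protocol is an ordered set of constant-voltage segments sampled on a
#' fixed grid. Segment durations are snapped to whole samples (the builders
#' only produce aligned durations).
#'
#' @param segments Data frame with columns `duration_ms` and `v_mV`.
#' @param sampling_rate_hz Sampling rate, Hz (default 50 kHz).
#' @param inter_sweep_s Time between sweep starts, s.
#' @param label Protocol label.
#' @param jp_corrected Logical: are voltages already expressed in the
#'   liquid-junction-potential-corrected convention? Builders default to
#'   `TRUE`; see [junction_correct()].
#' @return A `cav_protocol`: a tibble of segments with protocol metadata in
#'   attributes (`sampling_rate_hz`, `inter_sweep_s`, `label`,
#'   `jp_corrected`).
#' @export
protocol <- function(segments, sampling_rate_hz = 50000, inter_sweep_s = 5,
                     label = "protocol", jp_corrected = TRUE) {
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("duration_ms", "v_mV") %in% names(segments)),
            sampling_rate_hz > 0)
  if (nrow(segments) == 0) stop("protocol needs at least one segment")
  if (any(!is.finite(segments$v_mV))) stop("non-finite segment voltage")
  if (any(segments$duration_ms <= 0)) stop("zero-length protocol segment")
  dt_ms <- 1000 / sampling_rate_hz
  n <- round(segments$duration_ms / dt_ms)
  if (any(n < 1)) stop("zero-length protocol segment (shorter than one sample)")
  segments$duration_ms <- n * dt_ms   # snap to the sample grid
  structure(segments,
            sampling_rate_hz = sampling_rate_hz,
            inter_sweep_s = inter_sweep_s,
            label = label,
            jp_corrected = jp_corrected,
            class = c("cav_protocol", class(segments)))
}

new_family <- function(protocols, family_kind, varied, varied_name) {
  stopifnot(length(protocols) >= 1)
  structure(list(protocols = protocols, family_kind = family_kind,
                 varied = varied, varied_name = varied_name),
            class = "cav_protocol_family")
}

#' @export
print.cav_protocol_family <- function(x, ...) {
  cat("<cav_protocol_family> ", x$family_kind, ": ", length(x$protocols),
      " sweeps; ", x$varied_name, " = ",
      paste(signif(x$varied, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.cav_protocol_family <- function(x) length(x$protocols)

#' Current-voltage (I-V) protocol family
#'
#' 25-ms square depolarizations from the holding potential to a ladder of
#' test potentials in 5-mV steps, each sweep returning to the holding
#' potential.
#'
#' @param hp Holding potential, mV (default -89).
#' @param v_start,v_stop First and last test potential, mV. The defaults
#'   span -84 to +61 mV, covering the activation range and reversal approach
#'   of both WT and mutant channels.
#' @param step Test-potential increment, mV (> 0).
#' @param pulse_ms Test-pulse duration, ms.
#' @param hold_ms,post_ms Pre- and post-pulse holding durations, ms.
#' @param sampling_rate_hz,inter_sweep_s,jp_corrected See [protocol()].
#' @return A `cav_protocol_family` with one sweep per test potential.
#' @export
build_iv_family <- function(hp = -89, v_start = -84, v_stop = 61, step = 5,
                            pulse_ms = 25, hold_ms = 20, post_ms = 30,
                            sampling_rate_hz = 50000, inter_sweep_s = 5,
                            jp_corrected = TRUE) {
  stopifnot(step > 0)
  if (v_stop < v_start) stop("v_stop must be >= v_start")
  v_test <- seq(v_start, v_stop, by = step)
  if (max(v_test) < v_stop - 1e-9) {
    warning("step does not divide the voltage range; last pulse clipped to ",
            max(v_test), " mV")
  }
  prots <- purrr::map(v_test, function(v) {
    protocol(tibble::tibble(duration_ms = c(hold_ms, pulse_ms, post_ms),
                            v_mV = c(hp, v, hp)),
             sampling_rate_hz = sampling_rate_hz,
             inter_sweep_s = inter_sweep_s,
             label = sprintf("IV %+.0f mV", v), jp_corrected = jp_corrected)
  })
  new_family(prots, "IV", v_test, "v_test")
}

#' Steady-state inactivation (SSI) protocol family
#'
#' Each sweep holds at `hp`, applies a control pulse to `v_test` (the
#' voltage of maximal activation), returns to `hp`, applies a 5-s
#' conditioning step to one of a ladder of potentials in 10-mV increments,
#' and ends with a test pulse to `v_test`. Sweep starts are 30 s apart.
#'
#' @param v_test Control/test pulse potential (Vmax of the cell), mV.
#' @param hp Holding potential, mV.
#' @param control_ms Control/test pulse duration, ms; must lie in
#'   `[20, 75]`.
#' @param cond_ms Conditioning duration, ms (default 5000).
#' @param cond_start,cond_stop,step Conditioning-potential ladder, mV.
#' @param hold_ms Initial holding duration, ms.
#' @param gap_ms Holding gap between control pulse and conditioning, ms.
#' @inheritParams build_iv_family
#' @return A `cav_protocol_family` with one sweep per conditioning
#'   potential.
#' @export
build_ssi_family <- function(v_test, hp = -89, control_ms = 25,
                             cond_ms = 5000, cond_start = -89,
                             cond_stop = 21, step = 10,
                             hold_ms = 100, gap_ms = 100,
                             sampling_rate_hz = 50000, inter_sweep_s = 30,
                             jp_corrected = TRUE) {
  if (control_ms < 20 || control_ms > 75) {
    stop("control pulse must lie within 20-75 ms")
  }
  stopifnot(step > 0, cond_stop >= cond_start)
  v_cond <- seq(cond_start, cond_stop, by = step)
  prots <- purrr::map(v_cond, function(v) {
    protocol(tibble::tibble(
      duration_ms = c(hold_ms, control_ms, gap_ms, cond_ms, control_ms, 50),
      v_mV = c(hp, v_test, hp, v, v_test, hp)),
      sampling_rate_hz = sampling_rate_hz, inter_sweep_s = inter_sweep_s,
      label = sprintf("SSI cond %+.0f mV", v), jp_corrected = jp_corrected)
  })
  new_family(prots, "SSI", v_cond, "v_cond")
}

#' Two-pulse recovery-from-inactivation protocol family
#'
#' A 2-s conditioning prepulse to `v_test`, a variable recovery gap at the
#' holding potential, and a 25-ms test pulse to `v_test`. Gaps span 0.001 to
#' 20 s; the default ladder has 15 logarithmically spaced points. This
#' family is sampled at 10 kHz.
#'
#' @param v_test Prepulse/test potential (Vmax), mV.
#' @param gaps_s Recovery gaps, s; all must lie in `[0.001, 20]`.
#' @param prepulse_ms Conditioning prepulse duration, ms.
#' @param test_ms Test-pulse duration, ms.
#' @inheritParams build_ssi_family
#' @return A `cav_protocol_family` with one sweep per gap.
#' @export
build_recovery_family <- function(v_test, gaps_s = recovery_gap_ladder(),
                                  prepulse_ms = 2000, test_ms = 25,
                                  hp = -89, hold_ms = 50,
                                  sampling_rate_hz = 10000,
                                  inter_sweep_s = 30, jp_corrected = TRUE) {
  if (any(gaps_s < 0.001 - 1e-12 | gaps_s > 20 + 1e-12)) {
    stop("recovery gaps must lie within [0.001, 20] s")
  }
  dt_ms <- 1000 / sampling_rate_hz
  gap_ms <- pmax(round(gaps_s * 1000 / dt_ms), 1) * dt_ms
  prots <- purrr::map(gap_ms, function(g) {
    protocol(tibble::tibble(
      duration_ms = c(hold_ms, prepulse_ms, g, test_ms, 25),
      v_mV = c(hp, v_test, hp, v_test, hp)),
      sampling_rate_hz = sampling_rate_hz, inter_sweep_s = inter_sweep_s,
      label = sprintf("recovery gap %.4g s", g / 1000),
      jp_corrected = jp_corrected)
  })
  new_family(prots, "RECOVERY", gap_ms / 1000, "gap_s")
}

#' @rdname build_recovery_family
#' @param n Number of gap points.
#' @param from,to Gap range, s.
#' @export
recovery_gap_ladder <- function(n = 15, from = 0.001, to = 20) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Tail-current (deactivation) protocol family
#'
#' A 10-ms depolarization to the reversal potential followed by 20-ms
#' repolarizations to a ladder of test potentials in 10-mV steps. The
#' default ladder includes -69 and -49 mV.
#'
#' @param v_rev Reversal potential used for the activating pre-step, mV.
#' @param repol_voltages Repolarization potentials, mV.
#' @param pre_ms Depolarizing pre-step duration, ms.
#' @param repol_ms Repolarization duration, ms (> 0).
#' @inheritParams build_ssi_family
#' @return A `cav_protocol_family` with one sweep per repolarization
#'   potential.
#' @export
build_tail_family <- function(v_rev, repol_voltages = seq(-89, -29, by = 10),
                              pre_ms = 10, repol_ms = 20, hp = -89,
                              hold_ms = 10, sampling_rate_hz = 50000,
                              inter_sweep_s = 5, jp_corrected = TRUE) {
  if (length(repol_voltages) == 0) stop("empty repolarization voltage list")
  if (repol_ms <= 0) stop("repol_ms must be > 0")
  prots <- purrr::map(repol_voltages, function(v) {
    protocol(tibble::tibble(
      duration_ms = c(hold_ms, pre_ms, repol_ms, 10),
      v_mV = c(hp, v_rev, v, hp)),
      sampling_rate_hz = sampling_rate_hz, inter_sweep_s = inter_sweep_s,
      label = sprintf("tail %+.0f mV", v), jp_corrected = jp_corrected)
  })
  new_family(prots, "TAIL", repol_voltages, "v_repol")
}

#' Pharmacology and 5-s inactivation protocols
#'
#' `build_pharm_protocol()`: the drug-application train element, a 100-ms
#' square pulse to `v_test` repeated at 0.1 Hz from the holding potential.
#' `build_inact5s_protocol()`: a single 5-s depolarization to `v_test` used
#' to measure the inactivation time course.
#'
#' @param v_test Test potential (Vmax), mV.
#' @param pulse_ms Pulse duration, ms.
#' @param freq_hz Stimulation frequency, Hz (inter-sweep interval is
#'   `1/freq_hz`).
#' @inheritParams build_ssi_family
#' @return A `cav_protocol`.
#' @export
build_pharm_protocol <- function(v_test, pulse_ms = 100, freq_hz = 0.1,
                                 hp = -89, hold_ms = 50,
                                 sampling_rate_hz = 50000,
                                 jp_corrected = TRUE) {
  stopifnot(freq_hz > 0)
  protocol(tibble::tibble(duration_ms = c(hold_ms, pulse_ms, 50),
                          v_mV = c(hp, v_test, hp)),
           sampling_rate_hz = sampling_rate_hz,
           inter_sweep_s = 1 / freq_hz,
           label = "pharm pulse", jp_corrected = jp_corrected)
}

#' @rdname build_pharm_protocol
#' @param dur_ms Depolarization duration, ms (default 5000).
#' @export
build_inact5s_protocol <- function(v_test, dur_ms = 5000, hp = -89,
                                   hold_ms = 100, sampling_rate_hz = 50000,
                                   jp_corrected = TRUE) {
  protocol(tibble::tibble(duration_ms = c(hold_ms, dur_ms, 50),
                          v_mV = c(hp, v_test, hp)),
           sampling_rate_hz = sampling_rate_hz, inter_sweep_s = 30,
           label = "5-s inactivation", jp_corrected = jp_corrected)
}

#' Liquid-junction-potential correction
#'
#' Command voltages are corrected by the measured liquid junction potential
#' of -9.3 mV: `v_corrected = v_command - 9.3`. For protocols and protocol
#' families the correction is applied to every segment once; a bookkeeping
#' flag prevents double correction.
#'
#' @param x A numeric vector of command voltages, a `cav_protocol` or a
#'   `cav_protocol_family`.
#' @param jp Junction potential, mV (default -9.3).
#' @return The corrected object.
#' @export
junction_correct <- function(x, jp = -9.3) UseMethod("junction_correct")

#' @export
junction_correct.numeric <- function(x, jp = -9.3) {
  stopifnot(all(is.finite(x)))
  x + jp
}

#' @export
junction_correct.cav_protocol <- function(x, jp = -9.3) {
  if (isTRUE(attr(x, "jp_corrected"))) {
    stop("protocol voltages are already junction-corrected")
  }
  x$v_mV <- x$v_mV + jp
  attr(x, "jp_corrected") <- TRUE
  x
}

#' @export
junction_correct.cav_protocol_family <- function(x, jp = -9.3) {
  x$protocols <- purrr::map(x$protocols, junction_correct, jp = jp)
  x
}

#' P/4 leak-subtraction sub-sweeps
#'
#' Builds the four sub-sweeps of the online P/4 leak-subtraction protocol:
#' each sub-sweep applies, from the holding potential, the test waveform's
#' voltage excursions scaled by -1/4 with the same timing (a +40 mV test
#' excursion becomes four -10 mV excursions). The scaled waveform stays in
#' the channel-free hyperpolarized range, so only the linear leak responds.
#'
#' @param test A `cav_protocol` whose first segment is the holding
#'   potential.
#' @return A `cav_protocol_family` of 4 identical sub-sweeps.
#' @export
p4_leak_pulses <- function(test) {
  stopifnot(inherits(test, "cav_protocol"))
  hp <- test$v_mV[1]
  sub <- test
  sub$v_mV <- hp - (test$v_mV - hp) / 4
  attr(sub, "label") <- paste0(attr(test, "label"), " P/4")
  exc <- max(abs(test$v_mV - hp))
  new_family(rep(list(sub), 4), "P4", rep(-exc / 4, 4), "excursion")
}

#' Export a protocol as a stimulus table
#'
#' @param x A `cav_protocol`.
#' @return A tibble with columns `t_ms` and `v_mV`, one row per sample.
#' @export
as_stimulus <- function(x) {
  stopifnot(inherits(x, "cav_protocol"))
  rate <- attr(x, "sampling_rate_hz")
  dt <- 1000 / rate
  n <- round(x$duration_ms / dt)
  tibble::tibble(t_ms = seq_len(sum(n)) * dt,
                 v_mV = rep(x$v_mV, times = n))
}
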