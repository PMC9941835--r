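#' Online P/4 leak subtraction
#'
#' Subtracts the linear (ohmic) leak from a test sweep using the four
#' quarter-amplitude, inverted sub-sweeps of the P/4 protocol. Each sweep is
#' first referenced to its own pre-pulse holding baseline; the four
#' baseline-referenced sub-sweep currents are then summed and added to the
#' baseline-referenced test current, so any linear component cancels
#' exactly. The result is a fully baseline- and leak-subtracted trace.
#'
#' @param test A `cav_sweep` recorded with the test protocol.
#' @param leak_sweeps A list of 4 `cav_sweep`s recorded with
#'   [p4_leak_pulses()] of the same protocol (or a `cav_bundle` of them).
#' @return The corrected `cav_sweep`.
#' @export
p4_subtract <- function(test, leak_sweeps) {
  if (inherits(leak_sweeps, "cav_bundle")) leak_sweeps <- leak_sweeps$sweeps
  stopifnot(inherits(test, "cav_sweep"), length(leak_sweeps) == 4)
  n <- nrow(test)
  rate <- attr(test, "sampling_rate_hz")
  for (s in leak_sweeps) {
    if (nrow(s) != n || !isTRUE(all.equal(attr(s, "sampling_rate_hz"), rate))) {
      stop("P/4 sub-sweeps are misaligned with the test sweep")
    }
  }
  base_idx <- which(cumprod(test$v_mV == test$v_mV[1]) == 1)
  corrected <- test$i_pA - mean(test$i_pA[base_idx])
  for (s in leak_sweeps) {
    corrected <- corrected + (s$i_pA - mean(s$i_pA[base_idx]))
  }
  out <- test
  out$i_pA <- corrected
  meta <- attr(out, "meta"); meta$leak_subtracted <- "P/4"
  attr(out, "meta") <- meta
  out
}

#' Offline linear leak subtraction
#'
#' Fits `I = a + g * V` over the samples in the baseline window(s) and
#' subtracts the predicted linear leak from the whole sweep. If the window
#' contains a single command voltage (zero variance) the slope is
#' unidentifiable and only the mean baseline current is subtracted, with a
#' warning. Alternatively, precomputed leak coefficients (e.g. pooled over
#' the subthreshold sweeps of a family via [estimate_leak()]) can be
#' supplied.
#'
#' @param sweep A `cav_sweep`.
#' @param baseline_window A numeric `c(start, end)` in ms, or a list of such
#'   windows; they should lie in holding/subthreshold segments.
#' @param leak Optional named vector `c(intercept = , g = )` (pA, nS)
#'   overriding the window fit.
#' @return The leak-subtracted `cav_sweep`.
#' @export
offline_linear_subtract <- function(sweep, baseline_window = NULL,
                                    leak = NULL) {
  stopifnot(inherits(sweep, "cav_sweep"))
  if (is.null(leak)) {
    idx <- window_index(sweep, baseline_window)
    if (length(idx) < 2) stop("baseline window contains no samples")
    v <- sweep$v_mV[idx]
    if (stats::var(v) < 1e-12) {
      warning("baseline window has a single voltage; subtracting mean only")
      leak <- c(intercept = mean(sweep$i_pA[idx]), g = 0)
    } else {
      fit <- stats::lm(i ~ v, data = data.frame(i = sweep$i_pA[idx], v = v))
      leak <- c(intercept = unname(stats::coef(fit)[1]),
                g = unname(stats::coef(fit)[2]))
    }
  }
  out <- sweep
  out$i_pA <- sweep$i_pA - (leak[["intercept"]] + leak[["g"]] * sweep$v_mV)
  meta <- attr(out, "meta"); meta$leak_subtracted <- "offline-linear"
  attr(out, "meta") <- meta
  out
}

#' Pooled linear leak estimate over subthreshold sweeps
#'
#' Pools the samples of the given windows across sweeps and fits
#' `I = a + g * V` by ordinary least squares. Used by the steady-state
#' inactivation pipeline, where hyperpolarized-conditioning sweeps provide
#' two channel-free command voltages (holding and conditioning) from which
#' the leak conductance is identifiable.
#'
#' @param sweeps A list of `cav_sweep`s (or a `cav_bundle`).
#' @param windows A window `c(start, end)` in ms or list of windows applied
#'   to each sweep.
#' @return Named vector `c(intercept = , g = )` in pA and nS.
#' @export
estimate_leak <- function(sweeps, windows) {
  if (inherits(sweeps, "cav_bundle")) sweeps <- sweeps$sweeps
  if (inherits(sweeps, "cav_sweep")) sweeps <- list(sweeps)
  dat <- purrr::map_dfr(sweeps, function(s) {
    idx <- window_index(s, windows)
    tibble::tibble(i = s$i_pA[idx], v = s$v_mV[idx])
  })
  if (stats::var(dat$v) < 1e-12) {
    stop("leak estimation windows span a single voltage")
  }
  fit <- stats::lm(i ~ v, data = dat)
  c(intercept = unname(stats::coef(fit)[1]), g = unname(stats::coef(fit)[2]))
}

window_index <- function(sweep, window) {
  if (is.null(window)) {
    # default: the initial holding segment
    return(which(cumprod(sweep$v_mV == sweep$v_mV[1]) == 1))
  }
  if (is.list(window)) {
    return(sort(unique(unlist(lapply(window, window_index, sweep = sweep)))))
  }
  stopifnot(length(window) == 2)
  which(sweep$t_ms >= window[1] - 1e-9 & sweep$t_ms <= window[2] + 1e-9)
}

#' Peak current within a window
#'
#' Inward currents are negative; the peak is the signed minimum of the
#' current in the window (maximum for outward polarity). Current density is
#' the amplitude divided by the cell capacitance.
#'
#' @param sweep A `cav_sweep`.
#' @param window `c(start, end)` in ms; defaults to the whole sweep.
#' @param polarity `"inward"` (default), `"outward"`, or `"absolute"` (the
#'   signed extremum of largest magnitude -- appropriate for I-V families
#'   whose test potentials cross the reversal potential, where the current
#'   turns outward).
#' @return A one-row tibble with `amplitude_pA`, `density_pA_pF`,
#'   `t_peak_ms`.
#' @export
peak_current <- function(sweep, window = NULL,
                         polarity = c("inward", "outward", "absolute")) {
  polarity <- match.arg(polarity)
  idx <- if (is.null(window)) seq_len(nrow(sweep)) else window_index(sweep, window)
  if (length(idx) == 0) stop("empty peak window")
  i <- sweep$i_pA[idx]
  k <- switch(polarity, inward = which.min(i), outward = which.max(i),
              absolute = which.max(abs(i)))
  tibble::tibble(amplitude_pA = i[k],
                 density_pA_pF = i[k] / attr(sweep, "capacitance_pF"),
                 t_peak_ms = sweep$t_ms[idx[k]])
}

#' Linear run-down regression on a control peak series
#'
#' Peak amplitudes are normalized to the first sweep (in percent of the
#' initial peak, computed on magnitudes) and regressed on time in minutes
#' by ordinary least squares.
#'
#' @param peaks Data frame with columns `t_min` and `peak_pA` (>= 3 rows).
#' @return An object of class `cav_rundown`: a list with `slope`
#'   (percent/min), `intercept` (percent), `fit` (the `lm`), and the
#'   normalized data.
#' @export
fit_rundown <- function(peaks) {
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("t_min", "peak_pA") %in% names(peaks)))
  if (nrow(peaks) < 3) stop("run-down regression needs at least 3 points")
  pct <- 100 * abs(peaks$peak_pA) / abs(peaks$peak_pA[1])
  fit <- stats::lm(pct ~ t_min, data = data.frame(pct = pct,
                                                  t_min = peaks$t_min))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 fit = fit,
                 data = tibble::tibble(t_min = peaks$t_min, pct = pct)),
            class = "cav_rundown")
}

#' @export
print.cav_rundown <- function(x, ...) {
  cat(sprintf("<cav_rundown> slope = %.4f %%/min (intercept %.2f %%)\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Run-down-corrected inhibition series
#'
#' Converts a drug-run peak series into percent inhibition relative to the
#' drug-free current predicted by the control run-down regression:
#' `inhibition(t) = 100 * (1 - peak(t) / predicted(t))`, on magnitudes.
#' The drug-free scale is anchored on the run's initial control sweeps
#' (`conc_nM == 0` before the first application).
#'
#' @param peaks Data frame with columns `t_min`, `peak_pA` and `conc_nM`.
#' @param rundown A `cav_rundown` from the matched control condition.
#' @return The input tibble with an added `inhibition_pct` column, clipped
#'   to `[0, 100]` (with a warning when more than 2 points clip).
#' @export
rundown_correct <- function(peaks, rundown) {
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("t_min", "peak_pA", "conc_nM") %in% names(peaks)),
            inherits(rundown, "cav_rundown"))
  ctrl <- which(cumprod(peaks$conc_nM == 0) == 1)
  if (length(ctrl) == 0) stop("no leading drug-free control sweeps found")
  trend <- (rundown$intercept + rundown$slope * peaks$t_min) / 100
  if (any(trend <= 0)) stop("predicted drug-free current is <= 0")
  peak0 <- mean(abs(peaks$peak_pA[ctrl]) / trend[ctrl])
  predicted <- peak0 * trend
  inh <- 100 * (1 - abs(peaks$peak_pA) / predicted)
  n_clip <- sum(inh < 0 | inh > 100)
  if (n_clip > 2) {
    warning(n_clip, " inhibition points clipped to [0, 100]")
  }
  peaks$inhibition_pct <- pmin(pmax(inh, 0), 100)
  peaks
}

#' Peak series of a pharmacology bundle
#'
#' Applies offline baseline subtraction to each sweep of a `PHARM` bundle
#' and extracts the peak inward current of the test pulse, together with
#' the sweep time (minutes from the first sweep) and concentration tag.
#'
#' @param bundle A `cav_bundle` from [simulate_pharmacology_run()] (or read
#'   from disk).
#' @return Tibble with `sweep`, `t_min`, `conc_nM`, `peak_pA`.
#' @export
pharm_peaks <- function(bundle) {
  stopifnot(inherits(bundle, "cav_bundle"))
  purrr::imap_dfr(bundle$sweeps, function(s, k) {
    meta <- attr(s, "meta")
    sub <- offline_linear_subtract_quiet(s)
    pk <- peak_current(sub, window = pulse_window(s))
    tibble::tibble(sweep = k, t_min = meta$start_s / 60,
                   conc_nM = meta$conc_nM %||% 0,
                   peak_pA = pk$amplitude_pA)
  })
}

# mean-baseline subtraction without the degenerate-window warning; used by
# pipelines whose protocols hold a single baseline voltage by design
offline_linear_subtract_quiet <- function(sweep, window = NULL) {
  idx <- window_index(sweep, window)
  v <- sweep$v_mV[idx]
  if (stats::var(v) < 1e-12) {
    out <- sweep
    out$i_pA <- sweep$i_pA - mean(sweep$i_pA[idx])
    return(out)
  }
  offline_linear_subtract(sweep, window)
}

# window (ms) of the first segment that deviates from the initial holding
# voltage
pulse_window <- function(sweep) {
  hp <- sweep$v_mV[1]
  idx <- which(abs(sweep$v_mV - hp) > 1e-9)
  if (length(idx) == 0) stop("sweep has no test pulse")
  first <- idx[1]
  last <- idx[which(c(diff(idx), 2) > 1)[1]]
  c(sweep$t_ms[first], sweep$t_ms[last])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
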