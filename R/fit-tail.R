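#' Analyze a tail-current (deactivation) sweep
#'
#' Within the repolarization segment, locates the tail-current peak, fits a
#' mono-exponential (plus plateau) to the decaying phase to obtain the
#' deactivation time constant, integrates the peak-normalized tail over
#' 20 ms (a charge measure in ms), and reports whether the peak is delayed
#' relative to the repolarization onset (a "hook", indicating channel
#' reopening): present when the delay exceeds 2 samples.
#'
#' @param sweep A leak-subtracted `cav_sweep` from a tail protocol.
#' @param repol_window Optional `c(start, end)` ms of the repolarization
#'   segment; by default the segment following the depolarizing pre-step.
#' @param integral_ms Integration span, ms (default 20).
#' @param noise_floor_pA Minimum tail-peak magnitude, pA; smaller tails are
#'   rejected as unmeasurable.
#' @return A `cav_tail_fit` with `v_repol`, `tau_deact` (ms),
#'   `normalized_integral` (ms, in `(0, integral_ms]`), `hook_present`,
#'   `hook_delay_ms`.
#' @export
analyze_tail <- function(sweep, repol_window = NULL, integral_ms = 20,
                         noise_floor_pA = 1) {
  stopifnot(inherits(sweep, "cav_sweep"))
  if (is.null(repol_window)) {
    # segment after the first non-holding (depolarizing) segment
    hp <- sweep$v_mV[1]
    segs <- rle(sweep$v_mV)
    ends <- cumsum(segs$lengths)
    starts <- ends - segs$lengths + 1
    dep <- which(abs(segs$values - hp) > 1e-9)[1]
    if (is.na(dep) || dep + 1 > length(segs$values)) {
      stop("could not locate a repolarization segment")
    }
    repol_window <- c(sweep$t_ms[starts[dep + 1]], sweep$t_ms[ends[dep + 1]])
  }
  idx <- window_index(sweep, repol_window)
  dt <- 1000 / attr(sweep, "sampling_rate_hz")
  if (length(idx) * dt < integral_ms - 1e-6) {
    stop("repolarization segment must cover at least ", integral_ms, " ms")
  }
  i <- sweep$i_pA[idx]
  t <- sweep$t_ms[idx] - sweep$t_ms[idx[1]]
  kpk <- which.min(i)
  peak <- i[kpk]
  if (abs(peak) < noise_floor_pA) stop("no measurable tail current")
  hook_delay <- t[kpk]
  hook_present <- hook_delay > 2 * dt + 1e-9

  # deactivation time constant from the decaying phase (peak onward)
  dec <- tibble::tibble(t = t[kpk:length(t)] - t[kpk], i = i[kpk:length(i)])
  tau0 <- max(dec$t[which(dec$i <= peak * exp(-1))[1]], dt)
  if (!is.finite(tau0)) tau0 <- max(dec$t) / 3
  fit <- nls_lm(i ~ a * exp(-t / tau) + c0, dec,
                start = list(a = peak, tau = tau0, c0 = 0),
                lower = c(a = -Inf, tau = dt / 10, c0 = -Inf),
                upper = c(a = 0, tau = 1000, c0 = Inf))
  cf <- stats::coef(fit); se <- fit_se(fit)

  keep <- t <= integral_ms + 1e-9
  integral <- sum(diff(t[keep]) *
                    (utils::head(i[keep] / peak, -1) +
                       utils::tail(i[keep] / peak, -1)) / 2)
  new_cav_fit("cav_tail_fit",
              params = list(v_repol = sweep$v_mV[idx[1]],
                            tau_deact = cf[["tau"]],
                            normalized_integral = integral,
                            hook_delay_ms = hook_delay),
              se = c(tau_deact = se[["tau"]]),
              rss = sum(stats::resid(fit)^2), n = nrow(dec), fit = fit,
              data = tibble::tibble(t_ms = t, i_pA = i),
              extra = list(hook_present = hook_present))
}
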