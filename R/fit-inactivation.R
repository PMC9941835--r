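#' Fit the steady-state inactivation curve
#'
#' Fits test/control current-amplitude ratios against conditioning voltage
#' with the modified Boltzmann
#' `I = I_ni + (1 - I_ni) / (1 + exp((V - V0.5,inact) / k_inact))`,
#' where `I_ni` is the non-inactivating current component.
#'
#' @param data Data frame with columns `v_mV` (conditioning voltage) and
#'   `ratio` (I/Icontrol). Ratios must lie in `[0, 1.05]`; at least 6
#'   conditioning voltages are required.
#' @return A `cav_ssi_fit` with parameters `v05_inact`, `k_inact`,
#'   `frac_noninact`; a fit with `I_ni` pinned at 0 or 1 is flagged.
#' @export
fit_ssi <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("v_mV", "ratio") %in% names(data)))
  df <- tibble::tibble(v = data$v_mV, r = data$ratio)
  df <- df[stats::complete.cases(df), ]
  df <- df[order(df$v), ]
  if (nrow(df) < 6) stop("fit_ssi needs at least 6 conditioning voltages")
  if (any(df$r < 0 | df$r > 1.05)) {
    stop("SSI ratios must lie within [0, 1.05]")
  }
  if (max(df$r) - min(df$r) < 0.02) {
    stop("degenerate SSI data: ratios are constant, I_ni indeterminate")
  }
  ini0 <- min(df$r)
  v05_0 <- half_crossing(df$v, df$r, ini0 + (max(df$r) - ini0) / 2)
  start <- list(ini = ini0, v05 = v05_0, k = 6)
  lower <- c(ini = 0, v05 = -150, k = 0.5)
  upper <- c(ini = 1, v05 = 50, k = 30)
  fit <- nls_lm(r ~ ini + (1 - ini) / (1 + exp((v - v05) / k)),
                df, start, lower, upper)
  cf <- stats::coef(fit); se <- fit_se(fit)
  flags <- character()
  if ("ini" %in% pinned_at(cf, lower, upper)) flags <- c(flags, "I_ni_at_bound")
  if ("k" %in% pinned_at(cf, lower, upper)) flags <- c(flags, "k_at_bound")
  new_cav_fit("cav_ssi_fit",
              params = list(v05_inact = cf[["v05"]], k_inact = cf[["k"]],
                            frac_noninact = cf[["ini"]]),
              se = c(v05_inact = se[["v05"]], k_inact = se[["k"]],
                     frac_noninact = se[["ini"]]),
              rss = sum(stats::resid(fit)^2), n = nrow(df),
              fit = fit, flags = flags, data = df)
}

#' Window-current profile
#'
#' The voltage-resolved estimate of steady calcium influx: the product of
#' the peak current density and the fractional steady-state availability at
#' each voltage of the I-V grid (the SSI curve is evaluated on the I-V
#' voltages).
#'
#' @param iv_data Data frame with columns `v_mV` and `density_pA_pF`.
#' @param ssi A `cav_ssi_fit` (or a [gating_params()] object, whose
#'   steady-state availability is used directly).
#' @return A tibble with `v_mV`, `density_pA_pF`, `availability` and
#'   `window_pA_pF = density * availability`; class `cav_window`.
#' @export
window_current <- function(iv_data, ssi) {
  iv_data <- tibble::as_tibble(iv_data)
  stopifnot(all(c("v_mV", "density_pA_pF") %in% names(iv_data)))
  avail <- if (inherits(ssi, "cav_gating_params")) {
    steady_state_availability(iv_data$v_mV, ssi)
  } else if (inherits(ssi, "cav_ssi_fit")) {
    p <- ssi$params
    p$frac_noninact + (1 - p$frac_noninact) /
      (1 + exp((iv_data$v_mV - p$v05_inact) / p$k_inact))
  } else stop("ssi must be a cav_ssi_fit or gating_params")
  out <- tibble::tibble(v_mV = iv_data$v_mV,
                        density_pA_pF = iv_data$density_pA_pF,
                        availability = avail,
                        window_pA_pF = iv_data$density_pA_pF * avail)
  class(out) <- c("cav_window", class(out))
  out
}

#' Extract the decay phase of a long depolarization
#'
#' Returns the current from the peak to the end of the depolarizing pulse,
#' expressed in percent of the peak inward current (on magnitudes), with
#' time measured from the peak.
#'
#' @param sweep A baseline-subtracted `cav_sweep` containing a long
#'   depolarizing pulse.
#' @param window Optional pulse window `c(start, end)` ms; by default the
#'   first non-holding segment.
#' @return Tibble with `t_ms` (0 at the peak) and `pct`.
#' @export
extract_decay <- function(sweep, window = NULL) {
  if (is.null(window)) window <- pulse_window(sweep)
  idx <- window_index(sweep, window)
  i <- sweep$i_pA[idx]
  kpk <- which.min(i)
  peak <- i[kpk]
  if (abs(peak) < 1e-9) stop("no measurable inward current in pulse window")
  keep <- idx[kpk:length(idx)]
  tibble::tibble(t_ms = sweep$t_ms[keep] - sweep$t_ms[idx[kpk]],
                 pct = 100 * sweep$i_pA[keep] / peak)
}

#' Remaining current fractions at prespecified times
#'
#' `r_t`: the current remaining at time `t` after the peak, in percent of
#' the peak inward current. The conventional time points for a 5-s
#' depolarization are 50, 100, 250, 500, 1000 and 5000 ms. When the peak
#' latency pushes `t` a few ms past the end of the pulse, the final
#' in-pulse sample is used (the overshoot is far below the decay time
#' constants).
#'
#' @param x A `cav_sweep` or a decay tibble from [extract_decay()].
#' @param times Times after the peak, ms.
#' @param window Passed to [extract_decay()] when `x` is a sweep.
#' @return Tibble with `t_ms` and `r_pct`.
#' @export
remaining_fractions <- function(x, times = c(50, 100, 250, 500, 1000, 5000),
                                window = NULL) {
  decay <- if (inherits(x, "cav_sweep")) extract_decay(x, window) else
    tibble::as_tibble(x)
  stopifnot(all(c("t_ms", "pct") %in% names(decay)))
  t_end <- max(decay$t_ms)
  over <- times > t_end
  if (any(times[over] > t_end * 1.02)) {
    stop("requested time lies beyond the depolarizing pulse")
  }
  tq <- pmin(times, t_end)
  r <- stats::approx(decay$t_ms, decay$pct, xout = tq)$y
  tibble::tibble(t_ms = times, r_pct = r)
}

#' Fit the inactivation time course
#'
#' Least-squares fit of the decay (percent of peak) to
#' `plateau + sum A_i * exp(-t / tau_i)` with one (`mono`) or two (`bi`)
#' exponential components. With `model = "auto"`, the bi-exponential is
#' selected over the mono-exponential only if the extra sum-of-squares
#' F-test gives p < 0.05; a bi-exponential whose time constants collapse
#' (`tau_fast / tau_slow > 0.8`) is refit as mono and flagged, and an
#' (effectively) exactly mono trace short-circuits to mono.
#'
#' @param x A `cav_sweep` (>= 1 s depolarization) or a decay tibble with
#'   columns `t_ms`, `pct`.
#' @param model `"mono"`, `"bi"` or `"auto"`.
#' @param max_points Decays longer than this are thinned evenly before
#'   fitting (keeps the LM solver fast on 50-kHz traces without affecting a
#'   noise-free fit).
#' @param window Passed to [extract_decay()] when `x` is a sweep.
#' @return A `cav_decay_fit` with `model`, amplitudes (% of peak), time
#'   constants (ms, `tau_fast < tau_slow`), `plateau` (%), and the
#'   model-selection F-test when `model = "auto"`.
#' @export
fit_decay <- function(x, model = c("auto", "mono", "bi"), max_points = 2500,
                      window = NULL) {
  model <- match.arg(model)
  decay <- if (inherits(x, "cav_sweep")) extract_decay(x, window) else
    tibble::as_tibble(x)
  stopifnot(all(c("t_ms", "pct") %in% names(decay)))
  if (max(decay$t_ms) < 1000) stop("decay trace must cover at least 1 s")
  if (nrow(decay) > max_points) {
    decay <- decay[unique(round(seq(1, nrow(decay), length.out = max_points))), ]
  }
  mono <- fit_decay_mono(decay)
  if (model == "mono") return(mono)
  if (model == "bi") return(fit_decay_bi(decay))
  # auto selection
  tss <- sum((decay$pct - mean(decay$pct))^2)
  if (mono$rss / tss < 1e-12) return(add_ftest(mono, NULL))
  bi <- tryCatch(fit_decay_bi(decay), error = function(e) NULL)
  if (is.null(bi) || bi$rss >= mono$rss) return(add_ftest(mono, NULL))
  if (bi$params$tau_fast / bi$params$tau_slow > 0.8) {
    mono$flags <- c(mono$flags, "tau_collapse")
    return(add_ftest(mono, NULL))
  }
  ft <- ess_f_test(mono$rss, mono$n - 3, bi$rss, bi$n - 5)
  if (ft$p < 0.05) add_ftest(bi, ft) else add_ftest(mono, ft)
}

add_ftest <- function(fit, ft) { fit$f_test <- ft; fit }

fit_decay_mono <- function(decay) {
  plateau0 <- min(mean(decay$pct[decay$t_ms >= 0.9 * max(decay$t_ms)]), 99)
  a0 <- max(decay$pct[1] - plateau0, 1)
  tau0 <- log_linear_tau(decay, plateau0)
  start <- list(a = a0, tau = tau0, plateau = max(plateau0, 0))
  lower <- c(a = 0, tau = 1, plateau = 0)
  upper <- c(a = 200, tau = 60000, plateau = 100)
  fit <- nls_lm(pct ~ plateau + a * exp(-t_ms / tau), decay, start, lower, upper)
  cf <- stats::coef(fit); se <- fit_se(fit)
  new_cav_fit("cav_decay_fit",
              params = list(a_fast = NA_real_, tau_fast = NA_real_,
                            a_slow = cf[["a"]], tau_slow = cf[["tau"]],
                            plateau = cf[["plateau"]]),
              se = c(a_slow = se[["a"]], tau_slow = se[["tau"]],
                     plateau = se[["plateau"]]),
              rss = sum(stats::resid(fit)^2), n = nrow(decay), fit = fit,
              data = decay, extra = list(model = "mono"))
}

fit_decay_bi <- function(decay) {
  plateau0 <- min(mean(decay$pct[decay$t_ms >= 0.9 * max(decay$t_ms)]), 99)
  amp0 <- max(decay$pct[1] - plateau0, 1)
  tau0 <- log_linear_tau(decay, plateau0)
  start <- list(af = 0.6 * amp0, tf = tau0 / 5, as = 0.4 * amp0, ts = tau0 * 2,
                plateau = max(plateau0, 0))
  lower <- c(af = 0, tf = 1, as = 0, ts = 1, plateau = 0)
  upper <- c(af = 200, tf = 60000, as = 200, ts = 60000, plateau = 100)
  fit <- nls_lm(pct ~ plateau + af * exp(-t_ms / tf) + as * exp(-t_ms / ts),
                decay, start, lower, upper)
  cf <- stats::coef(fit); se <- fit_se(fit)
  if (cf[["tf"]] > cf[["ts"]]) {  # order: tau_fast < tau_slow
    cf <- cf[c("as", "ts", "af", "tf", "plateau")]
    names(cf) <- c("af", "tf", "as", "ts", "plateau")
    se <- se[c("as", "ts", "af", "tf", "plateau")]
    names(se) <- c("af", "tf", "as", "ts", "plateau")
  }
  new_cav_fit("cav_decay_fit",
              params = list(a_fast = cf[["af"]], tau_fast = cf[["tf"]],
                            a_slow = cf[["as"]], tau_slow = cf[["ts"]],
                            plateau = cf[["plateau"]]),
              se = c(a_fast = se[["af"]], tau_fast = se[["tf"]],
                     a_slow = se[["as"]], tau_slow = se[["ts"]],
                     plateau = se[["plateau"]]),
              rss = sum(stats::resid(fit)^2), n = nrow(decay), fit = fit,
              data = decay, extra = list(model = "bi"))
}

# crude tau from a log-linear regression on the plateau-subtracted tail
log_linear_tau <- function(decay, plateau) {
  y <- decay$pct - plateau
  keep <- y > max(y) * 0.02
  if (sum(keep) < 3) return(max(decay$t_ms) / 3)
  fit <- stats::lm(log(y[keep]) ~ decay$t_ms[keep])
  tau <- -1 / stats::coef(fit)[2]
  if (!is.finite(tau) || tau <= 1) tau <- max(decay$t_ms) / 3
  min(tau, 59000)
}
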