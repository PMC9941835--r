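#' Double-exponential recovery-curve model
#'
#' `frac(t) = offset + A_fast * (1 - exp(-t / tau_fast))
#'          + A_slow * (1 - exp(-t / tau_slow))`
#' evaluated at recovery gaps `t` (ms). Used both to generate closed-form
#' fixtures from a parameter set and as the fitted model.
#'
#' @param t_ms Recovery gaps, ms.
#' @param params List with `a_fast`, `tau_fast`, `a_slow`, `tau_slow`,
#'   `offset` (e.g. [preset_recovery()]).
#' @return Fractional recovery at each gap.
#' @export
recovery_curve <- function(t_ms, params) {
  params$offset +
    params$a_fast * (1 - exp(-t_ms / params$tau_fast)) +
    params$a_slow * (1 - exp(-t_ms / params$tau_slow))
}

#' Fit recovery from inactivation
#'
#' Fits fractional recovery against the recovery gap with a double
#' exponential plus a free instantaneous offset (the fitted amplitudes are
#' not constrained to sum to 1). Components are ordered so that
#' `tau_fast < tau_slow`.
#'
#' The offset (the instantaneous/unrecovered fraction) is bounded to
#' `[0, offset_max]`. When the shortest measured gap already shows a
#' fraction above `offset_max` -- e.g. after a conditioning pulse that is
#' short relative to a slow inactivation time constant -- the bound is
#' raised to just above that observed floor, since capping the offset
#' below the data would force a spurious fast component.
#'
#' @param data Data frame with columns `gap_s` (or `t_ms`) and `fraction`.
#'   At least 6 gaps spanning two decades are required.
#' @param offset_max Default upper bound of the instantaneous offset.
#' @return A `cav_recovery_fit` with `a_fast`, `tau_fast` (ms), `a_slow`,
#'   `tau_slow` (ms), `offset`.
#' @export
fit_recovery <- function(data, offset_max = 0.3) {
  data <- tibble::as_tibble(data)
  t_ms <- if ("t_ms" %in% names(data)) data$t_ms else {
    stopifnot("gap_s" %in% names(data)); data$gap_s * 1000
  }
  df <- tibble::tibble(t = t_ms, y = data$fraction)
  df <- df[stats::complete.cases(df), ]
  df <- df[order(df$t), ]
  if (nrow(df) < 6) stop("fit_recovery needs at least 6 gap points")
  if (max(df$t) / min(df$t) < 100) {
    stop("recovery gaps must span at least two decades")
  }
  offset_max <- max(offset_max, min(df$y) * 1.02)
  off0 <- min(max(min(df$y), 0), offset_max)
  amp <- max(df$y) - off0
  t_half <- half_crossing(df$t, df$y, off0 + amp / 2)
  start <- list(af = 0.7 * amp, tf = max(t_half, 2), as = 0.3 * amp,
                ts = max(t_half * 50, 500), offset = off0)
  lower <- c(af = 0, tf = 1, as = 0, ts = 1, offset = 0)
  upper <- c(af = 1, tf = 60000, as = 1, ts = 600000, offset = offset_max)
  fit <- nls_lm(y ~ offset + af * (1 - exp(-t / tf)) + as * (1 - exp(-t / ts)),
                df, start, lower, upper)
  cf <- stats::coef(fit); se <- fit_se(fit)
  if (cf[["tf"]] > cf[["ts"]]) {
    cf <- cf[c("as", "ts", "af", "tf", "offset")]
    names(cf) <- c("af", "tf", "as", "ts", "offset")
    se <- se[c("as", "ts", "af", "tf", "offset")]
    names(se) <- c("af", "tf", "as", "ts", "offset")
  }
  flags <- character()
  pin <- pinned_at(cf, lower[c("af", "tf", "as", "ts", "offset")],
                   upper[c("af", "tf", "as", "ts", "offset")])
  if (any(c("af", "as") %in% pin)) flags <- "amplitude_at_bound"
  new_cav_fit("cav_recovery_fit",
              params = list(a_fast = cf[["af"]], tau_fast = cf[["tf"]],
                            a_slow = cf[["as"]], tau_slow = cf[["ts"]],
                            offset = cf[["offset"]]),
              se = c(a_fast = se[["af"]], tau_fast = se[["tf"]],
                     a_slow = se[["as"]], tau_slow = se[["ts"]],
                     offset = se[["offset"]]),
              rss = sum(stats::resid(fit)^2), n = nrow(df),
              fit = fit, flags = flags, data = df)
}
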