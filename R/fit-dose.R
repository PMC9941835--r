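#' Hill (slope 1) equilibrium inhibition
#'
#' Fractional block `100 * c / (c + IC50)` in percent, the equilibrium of
#' the one-site binding model with Hill slope 1.
#'
#' @param conc_nM Concentration(s), nM.
#' @param ic50_nM Half-maximal inhibitory concentration, nM.
#' @return Percent inhibition.
#' @export
hill_inhibition <- function(conc_nM, ic50_nM) {
  100 * conc_nM / (conc_nM + ic50_nM)
}

#' Fit the concentration-inhibition curve (IC50)
#'
#' Fits run-down-corrected steady-state inhibition against concentration
#' with the log-concentration Hill model with slope 1 and both asymptotes
#' fixed (bottom = 0, top = 100):
#' `remaining = 100 / (1 + 10^(X - logIC50))`, `X = log10(concentration)`.
#' Only `logIC50` is free; its asymptotic 95% CI is exponentiated to the
#' concentration scale.
#'
#' @param data Data frame with columns `conc_nM` (> 0) and
#'   `inhibition_pct`. At least 2 concentrations are required.
#' @return A `cav_dose_fit` with `ic50_nM`, `log_ic50`, `ic50_ci_nM`
#'   (length-2), standard error of `logIC50`, and residual SS.
#' @export
fit_dose_response <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("conc_nM", "inhibition_pct") %in% names(data)))
  df <- tibble::tibble(x = log10(data$conc_nM),
                       y = 100 - data$inhibition_pct)
  df <- df[stats::complete.cases(df) & is.finite(df$x), ]
  if (nrow(df) < 2) stop("fit_dose_response needs at least 2 concentrations")
  if (all(df$y < 1e-9) || all(df$y > 100 - 1e-9)) {
    stop("degenerate dose-response data: all points at an asymptote")
  }
  ord <- order(df$x)
  if (any(diff(df$y[ord]) > 5)) {
    warning("inhibition decreases with concentration beyond tolerance")
  }
  # start: average per-point closed-form inversion
  y_in <- pmin(pmax(df$y, 1), 99)
  start <- list(logic50 = mean(df$x + log10(y_in / (100 - y_in))))
  fit <- nls_lm(y ~ 100 / (1 + 10^(x - logic50)), df, start,
                lower = c(logic50 = -3), upper = c(logic50 = 9))
  cf <- stats::coef(fit); se <- fit_se(fit)
  # an exact (zero-residual) fit has no estimable spread: the CI collapses
  se_l <- if (is.finite(se[["logic50"]])) se[["logic50"]] else 0
  ci <- cf[["logic50"]] + c(-1, 1) * stats::qnorm(0.975) * se_l
  new_cav_fit("cav_dose_fit",
              params = list(ic50_nM = 10^cf[["logic50"]],
                            log_ic50 = cf[["logic50"]]),
              se = c(log_ic50 = se[["logic50"]]),
              rss = sum(stats::resid(fit)^2), n = nrow(df), fit = fit,
              data = tibble::tibble(conc_nM = data$conc_nM,
                                    inhibition_pct = data$inhibition_pct),
              extra = list(ic50_ci_nM = 10^ci))
}

#' Steady-state inhibition per concentration
#'
#' Averages the last `n_last` sweeps at each non-zero concentration of a
#' run-down-corrected inhibition series (the paper-style "steady-state
#' inhibition" read-out; the averaging rule is configurable).
#'
#' @param inhibition Tibble from [rundown_correct()] (columns `conc_nM`,
#'   `inhibition_pct`, `sweep`).
#' @param n_last Number of final sweeps to average per concentration.
#' @param drop_full_block Concentrations at or above this value (nM) are
#'   treated as the full-block reference and excluded from the returned
#'   table (default `Inf`: keep everything).
#' @return Tibble with `conc_nM` and `inhibition_pct`.
#' @export
steady_state_inhibition <- function(inhibition, n_last = 3,
                                    drop_full_block = Inf) {
  inhibition <- tibble::as_tibble(inhibition)
  stopifnot(all(c("conc_nM", "inhibition_pct") %in% names(inhibition)))
  inhibition |>
    dplyr::filter(.data$conc_nM > 0, .data$conc_nM < drop_full_block) |>
    dplyr::group_by(.data$conc_nM) |>
    dplyr::slice_tail(n = n_last) |>
    dplyr::summarise(inhibition_pct = mean(.data$inhibition_pct),
                     .groups = "drop")
}
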