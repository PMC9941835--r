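#' Fit the current-voltage relationship
#'
#' Fits peak current densities from an I-V family to the product of a
#' linear ohmic driving force and a Boltzmann activation term:
#' `I(V) = Gmax * (V - Vrev) / (1 + exp(-(V - V0.5,act) / k_act))`.
#'
#' Initialization: `Vrev` from the interpolated zero crossing of the
#' density beyond the peak, `V0.5` from the interpolated half-maximum
#' crossing of the chord conductance, `k = 6` mV. `k` is bounded to
#' `(0.5, 30)` mV; a fit pinned at either bound is flagged.
#'
#' @param data Data frame with columns `v_mV` and `density_pA_pF` (or
#'   `amplitude_pA`; the fitted `gmax` is then in nS). At least 6 voltages
#'   spanning the rising phase and the reversal approach are required.
#' @return A `cav_iv_fit` with parameters `v05_act`, `k_act`, `v_rev`,
#'   `gmax`, standard errors, and residual sum of squares. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_iv <- function(data) {
  data <- tibble::as_tibble(data)
  ycol <- if ("density_pA_pF" %in% names(data)) "density_pA_pF" else "amplitude_pA"
  stopifnot("v_mV" %in% names(data), ycol %in% names(data))
  df <- tibble::tibble(v = data$v_mV, y = data[[ycol]])
  df <- df[stats::complete.cases(df), ]
  df <- df[order(df$v), ]
  if (nrow(df) < 6) stop("fit_iv needs at least 6 voltages")
  if (all(abs(df$y) < 1e-12)) stop("degenerate I-V data: all densities zero")

  k_pk <- which.min(df$y)
  vrev0 <- {
    post <- df[df$v > df$v[k_pk], ]
    cross <- which(post$y[-1] > 0 & post$y[-nrow(post)] <= 0)
    if (nrow(post) > 1 && length(cross) > 0) {
      half_crossing(post$v, post$y, 0)
    } else max(df$v) + 10
  }
  sub <- df[df$v <= vrev0 - 10, ]
  g <- sub$y / (sub$v - vrev0)
  v05_0 <- half_crossing(sub$v, g / max(g), 0.5)
  start <- list(gmax = max(g), v05 = v05_0, k = 6, vrev = vrev0)
  lower <- c(gmax = 1e-9, v05 = -150, k = 0.5, vrev = -50)
  upper <- c(gmax = Inf, v05 = 100, k = 30, vrev = 200)
  fit <- nls_lm(y ~ gmax * (v - vrev) / (1 + exp(-(v - v05) / k)),
                df, start, lower, upper)
  cf <- stats::coef(fit)
  se <- fit_se(fit)
  flags <- if (any(c("k") %in% pinned_at(cf, lower, upper)))
    "k_at_bound" else character()
  new_cav_fit("cav_iv_fit",
              params = list(v05_act = cf[["v05"]], k_act = cf[["k"]],
                            v_rev = cf[["vrev"]], gmax = cf[["gmax"]]),
              se = c(v05_act = se[["v05"]], k_act = se[["k"]],
                     v_rev = se[["vrev"]], gmax = se[["gmax"]]),
              rss = sum(stats::resid(fit)^2), n = nrow(df),
              fit = fit, flags = flags, data = df)
}

#' Fit the conductance-voltage (activation) Boltzmann
#'
#' Converts peak currents to chord conductances `G = I / (V - Vrev)` away
#' from the reversal potential (`|V - Vrev| >= 10` mV) and fits
#' `G(V) = Gmax / (1 + exp(-(V - V0.5,act) / k_act))`.
#'
#' @param data Data frame with columns `v_mV` and `density_pA_pF` (or
#'   `g_nS_pF` to supply conductances directly).
#' @param v_rev Reversal potential used for the conversion, mV (e.g. from
#'   [fit_iv()]).
#' @return A `cav_conductance_fit` with `v05_act`, `k_act`, `gmax`.
#' @export
fit_conductance <- function(data, v_rev = NULL) {
  data <- tibble::as_tibble(data)
  if ("g_nS_pF" %in% names(data)) {
    df <- tibble::tibble(v = data$v_mV, g = data$g_nS_pF)
  } else {
    stopifnot(!is.null(v_rev))
    keep <- data$v_mV <= v_rev - 10
    df <- tibble::tibble(v = data$v_mV[keep],
                         g = data$density_pA_pF[keep] / (data$v_mV[keep] - v_rev))
  }
  df <- df[stats::complete.cases(df), ]
  df <- df[order(df$v), ]
  if (nrow(df) < 5) stop("fit_conductance needs at least 5 usable voltages")
  start <- list(gmax = max(df$g), v05 = half_crossing(df$v, df$g / max(df$g), 0.5),
                k = 6)
  lower <- c(gmax = 1e-9, v05 = -150, k = 0.5)
  upper <- c(gmax = Inf, v05 = 100, k = 30)
  fit <- nls_lm(g ~ gmax / (1 + exp(-(v - v05) / k)), df, start, lower, upper)
  cf <- stats::coef(fit); se <- fit_se(fit)
  flags <- if ("k" %in% pinned_at(cf, lower, upper)) "k_at_bound" else character()
  new_cav_fit("cav_conductance_fit",
              params = list(v05_act = cf[["v05"]], k_act = cf[["k"]],
                            gmax = cf[["gmax"]]),
              se = c(v05_act = se[["v05"]], k_act = se[["k"]],
                     gmax = se[["gmax"]]),
              rss = sum(stats::resid(fit)^2), n = nrow(df),
              fit = fit, flags = flags, data = df)
}
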