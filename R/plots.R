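#' Plot methods
#'
#' `autoplot()` methods for the package's result objects: sweep bundles
#' (current traces), I-V fits (peak densities with the fitted
#' driving-force Boltzmann), SSI fits, window-current profiles, recovery
#' fits (log time axis) and concentration-inhibition fits (log
#' concentration axis).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name cav-autoplot
NULL

#' @rdname cav-autoplot
#' @param n_max Maximum number of sweeps to draw.
#' @method autoplot cav_bundle
#' @export
autoplot.cav_bundle <- function(object, n_max = 20, ...) {
  df <- as_tibble.cav_bundle(object)
  keep <- unique(round(seq(1, length(object$sweeps),
                           length.out = min(n_max, length(object$sweeps)))))
  df <- df[df$sweep %in% keep, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$t_ms, .data$i_pA,
                                   group = .data$sweep,
                                   colour = factor(.data$sweep))) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::labs(x = "time (ms)", y = "current (pA)",
                  title = object$family_kind)
}

#' @rdname cav-autoplot
#' @method autoplot cav_iv_fit
#' @export
autoplot.cav_iv_fit <- function(object, ...) {
  p <- object$params
  grid <- tibble::tibble(v = seq(min(object$data$v), max(object$data$v),
                                 length.out = 200))
  grid$y <- p$gmax * (grid$v - p$v_rev) /
    (1 + exp(-(grid$v - p$v05_act) / p$k_act))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$v, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::labs(x = "test potential (mV)", y = "peak density (pA/pF)")
}

#' @rdname cav-autoplot
#' @method autoplot cav_ssi_fit
#' @export
autoplot.cav_ssi_fit <- function(object, ...) {
  p <- object$params
  grid <- tibble::tibble(v = seq(min(object$data$v), max(object$data$v),
                                 length.out = 200))
  grid$y <- p$frac_noninact + (1 - p$frac_noninact) /
    (1 + exp((grid$v - p$v05_inact) / p$k_inact))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$v, .data$r)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$y),
                       colour = "grey40") +
    ggplot2::labs(x = "conditioning potential (mV)", y = "I / Icontrol")
}

#' @rdname cav-autoplot
#' @method autoplot cav_window
#' @export
autoplot.cav_window <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$v_mV, .data$window_pA_pF)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "potential (mV)", y = "window current (pA/pF)")
}

#' @rdname cav-autoplot
#' @method autoplot cav_recovery_fit
#' @export
autoplot.cav_recovery_fit <- function(object, ...) {
  p <- object$params
  grid <- tibble::tibble(t = exp(seq(log(min(object$data$t)),
                                     log(max(object$data$t)),
                                     length.out = 200)))
  grid$y <- recovery_curve(grid$t, p)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$t / 1000, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$t / 1000),
                       colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "recovery gap (s)", y = "fractional recovery")
}

#' @rdname cav-autoplot
#' @method autoplot cav_dose_fit
#' @export
autoplot.cav_dose_fit <- function(object, ...) {
  ic50 <- object$params$ic50_nM
  rng <- range(object$data$conc_nM)
  grid <- tibble::tibble(c = exp(seq(log(rng[1] / 10), log(rng[2] * 10),
                                     length.out = 200)))
  grid$y <- hill_inhibition(grid$c, ic50)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$conc_nM, .data$inhibition_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$c, .data$y),
                       colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (nM)", y = "inhibition (%)")
}
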