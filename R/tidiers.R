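#' Tidy a curve fit
#'
#' Broom-style one-row-per-parameter summary of any `cav_fit` (I-V,
#' conductance, SSI, decay, recovery, tail, dose-response).
#'
#' @param x A `cav_fit`.
#' @param conf.level Confidence level for normal-approximation intervals.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @method tidy cav_fit
#' @export
tidy.cav_fit <- function(x, conf.level = 0.95, ...) {
  p <- unlist(x$params)
  p <- p[!is.na(p)]
  se <- rep(NA_real_, length(p))
  if (!is.null(x$se)) {
    hit <- intersect(names(p), names(x$se))
    se[match(hit, names(p))] <- x$se[hit]
  }
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(term = names(p), estimate = unname(p), std.error = se,
                 conf.low = unname(p) - z * se,
                 conf.high = unname(p) + z * se)
}

#' Glance at a curve fit
#'
#' @param x A `cav_fit`.
#' @param ... Unused.
#' @return One-row tibble with `rss`, `sigma`, `nobs`, `n.parameters`,
#'   `flags`.
#' @method glance cav_fit
#' @export
glance.cav_fit <- function(x, ...) {
  npar <- sum(!is.na(unlist(x$params)))
  tibble::tibble(rss = x$rss,
                 sigma = sqrt(x$rss / max(x$n - npar, 1)),
                 nobs = x$n, n.parameters = npar,
                 flags = paste(x$flags, collapse = ";"))
}

#' @method tidy cav_rundown
#' @export
tidy.cav_rundown <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = s[, "Std. Error"])
}

#' @method tidy cav_f_test
#' @export
tidy.cav_f_test <- function(x, ...) {
  tibble::tibble(statistic = x$f, df_num = x$df_num, df_den = x$df_den,
                 p.value = x$p)
}

#' @method tidy cav_group_comparison
#' @export
tidy.cav_group_comparison <- function(x, ...) x$pairwise

#' @method glance cav_group_comparison
#' @export
glance.cav_group_comparison <- function(x, ...) x$omnibus
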