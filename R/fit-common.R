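# Shared nonlinear least-squares plumbing for all curve fits.
# Levenberg-Marquardt with box bounds via minpack.lm; tight tolerances so
# noise-free closed-form fixtures are recovered to machine precision.

nls_lm <- function(formula, data, start, lower = NULL, upper = NULL) {
  if (is.null(lower)) lower <- rep(-Inf, length(start))
  if (is.null(upper)) upper <- rep(Inf, length(start))
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      formula, data = data, start = start,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = 1000, ftol = 1e-15, ptol = 1e-15, gtol = 0))),
    error = function(e) NULL)
  if (!is.null(fit)) return(fit)
  # nlsLM's final nls-object construction rejects rank-deficient gradients
  # (e.g. an exact zero-residual fit); fall back to the raw LM optimizer
  nls_lm_raw(formula, data, start, lower, upper)
}

nls_lm_raw <- function(formula, data, start, lower, upper) {
  lhs <- eval(formula[[2]], data)
  rhs <- formula[[3]]
  fn <- function(par) lhs - eval(rhs, c(as.list(data), par))
  out <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper, fn = fn,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15))),
    error = function(e) {
      stop("nonlinear fit failed to converge: ", conditionMessage(e),
           " [start: ", paste(names(start), signif(unlist(start), 4),
                              sep = "=", collapse = ", "), "]",
           call. = FALSE)
    })
  if (out$info == 0 || out$info == 5) {
    stop("nonlinear fit failed to converge: ", out$message,
         " [start: ", paste(names(start), signif(unlist(start), 4),
                            sep = "=", collapse = ", "), "]",
         call. = FALSE)
  }
  structure(list(par = out$par, fvec = out$fvec, lm = out),
            class = "cav_nlslm")
}

#' @export
coef.cav_nlslm <- function(object, ...) unlist(object$par)

#' @export
residuals.cav_nlslm <- function(object, ...) object$fvec

fit_se <- function(fit) {
  se <- tryCatch(
    suppressWarnings(
      if (inherits(fit, "cav_nlslm")) {
        summary(fit$lm)$coefficients[, "Std. Error"]
      } else {
        summary(fit)$coefficients[, "Std. Error"]
      }),
    error = function(e) rep(NA_real_, length(stats::coef(fit))))
  stats::setNames(as.numeric(se), names(stats::coef(fit)))
}

pinned_at <- function(coef, lower, upper, tol = 1e-6) {
  names(coef)[(is.finite(lower) & abs(coef - lower) < tol * pmax(1, abs(lower))) |
              (is.finite(upper) & abs(coef - upper) < tol * pmax(1, abs(upper)))]
}

new_cav_fit <- function(subclass, params, se = NULL, rss = NA_real_,
                        n = NA_integer_, fit = NULL, flags = character(),
                        data = NULL, extra = list()) {
  structure(c(list(params = params, se = se, rss = rss, n = n,
                   fit = fit, flags = flags, data = data), extra),
            class = c(subclass, "cav_fit"))
}

#' @export
print.cav_fit <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  p <- unlist(x$params)
  se <- if (!is.null(x$se)) x$se[names(p)] else rep(NA_real_, length(p))
  for (k in seq_along(p)) {
    if (is.na(p[k])) next
    cat(sprintf("  %-12s %10.4f", names(p)[k], p[k]))
    if (!is.na(se[k])) cat(sprintf("  (SE %.4f)", se[k]))
    cat("\n")
  }
  cat(sprintf("  RSS = %.4g on %d points", x$rss, x$n))
  if (length(x$flags)) cat("  [flags: ", paste(x$flags, collapse = ", "), "]",
                           sep = "")
  cat("\n")
  invisible(x)
}

# linear interpolation of the crossing of `y` through `level` on an
# increasing grid; used for initialization only
half_crossing <- function(x, y, level) {
  above <- y >= level
  k <- which(above[-1] != above[-length(above)])
  if (length(k) == 0) return(x[which.min(abs(y - level))])
  k <- k[1]
  x[k] + (level - y[k]) * (x[k + 1] - x[k]) / (y[k + 1] - y[k])
}
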