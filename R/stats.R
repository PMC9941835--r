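#' Extra sum-of-squares F test for nested models
#'
#' Compares a reduced (shared-parameter) fit against a full
#' (separate-parameter) fit:
#' `F = ((SS_reduced - SS_full) / (df_reduced - df_full)) / (SS_full / df_full)`
#' with the p-value from the F distribution.
#'
#' @param ss_reduced,df_reduced Residual sum of squares and residual
#'   degrees of freedom of the reduced model.
#' @param ss_full,df_full Same for the full model; `df_reduced` must exceed
#'   `df_full` and `ss_reduced` must be at least `ss_full`.
#' @return A `cav_f_test`: list with `f`, `df_num`, `df_den`, `p`.
#' @export
ess_f_test <- function(ss_reduced, df_reduced, ss_full, df_full) {
  if (df_reduced <= df_full) {
    stop("reduced model must have more residual degrees of freedom")
  }
  if (df_full <= 0) stop("full model has no residual degrees of freedom")
  if (ss_reduced < ss_full - 1e-12 * max(1, ss_full)) {
    stop("reduced-model SS must be >= full-model SS")
  }
  f <- ((ss_reduced - ss_full) / (df_reduced - df_full)) / (ss_full / df_full)
  f <- max(f, 0)
  structure(list(f = f, df_num = df_reduced - df_full, df_den = df_full,
                 p = stats::pf(f, df_reduced - df_full, df_full,
                               lower.tail = FALSE)),
            class = "cav_f_test")
}

#' @export
print.cav_f_test <- function(x, ...) {
  cat(sprintf("<cav_f_test> F(%d, %d) = %.4g, p = %.4g\n",
              x$df_num, x$df_den, x$f, x$p))
  invisible(x)
}

#' One-way ANOVA with Bonferroni post hoc comparisons
#'
#' Omnibus one-way ANOVA followed by pairwise pooled-SD t tests whose
#' p-values are Bonferroni-adjusted (multiplied by the number of pairs,
#' capped at 1).
#'
#' @param data Data frame with a value column and a group column.
#' @param value,group Column names (strings) of the measurement and the
#'   grouping factor. Each group needs n >= 2.
#' @return A `cav_group_comparison`: list with `omnibus` (tibble: `f`,
#'   `df_num`, `df_den`, `p`) and `pairwise` (tibble: `group1`, `group2`,
#'   `p_raw`, `p_adj`).
#' @export
anova_bonferroni <- function(data, value = "value", group = "group") {
  data <- tibble::as_tibble(data)
  stopifnot(all(c(value, group) %in% names(data)))
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("each group needs at least 2 observations")
  if (all(tapply(y, g, stats::var) < 1e-24)) {
    stop("zero within-group variance in every group")
  }
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  omnibus <- tibble::tibble(f = tab$`F value`[1], df_num = tab$Df[1],
                            df_den = tab$Df[2], p = tab$`Pr(>F)`[1])
  pt_raw <- stats::pairwise.t.test(y, g, p.adjust.method = "none",
                                   pool.sd = TRUE)$p.value
  pairs <- which(!is.na(pt_raw), arr.ind = TRUE)
  m <- nrow(pairs)
  pairwise <- tibble::tibble(
    group1 = rownames(pt_raw)[pairs[, 1]],
    group2 = colnames(pt_raw)[pairs[, 2]],
    p_raw = pt_raw[pairs],
    p_adj = pmin(pt_raw[pairs] * m, 1))
  structure(list(omnibus = omnibus, pairwise = pairwise,
                 method = "anova_bonferroni"),
            class = "cav_group_comparison")
}

#' @export
print.cav_group_comparison <- function(x, ...) {
  cat(sprintf("<cav_group_comparison> omnibus F(%d, %d) = %.4g, p = %.4g\n",
              x$omnibus$df_num, x$omnibus$df_den, x$omnibus$f, x$omnibus$p))
  print(x$pairwise)
  invisible(x)
}

#' Mean, SEM and n
#'
#' @param x Numeric vector (n >= 1).
#' @return One-row tibble with `mean`, `sem` (`sd / sqrt(n)`; 0 for n = 1
#'   with zero variance undefined -> `NA`), and `n`.
#' @export
summarize_sem <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 1) stop("summarize_sem needs at least one value")
  tibble::tibble(mean = mean(x),
                 sem = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
                 n = n)
}
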