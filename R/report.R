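#' Gating-parameter summary table
#'
#' Collects activation and inactivation fits into one row per channel
#' combination, mirroring the layout of a steady-state gating table
#' (activation V0.5, k, Vrev; inactivation V0.5, k, non-inactivating %).
#' When standard errors are available values are formatted
#' `estimate +/- SE`; missing uncertainties render as an em-dash in
#' [render_report()].
#'
#' @param activation Named list of `cav_iv_fit`s (names are row labels).
#' @param inactivation Named list of `cav_ssi_fit`s with matching names
#'   (optional).
#' @return A tibble with one row per label.
#' @export
gating_table <- function(activation, inactivation = NULL) {
  labs <- names(activation)
  stopifnot(length(labs) > 0)
  preferred <- c("WT+b3", "F747S+b3", "WT+b2a", "F747S+b2a")
  labs <- c(intersect(preferred, labs), setdiff(labs, preferred))
  purrr::map_dfr(labs, function(l) {
    a <- activation[[l]]
    i <- inactivation[[l]]
    tibble::tibble(
      label = l,
      v05_act = a$params$v05_act, v05_act_se = a$se[["v05_act"]],
      k_act = a$params$k_act, k_act_se = a$se[["k_act"]],
      v_rev = a$params$v_rev, v_rev_se = a$se[["v_rev"]],
      v05_inact = if (!is.null(i)) i$params$v05_inact else NA_real_,
      v05_inact_se = if (!is.null(i)) i$se[["v05_inact"]] else NA_real_,
      k_inact = if (!is.null(i)) i$params$k_inact else NA_real_,
      k_inact_se = if (!is.null(i)) i$se[["k_inact"]] else NA_real_,
      noninact_pct = if (!is.null(i)) 100 * i$params$frac_noninact else NA_real_,
      noninact_pct_se = if (!is.null(i)) 100 * i$se[["frac_noninact"]] else NA_real_)
  })
}

#' @rdname gating_table
#' @param decay Named list of `cav_decay_fit`s.
#' @return `decay_table()`: a tibble mirroring an exponential
#'   inactivation-parameter table (`a_slow`, `tau_slow`, `a_fast`,
#'   `tau_fast`, `plateau`; mono fits leave the fast columns empty).
#' @export
decay_table <- function(decay) {
  purrr::imap_dfr(decay, function(d, l) {
    tibble::tibble(label = l, model = d$model,
                   a_slow = d$params$a_slow, tau_slow = d$params$tau_slow,
                   a_fast = d$params$a_fast, tau_fast = d$params$tau_fast,
                   plateau = d$params$plateau)
  })
}

#' Render a result table as Markdown
#'
#' Formats a tibble (typically from [gating_table()] or [decay_table()])
#' as a GitHub-style Markdown table. Columns named `<x>` with a matching
#' `<x>_se` column are merged into `estimate +/- SE` cells; missing values
#' render as an em-dash.
#'
#' @param table A data frame.
#' @param digits Significant digits for formatting.
#' @return Character vector of Markdown lines.
#' @export
render_report <- function(table, digits = 4) {
  table <- tibble::as_tibble(table)
  se_cols <- grep("_se$", names(table), value = TRUE)
  base <- sub("_se$", "", se_cols)
  fmt1 <- function(x) {
    ifelse(is.na(x), "—", vapply(x, function(v) {
      if (is.numeric(v)) format(signif(v, digits)) else as.character(v)
    }, ""))
  }
  out <- table[, setdiff(names(table), se_cols)]
  cells <- purrr::imap_dfc(out, function(col, nm) {
    if (nm %in% base) {
      se <- table[[paste0(nm, "_se")]]
      ifelse(is.na(col), "—",
             ifelse(is.na(se), fmt1(col),
                    paste0(fmt1(col), " ± ", fmt1(se))))
    } else fmt1(col)
  })
  header <- paste0("| ", paste(names(cells), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(cells)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, rule, rows)
}
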