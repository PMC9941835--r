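#' Shipped Cav1.3 parameter presets
#'
#' Four channel/beta-subunit combinations are shipped, parameterized from
#' published whole-cell gating tables for wild-type (WT) and F747S mutant
#' Cav1.3 channels co-expressed with cytosolic beta3 or membrane-anchored
#' beta2a subunits: `"WT+b3"`, `"F747S+b3"`, `"WT+b2a"`, `"F747S+b2a"`.
#'
#' The simulator-side amplitude weights of the two inactivation gates are
#' derived as follows. `frac_noninact` is the steady-state availability
#' plateau (the quantity the two-pulse steady-state-inactivation protocol
#' measures). For WT presets, `1 - frac_noninact` is split between the fast
#' and slow gates in the proportion of the published 5-s decay amplitudes.
#' F747S inactivates mono-exponentially but recovers bi-exponentially, so
#' its two gates share a single depolarized time constant (making the 5-s
#' decay exactly mono-exponential) while keeping distinct recovery time
#' constants, with weights in the proportion of the published recovery
#' amplitudes. Recovery time constants were measured with beta3
#' co-expression; the beta2a presets reuse the matching variant's values.
#'
#' @param label Preset label (case-insensitive; `"_"` may be used for `"+"`).
#' @return `preset_gating()`: a [gating_params()] object.
#' @export
preset_gating <- function(label) {
  switch(match_preset(label),
    "WT+b3" = {
      ni <- 0.2048
      w <- split_weights(1 - ni, fast = 63.74, slow = 25.13)
      gating_params("WT+b3",
        v05_act = -0.12, k_act = 9.14, v_rev = 62.82, gmax_density = 0.4,
        v05_inact = -26.02, k_inact = 6.07, frac_noninact = ni,
        a_fast = w[1], a_slow = w[2],
        tau_inact_fast = 227.20, tau_inact_slow = 1987.59,
        tau_rec_fast = 67.6, tau_rec_slow = 5625,
        tau_deact_ref = 0.8)
    },
    "F747S+b3" = {
      ni <- 0.3124
      w <- split_weights(1 - ni, fast = 0.36, slow = 0.44)
      gating_params("F747S+b3",
        v05_act = -28.5, k_act = 5.97, v_rev = 41.64, gmax_density = 0.4,
        v05_inact = -42.88, k_inact = 4.93, frac_noninact = ni,
        a_fast = w[1], a_slow = w[2],
        tau_inact_fast = 1424.08, tau_inact_slow = 1424.08,
        tau_rec_fast = 165.94, tau_rec_slow = 6778.23,
        tau_deact_ref = 3.5,
        hook = list(enabled = FALSE, tau_unblock = 0.3, blocked_frac = 0.4))
    },
    "WT+b2a" = {
      ni <- 0.3030
      w <- split_weights(1 - ni, fast = 28.97, slow = 41.27)
      gating_params("WT+b2a",
        v05_act = 1.98, k_act = 10.08, v_rev = 66.41, gmax_density = 0.4,
        v05_inact = -16.22, k_inact = 10.12, frac_noninact = ni,
        a_fast = w[1], a_slow = w[2],
        tau_inact_fast = 283.48, tau_inact_slow = 2070.87,
        tau_rec_fast = 67.6, tau_rec_slow = 5625,
        tau_deact_ref = 0.8)
    },
    "F747S+b2a" = {
      ni <- 0.4248
      w <- split_weights(1 - ni, fast = 0.36, slow = 0.44)
      gating_params("F747S+b2a",
        v05_act = -24.68, k_act = 5.94, v_rev = 44.79, gmax_density = 0.4,
        v05_inact = -38.94, k_inact = 4.04, frac_noninact = ni,
        a_fast = w[1], a_slow = w[2],
        tau_inact_fast = 2176.09, tau_inact_slow = 2176.09,
        tau_rec_fast = 165.94, tau_rec_slow = 6778.23,
        tau_deact_ref = 3.5,
        hook = list(enabled = FALSE, tau_unblock = 0.3, blocked_frac = 0.4))
    }
  )
}

#' @rdname preset_gating
#' @details `preset_cell()` returns a typical tsA-201 recording condition:
#'   20 pF capacitance, 0.5 nS ohmic leak, 5 pA current noise and the
#'   published per-combination linear run-down slope (percent of initial
#'   peak per minute).
#' @param seed Integer noise seed for `preset_cell()`.
#' @return `preset_cell()`: a [cell_model()] object.
#' @export
preset_cell <- function(label, seed = 1L) {
  slope <- switch(match_preset(label),
                  "WT+b3" = -1.5383, "F747S+b3" = -0.4941,
                  "WT+b2a" = -0.4046, "F747S+b2a" = -0.1006)
  cell_model(capacitance_pF = 20, leak_nS = 0.5, noise_sd_pA = 5,
             rundown_pct_per_min = slope, seed = seed)
}

#' @rdname preset_gating
#' @details `preset_decay()` returns the published 5-s decay description
#'   verbatim (amplitudes in percent of the peak current, time constants in
#'   ms, non-inactivating plateau in percent): a bi-exponential for WT and a
#'   mono-exponential for F747S. These are the closed-form fixtures used for
#'   exact kinetics recovery.
#' @return `preset_decay()`: a list with `model` (`"bi"` or `"mono"`),
#'   `a_fast`, `tau_fast`, `a_slow`, `tau_slow`, `plateau`.
#' @export
preset_decay <- function(label) {
  switch(match_preset(label),
    "WT+b3" = list(model = "bi", a_fast = 63.74, tau_fast = 227.20,
                   a_slow = 25.13, tau_slow = 1987.59, plateau = 7.12),
    "F747S+b3" = list(model = "mono", a_fast = NA_real_, tau_fast = NA_real_,
                      a_slow = 67.48, tau_slow = 1424.08, plateau = 28.27),
    "WT+b2a" = list(model = "bi", a_fast = 28.97, tau_fast = 283.48,
                    a_slow = 41.27, tau_slow = 2070.87, plateau = 24.74),
    "F747S+b2a" = list(model = "mono", a_fast = NA_real_, tau_fast = NA_real_,
                       a_slow = 65.75, tau_slow = 2176.09, plateau = 31.61)
  )
}

#' @rdname preset_gating
#' @details `preset_recovery()` returns the published double-exponential
#'   recovery-from-inactivation description (fractional amplitudes, time
#'   constants in ms) measured with beta3 co-expression, plus the package's
#'   default instantaneous offset (0.1) for closed-form fixtures.
#' @return `preset_recovery()`: a list with `a_fast`, `tau_fast`, `a_slow`,
#'   `tau_slow`, `offset`.
#' @export
preset_recovery <- function(label) {
  switch(match_preset(label),
    "WT+b3" = , "WT+b2a" =
      list(a_fast = 0.72, tau_fast = 67.6, a_slow = 0.10, tau_slow = 5625,
           offset = 0.1),
    "F747S+b3" = , "F747S+b2a" =
      list(a_fast = 0.36, tau_fast = 165.94, a_slow = 0.44,
           tau_slow = 6778.23, offset = 0.1)
  )
}

#' @rdname preset_gating
#' @return `cav_presets()`: a tibble with one row per shipped preset and its
#'   headline gating parameters.
#' @export
cav_presets <- function() {
  labs <- c("WT+b3", "F747S+b3", "WT+b2a", "F747S+b2a")
  purrr::map_dfr(labs, function(l) {
    p <- preset_gating(l)
    tibble::tibble(label = l, v05_act = p$v05_act, k_act = p$k_act,
                   v_rev = p$v_rev, v05_inact = p$v05_inact,
                   k_inact = p$k_inact,
                   noninact_pct = 100 * p$frac_noninact,
                   rundown_pct_per_min = preset_cell(l)$rundown_pct_per_min)
  })
}

match_preset <- function(label) {
  lab <- gsub("_", "+", tolower(label), fixed = TRUE)
  labs <- c("WT+b3", "F747S+b3", "WT+b2a", "F747S+b2a")
  hit <- match(lab, tolower(labs))
  if (is.na(hit)) {
    stop("unknown preset '", label, "'; available: ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  labs[hit]
}

split_weights <- function(total, fast, slow) {
  c(total * fast / (fast + slow), total * slow / (fast + slow))
}
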