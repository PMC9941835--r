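#' Simulate one whole-cell current sweep
#'
#' Integrates the gating model along a square-segment voltage command.
#' Because command voltages are piecewise constant, every gate relaxes
#' exponentially toward its steady state within a segment, so trajectories
#' are evaluated in closed form at each sample (no numerical integrator).
#'
#' The membrane current is
#' `I(t) = Gmax_density * C * (V - Vrev) * p_open(t) * h(t) * scale
#'        + g_leak * V + noise`,
#' with `p_open = m` (or `m - b` when the hook pool is enabled) and
#' `h = frac_noninact + a_fast * h_fast + a_slow * h_slow`.
#'
#' @param protocol A `cav_protocol`.
#' @param params A [gating_params()] object.
#' @param cell A [cell_model()] object; `cell$noise_sd_pA = 0` gives a
#'   deterministic, bit-reproducible trace.
#' @param scale Multiplier on the channel conductance (used for run-down
#'   and drug block), default 1.
#' @param state0 Optional named list `list(m, h_fast, h_slow, b)` of initial
#'   gate values; by default all gates start at equilibrium for the first
#'   segment's voltage.
#' @param seed_offset Integer added to `cell$seed` for the noise stream of
#'   this sweep.
#' @param start_s Wall-clock sweep start, s (stored in metadata).
#' @param conc_nM Drug concentration tag for this sweep (stored in
#'   metadata), or `NULL`.
#' @return A `cav_sweep`: a tibble with columns `t_ms`, `v_mV`, `i_pA` and
#'   attributes `sampling_rate_hz`, `capacitance_pF` and `meta` (label,
#'   start_s, conc_nM, jp_corrected).
#' @export
simulate_sweep <- function(protocol, params, cell, scale = 1,
                           state0 = NULL, seed_offset = 0L,
                           start_s = 0, conc_nM = NULL) {
  stopifnot(inherits(protocol, "cav_protocol"),
            inherits(params, "cav_gating_params"),
            inherits(cell, "cav_cell_model"))
  if (any(!is.finite(protocol$v_mV))) stop("non-finite segment voltage")
  rate <- attr(protocol, "sampling_rate_hz")
  dt <- 1000 / rate
  nseg <- round(protocol$duration_ms / dt)
  if (any(nseg < 1)) stop("zero-length protocol segment")
  hook_on <- isTRUE(params$hook$enabled)

  v0 <- protocol$v_mV[1]
  if (is.null(state0)) {
    state0 <- list(m = steady_state_activation(v0, params),
                   h_fast = h_inf_gate(v0, params),
                   h_slow = h_inf_gate(v0, params),
                   b = if (hook_on) b_inf(v0, params) else 0)
  }
  m0 <- state0$m; hf0 <- state0$h_fast; hs0 <- state0$h_slow; b0 <- state0$b

  out_i <- vector("list", nrow(protocol))
  out_v <- vector("list", nrow(protocol))
  for (s in seq_len(nrow(protocol))) {
    v <- protocol$v_mV[s]
    tt <- seq_len(nseg[s]) * dt    # times within segment
    m_inf <- steady_state_activation(v, params)
    hi <- h_inf_gate(v, params)
    tm <- tau_m(v, params)
    tf <- tau_h(v, params$tau_rec_fast, params$tau_inact_fast)
    ts <- tau_h(v, params$tau_rec_slow, params$tau_inact_slow)
    m_t <- m_inf + (m0 - m_inf) * exp(-tt / tm)
    hf_t <- hi + (hf0 - hi) * exp(-tt / tf)
    hs_t <- hi + (hs0 - hi) * exp(-tt / ts)
    if (hook_on) {
      bi <- b_inf(v, params)
      b_t <- bi + (b0 - bi) * exp(-tt / params$hook$tau_unblock)
      open_t <- pmin(pmax(m_t - b_t, 0), 1)
      b0 <- b_t[nseg[s]]
    } else {
      open_t <- m_t
    }
    h_t <- params$frac_noninact + params$a_fast * hf_t + params$a_slow * hs_t
    out_i[[s]] <- params$gmax_density * cell$capacitance_pF *
      (v - params$v_rev) * open_t * h_t * scale + cell$leak_nS * v
    out_v[[s]] <- rep(v, nseg[s])
    m0 <- m_t[nseg[s]]; hf0 <- hf_t[nseg[s]]; hs0 <- hs_t[nseg[s]]
  }
  i <- unlist(out_i, use.names = FALSE)
  if (cell$noise_sd_pA > 0) {
    i <- i + withr::with_seed(
      cell$seed + as.integer(seed_offset),
      stats::rnorm(length(i), sd = cell$noise_sd_pA))
  }
  new_sweep(tibble::tibble(t_ms = seq_along(i) * dt,
                           v_mV = unlist(out_v, use.names = FALSE),
                           i_pA = i),
            sampling_rate_hz = rate,
            capacitance_pF = cell$capacitance_pF,
            meta = list(label = attr(protocol, "label"),
                        start_s = start_s,
                        conc_nM = conc_nM,
                        jp_corrected = attr(protocol, "jp_corrected")))
}

new_sweep <- function(df, sampling_rate_hz, capacitance_pF, meta = list()) {
  structure(df,
            sampling_rate_hz = sampling_rate_hz,
            capacitance_pF = capacitance_pF,
            meta = meta,
            class = c("cav_sweep", class(tibble::tibble())))
}

new_bundle <- function(sweeps, family_kind, meta = list()) {
  structure(list(sweeps = sweeps, family_kind = family_kind, meta = meta),
            class = "cav_bundle")
}

#' @export
print.cav_bundle <- function(x, ...) {
  cat("<cav_bundle> ", x$family_kind, ": ", length(x$sweeps), " sweeps, ",
      nrow(x$sweeps[[1]]), " samples each\n", sep = "")
  invisible(x)
}

#' Simulate every sweep of a protocol family
#'
#' @inheritParams simulate_sweep
#' @param family A `cav_protocol_family`.
#' @return A `cav_bundle`: list of `cav_sweep` objects plus `family_kind`
#'   and family metadata (including the varied quantity).
#' @export
simulate_family <- function(family, params, cell, scale = 1) {
  stopifnot(inherits(family, "cav_protocol_family"))
  interval <- attr(family$protocols[[1]], "inter_sweep_s")
  sweeps <- purrr::imap(family$protocols, function(p, k) {
    simulate_sweep(p, params, cell, scale = scale, seed_offset = k,
                   start_s = (k - 1) * interval)
  })
  new_bundle(sweeps, family$family_kind,
             meta = list(varied = family$varied,
                         varied_name = family$varied_name,
                         label = params$label))
}

#' Combine a bundle into one long tibble
#'
#' @param x A `cav_bundle`.
#' @param ... Unused.
#' @return A tibble with columns `sweep`, `t_ms`, `v_mV`, `i_pA` (and
#'   `conc_nM` if present).
#' @method as_tibble cav_bundle
#' @export
as_tibble.cav_bundle <- function(x, ...) {
  purrr::imap_dfr(x$sweeps, function(s, k) {
    conc <- attr(s, "meta")$conc_nM
    out <- tibble::tibble(sweep = k, t_ms = s$t_ms, v_mV = s$v_mV,
                          i_pA = s$i_pA)
    if (!is.null(conc)) out$conc_nM <- conc
    out
  })
}

#' Voltage of maximal inward current
#'
#' The test potential eliciting the largest steady inward current for a
#' parameter set: the argmin of `(V - Vrev) * m_inf(V)` on a 0.1-mV grid
#' (availability from the holding potential is ~1 and cancels).
#'
#' @param params A [gating_params()] object.
#' @param v_range Search range, mV.
#' @return Vmax, mV (rounded to the nearest mV, matching how a test
#'   potential would be chosen from an I-V family).
#' @export
v_max <- function(params, v_range = c(-80, 30)) {
  v <- seq(v_range[1], v_range[2], by = 0.1)
  drive <- (v - params$v_rev) * steady_state_activation(v, params)
  round(v[which.min(drive)])
}

#' Simulate a drug-application train
#'
#' Repeats the pharmacology pulse protocol at its stimulation frequency
#' while stepping the bath concentration according to `schedule`.
#' Fractional block approaches the Hill equilibrium `c / (c + IC50)` (slope
#' 1) with first-order equilibration between sweeps; the channel current is
#' additionally scaled by the cell's linear run-down, multiplicatively per
#' sweep.
#'
#' @param params,cell See [simulate_sweep()].
#' @param drug A [drug_model()], or `NULL` for a drug-free control run.
#' @param schedule Data frame with columns `conc_nM` and `n_sweeps`, applied
#'   in order; concentrations must be >= 0.
#' @param protocol The pulse protocol, default
#'   `build_pharm_protocol(v_max(params))`.
#' @return A `cav_bundle` of `PHARM` sweeps; each sweep's metadata carries
#'   its concentration and wall-clock start.
#' @export
simulate_pharmacology_run <- function(params, cell, drug = NULL,
                                      schedule = tibble::tibble(
                                        conc_nM = 0, n_sweeps = 10),
                                      protocol = NULL) {
  schedule <- tibble::as_tibble(schedule)
  stopifnot(all(c("conc_nM", "n_sweeps") %in% names(schedule)))
  if (any(schedule$conc_nM < 0)) stop("negative drug concentration")
  if (any(schedule$conc_nM > 0) && is.null(drug)) {
    stop("schedule applies drug but no drug_model was given")
  }
  if (is.null(protocol)) protocol <- build_pharm_protocol(v_max(params))
  interval <- attr(protocol, "inter_sweep_s")
  conc <- rep(schedule$conc_nM, times = schedule$n_sweeps)
  block <- 0
  sweeps <- vector("list", length(conc))
  for (k in seq_along(conc)) {
    t_start <- (k - 1) * interval
    if (!is.null(drug)) {
      b_eq <- conc[k] / (conc[k] + drug$ic50_nM)
      block <- b_eq + (block - b_eq) * exp(-interval / drug$equilibration_tau_s)
    }
    rundown <- 1 + cell$rundown_pct_per_min / 100 * (t_start / 60)
    sweeps[[k]] <- simulate_sweep(protocol, params, cell,
                                  scale = (1 - block) * max(rundown, 0),
                                  seed_offset = k, start_s = t_start,
                                  conc_nM = conc[k])
  }
  new_bundle(sweeps, "PHARM",
             meta = list(label = params$label, schedule = schedule,
                         interval_s = interval))
}
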