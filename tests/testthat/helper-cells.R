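# Shared fixtures: noise-free recording conditions used by the
# deterministic round-trip tests.

quiet_cell <- function(leak_nS = 0.5, ...) {
  cell_model(noise_sd_pA = 0, leak_nS = leak_nS, ...)
}

all_presets <- c("WT+b3", "F747S+b3", "WT+b2a", "F747S+b2a")

# closed-form availability of one inactivation gate after holding `dur_ms`
# at voltage v, starting from h0 (independent oracle used against the
# simulator)
gate_after <- function(h0, v, dur_ms, params, tau_rec, tau_inact) {
  hi <- 1 / (1 + exp((v - params$v05_inact) / params$k_inact))
  w <- stats::plogis((v + 50) / 5)
  tau <- tau_rec + (tau_inact - tau_rec) * w
  hi + (h0 - hi) * exp(-dur_ms / tau)
}
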