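ssi_closed_form <- function(v, v05, k, ini) {
  ini + (1 - ini) / (1 + exp((v - v05) / k))
}

test_that("fit_ssi is exact on its closed form (published F747S+b3 row)", {
  v <- seq(-89, 21, by = 10)
  r <- ssi_closed_form(v, v05 = -42.88, k = 4.93, ini = 0.3124)
  fit <- fit_ssi(data.frame(v_mV = v, ratio = r))
  expect_equal(fit$params$v05_inact, -42.88, tolerance = 1e-6)
  expect_equal(fit$params$k_inact, 4.93, tolerance = 1e-6)
  expect_equal(fit$params$frac_noninact, 0.3124, tolerance = 1e-6)
})

test_that("fit_ssi flags degenerate and out-of-range input", {
  v <- seq(-89, 21, by = 10)
  expect_error(fit_ssi(data.frame(v_mV = v, ratio = rep(1, length(v)))),
               "indeterminate")
  r <- ssi_closed_form(v, -42.88, 4.93, 0.3124)
  r[1] <- 1.2
  expect_error(fit_ssi(data.frame(v_mV = v, ratio = r)), "1.05")
})

test_that("window current multiplies density by availability", {
  iv <- data.frame(v_mV = seq(-60, 0, 10),
                   density_pA_pF = c(-1, -4, -9, -14, -16, -15, -13))
  p <- preset_gating("WT+b3")
  # availability = 1 -> window equals the I-V densities
  p1 <- p; p1$frac_noninact <- 1; p1$a_fast <- 0; p1$a_slow <- 0
  w1 <- window_current(iv, p1)
  expect_equal(w1$window_pA_pF, iv$density_pA_pF)
  # plateau at depolarized voltages -> density * I_ni
  wp <- window_current(data.frame(v_mV = 40, density_pA_pF = -5), p)
  expect_equal(wp$window_pA_pF, -5 * steady_state_availability(40, p),
               tolerance = 1e-12)
  expect_true(all(abs(w1$window_pA_pF) <= abs(iv$density_pA_pF) + 1e-12))
})

test_that("mutant window current exceeds WT over the subthreshold range", {
  cell <- quiet_cell()
  wins <- lapply(c("WT+b3", "F747S+b3"), function(lab) {
    p <- preset_gating(lab)
    fit <- analyze_iv(p, cell)
    ssi <- analyze_ssi(p, cell)
    window_current(fit$peaks, ssi)
  })
  sel <- wins[[1]]$v_mV >= -50 & wins[[1]]$v_mV <= -20
  expect_true(all(abs(wins[[2]]$window_pA_pF[sel]) >
                    abs(wins[[1]]$window_pA_pF[sel])))
  # the mutant predicts measurable steady influx already at -40 mV
  at40 <- function(w) abs(w$window_pA_pF[w$v_mV == -39])
  expect_gt(at40(wins[[2]]), at40(wins[[1]]))
})

test_that("remaining fractions follow the decay closed form", {
  # non-decaying trace -> all 100
  flat <- data.frame(t_ms = seq(0, 5000, by = 1), pct = 100)
  expect_equal(remaining_fractions(flat)$r_pct, rep(100, 6))
  # pure mono-exponential, tau 1000 ms, no plateau: r1000 = 100/e = 36.8
  mono <- data.frame(t_ms = seq(0, 5000, by = 1),
                     pct = 100 * exp(-seq(0, 5000, by = 1) / 1000))
  r <- remaining_fractions(mono)
  expect_equal(r$r_pct[r$t_ms == 1000], 100 * exp(-1), tolerance = 1e-3)
  expect_error(remaining_fractions(mono, times = 8000), "beyond")
  # simulated decays are non-increasing in time
  for (lab in c("WT+b3", "F747S+b3")) {
    res <- analyze_decay(preset_gating(lab), quiet_cell(leak_nS = 0))
    expect_true(all(diff(res$r_values$r_pct) <= 1e-9))
  }
})

test_that("fit_decay recovers published closed-form kinetics exactly", {
  t <- seq(0, 5000, by = 2)
  # WT+b3 bi-exponential row
  d <- preset_decay("WT+b3")
  y <- d$plateau + d$a_fast * exp(-t / d$tau_fast) +
    d$a_slow * exp(-t / d$tau_slow)
  fit <- fit_decay(data.frame(t_ms = t, pct = y), model = "auto")
  expect_equal(fit$model, "bi")
  expect_equal(fit$params$a_fast, 63.74, tolerance = 1e-6)
  expect_equal(fit$params$tau_fast, 227.20, tolerance = 1e-6)
  expect_equal(fit$params$a_slow, 25.13, tolerance = 1e-6)
  expect_equal(fit$params$tau_slow, 1987.59, tolerance = 1e-6)
  expect_equal(fit$params$plateau, 7.12, tolerance = 1e-6)
  # F747S+b3 mono-exponential row; auto must select mono
  dm <- preset_decay("F747S+b3")
  ym <- dm$plateau + dm$a_slow * exp(-t / dm$tau_slow)
  fitm <- fit_decay(data.frame(t_ms = t, pct = ym), model = "auto")
  expect_equal(fitm$model, "mono")
  expect_equal(fitm$params$a_slow, 67.48, tolerance = 1e-6)
  expect_equal(fitm$params$tau_slow, 1424.08, tolerance = 1e-6)
  expect_equal(fitm$params$plateau, 28.27, tolerance = 1e-6)
  # forced bi on bi data keeps tau ordering
  fitb <- fit_decay(data.frame(t_ms = t, pct = y), model = "bi")
  expect_lt(fitb$params$tau_fast, fitb$params$tau_slow)
})

test_that("decay round-trips recover simulator amplitudes within 2 points", {
  cell <- quiet_cell(leak_nS = 0)
  for (lab in all_presets) {
    p <- preset_gating(lab)
    fit <- analyze_decay(p, cell)$decay_fit
    if (fit$model == "bi") {
      expect_lt(abs(fit$params$a_fast - 100 * p$a_fast), 2)
      expect_lt(abs(fit$params$a_slow - 100 * p$a_slow), 2)
    } else {
      expect_lt(abs(fit$params$a_slow - 100 * (p$a_fast + p$a_slow)), 2)
    }
    # the fitted plateau is the availability floor at Vmax, not
    # frac_noninact alone: the per-gate Boltzmann floor h_inf(Vmax)
    # contributes for shallow-k combinations
    hi <- 1 / (1 + exp((v_max(p) - p$v05_inact) / p$k_inact))
    floor_pct <- 100 * (p$frac_noninact + (p$a_fast + p$a_slow) * hi)
    expect_lt(abs(fit$params$plateau - floor_pct), 2)
  }
})
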