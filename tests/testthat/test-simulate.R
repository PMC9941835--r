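test_that("zero conductance and zero driving force behave trivially", {
  p <- preset_gating("WT+b3")
  p0 <- p; p0$gmax_density <- 1e-300   # effectively zero channel conductance
  cell <- quiet_cell(leak_nS = 2)
  prot <- protocol(data.frame(duration_ms = c(10, 25, 10),
                              v_mV = c(-89, -10, -89)))
  sw <- simulate_sweep(prot, p0, cell)
  expect_equal(sw$i_pA, cell$leak_nS * sw$v_mV, tolerance = 1e-12)
  # constant V = Vrev with no leak or noise: identically 0 pA
  protv <- protocol(data.frame(duration_ms = 20, v_mV = p$v_rev))
  sw2 <- simulate_sweep(protv, p, quiet_cell(leak_nS = 0))
  expect_equal(sw2$i_pA, rep(0, nrow(sw2)))
})

test_that("simulation is bit-reproducible for a fixed seed", {
  p <- preset_gating("WT+b3")
  cell <- cell_model(noise_sd_pA = 5, leak_nS = 0.5, seed = 42L)
  prot <- build_pharm_protocol(v_test = -10)
  a <- simulate_sweep(prot, p, cell, seed_offset = 3L)
  b <- simulate_sweep(prot, p, cell, seed_offset = 3L)
  expect_identical(a$i_pA, b$i_pA)
  c <- simulate_sweep(prot, p, cell, seed_offset = 4L)
  expect_false(identical(a$i_pA, c$i_pA))
})

test_that("gates stay within [0, 1]: channel current never exceeds the
           conductance-driving bound", {
  p <- preset_gating("F747S+b3")
  p$hook$enabled <- TRUE
  cell <- quiet_cell(leak_nS = 0)
  withr::with_seed(7, {
    for (rep in 1:10) {
      volts <- runif(5, -110, 50)
      prot <- protocol(data.frame(duration_ms = rep(5, 5), v_mV = volts),
                       sampling_rate_hz = 20000)
      sw <- simulate_sweep(prot, p, cell)
      bound <- p$gmax_density * cell$capacitance_pF * abs(sw$v_mV - p$v_rev)
      expect_true(all(abs(sw$i_pA) <= bound + 1e-9))
    }
  })
})

test_that("late-pulse current matches the analytic quasi-steady oracle", {
  # 25-ms step to -20 mV with fast activation: the end-of-pulse current
  # equals Gmax*C*(V - Vrev)*m_inf(V)*h(25 ms) computed in closed form
  p <- preset_gating("WT+b3")
  cell <- quiet_cell(leak_nS = 0)
  prot <- protocol(data.frame(duration_ms = c(50, 25), v_mV = c(-89, -20)))
  sw <- simulate_sweep(prot, p, cell)
  h0 <- 1 / (1 + exp((-89 - p$v05_inact) / p$k_inact))
  hf <- gate_after(h0, -20, 25, p, p$tau_rec_fast, p$tau_inact_fast)
  hs <- gate_after(h0, -20, 25, p, p$tau_rec_slow, p$tau_inact_slow)
  h25 <- p$frac_noninact + p$a_fast * hf + p$a_slow * hs
  m_inf <- 1 / (1 + exp(-(-20 - p$v05_act) / p$k_act))
  tau <- cavclamp:::tau_m(-20, p)
  m25 <- m_inf + (1 / (1 + exp(-(-89 - p$v05_act) / p$k_act)) - m_inf) *
    exp(-25 / tau)
  pred <- p$gmax_density * cell$capacitance_pF * (-20 - p$v_rev) * m25 * h25
  expect_equal(sw$i_pA[nrow(sw)], pred, tolerance = 1e-9)
})

test_that("closed-form integration agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- preset_gating("WT+b3")
  cell <- quiet_cell(leak_nS = 0)
  v_step <- -20
  prot <- protocol(data.frame(duration_ms = c(10, 25), v_mV = c(-89, v_step)),
                   sampling_rate_hz = 10000)
  sw <- simulate_sweep(prot, p, cell)
  # integrate the step segment with lsoda from the holding equilibrium
  rhs <- function(t, y, parms) {
    v <- v_step
    m_inf <- 1 / (1 + exp(-(v - p$v05_act) / p$k_act))
    hi <- 1 / (1 + exp((v - p$v05_inact) / p$k_inact))
    w <- stats::plogis((v + 50) / 5)
    list(c((m_inf - y[1]) / cavclamp:::tau_m(v, p),
           (hi - y[2]) / (p$tau_rec_fast + (p$tau_inact_fast - p$tau_rec_fast) * w),
           (hi - y[3]) / (p$tau_rec_slow + (p$tau_inact_slow - p$tau_rec_slow) * w)))
  }
  h0 <- 1 / (1 + exp((-89 - p$v05_inact) / p$k_inact))
  m0 <- 1 / (1 + exp(-(-89 - p$v05_act) / p$k_act))
  times <- seq(0, 25, by = 0.1)
  out <- deSolve::lsoda(c(m0, h0, h0), times, rhs, NULL,
                        rtol = 1e-11, atol = 1e-12)
  h <- p$frac_noninact + p$a_fast * out[, 3] + p$a_slow * out[, 4]
  i_ode <- p$gmax_density * cell$capacitance_pF * (v_step - p$v_rev) *
    out[, 2] * h
  i_sim <- sw$i_pA[sw$v_mV == v_step]
  expect_equal(i_sim, i_ode[-1], tolerance = 1e-7)
})

test_that("pharmacology runs follow Hill-type block with equilibration", {
  p <- preset_gating("WT+b3")
  cell <- quiet_cell(leak_nS = 0, rundown_pct_per_min = 0)
  # no drug, no run-down: constant peaks
  ctrl <- simulate_pharmacology_run(p, cell,
                                    schedule = data.frame(conc_nM = 0,
                                                          n_sweeps = 5))
  pk <- pharm_peaks(ctrl)
  expect_equal(diff(range(pk$peak_pA)), 0, tolerance = 1e-9)
  # c = IC50 at equilibrium: 50% peak reduction
  drug <- drug_model(ic50_nM = 60, equilibration_tau_s = 5)
  run <- simulate_pharmacology_run(p, cell, drug,
                                   schedule = data.frame(
                                     conc_nM = c(0, 60), n_sweeps = c(3, 15)))
  pk <- pharm_peaks(run)
  expect_equal(abs(pk$peak_pA[18]) / abs(pk$peak_pA[1]), 0.5,
               tolerance = 1e-3)
  # equilibrium inhibitions for 30 then 300 nM with IC50 60:
  # c/(c+IC50) = 1/3 and 5/6
  run2 <- simulate_pharmacology_run(p, cell, drug,
                                    schedule = data.frame(
                                      conc_nM = c(0, 30, 300),
                                      n_sweeps = c(3, 15, 15)))
  pk2 <- pharm_peaks(run2)
  inh <- 100 * (1 - abs(pk2$peak_pA) / abs(pk2$peak_pA[1]))
  expect_equal(inh[18], 100 * 30 / 90, tolerance = 0.2)
  expect_equal(inh[33], 100 * 300 / 360, tolerance = 0.2)
  expect_error(simulate_pharmacology_run(p, cell, drug,
                                         schedule = data.frame(conc_nM = -1,
                                                               n_sweeps = 2)),
               "negative")
})

test_that("simulate_sweep rejects invalid inputs", {
  p <- preset_gating("WT+b3")
  cell <- quiet_cell()
  prot <- protocol(data.frame(duration_ms = 10, v_mV = -89))
  bad <- prot; bad$v_mV <- Inf
  expect_error(simulate_sweep(bad, p, cell), "non-finite")
})
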