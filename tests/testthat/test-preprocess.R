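sim_p4_pair <- function(params, cell, v_test = -10) {
  prot <- protocol(data.frame(duration_ms = c(20, 25, 20),
                              v_mV = c(-89, v_test, -89)))
  test <- simulate_sweep(prot, params, cell)
  leak <- lapply(p4_leak_pulses(prot)$protocols, simulate_sweep,
                 params = params, cell = cell)
  list(test = test, leak = leak, prot = prot)
}

test_that("P/4 cancels ohmic leak exactly", {
  p <- preset_gating("WT+b3")
  # pure ohmic cell: zero channel conductance, leak only
  p0 <- p; p0$gmax_density <- 1e-300
  x <- sim_p4_pair(p0, quiet_cell(leak_nS = 3))
  out <- p4_subtract(x$test, x$leak)
  expect_lt(max(abs(out$i_pA)), 1e-9)
  # no leak: P/4 output equals the baseline-referenced input up to the
  # sub-sweeps' residual channel current (< 0.1 pA at -1/4 excursions)
  x2 <- sim_p4_pair(p, quiet_cell(leak_nS = 0))
  out2 <- p4_subtract(x2$test, x2$leak)
  expect_lt(max(abs(out2$i_pA -
                      (x2$test$i_pA - mean(x2$test$i_pA[1:100])))), 0.3)
  # ohmic + channel: residual equals the channel-only simulation to the
  # same sub-threshold channel-current floor (< 0.1% of the peak)
  x3 <- sim_p4_pair(p, quiet_cell(leak_nS = 1.5))
  out3 <- p4_subtract(x3$test, x3$leak)
  ref <- simulate_sweep(x3$prot, p, quiet_cell(leak_nS = 0))
  dmax <- max(abs(out3$i_pA - (ref$i_pA - mean(ref$i_pA[1:100]))))
  expect_lt(dmax, 0.3)
  expect_lt(dmax / max(abs(ref$i_pA)), 2e-3)
  # misaligned sub-sweeps are rejected
  short <- x3$leak
  short[[1]] <- short[[1]][-1, ]
  expect_error(p4_subtract(x3$test, short), "misaligned")
})

test_that("offline linear subtraction removes the fitted leak line", {
  p0 <- preset_gating("WT+b3"); p0$gmax_density <- 1e-300
  cell <- quiet_cell(leak_nS = 2)
  # two baseline voltages -> slope identifiable, leak-only sweep goes to ~0
  prot <- protocol(data.frame(duration_ms = c(50, 50, 25),
                              v_mV = c(-89, -99, -10)))
  sw <- simulate_sweep(prot, p0, cell)
  out <- offline_linear_subtract(sw, baseline_window = c(0, 100))
  expect_lt(max(abs(out$i_pA)), 1e-9)
  # single-voltage window: mean-only subtraction with a warning
  expect_warning(out2 <- offline_linear_subtract(sw, c(0, 50)), "mean only")
  expect_lt(max(abs(out2$i_pA[1:2500])), 1e-9)
  # zero-leak sweep is unchanged to within the tiny holding-level channel
  # current that the baseline fit mistakes for leak
  p <- preset_gating("WT+b3")
  sw3 <- simulate_sweep(prot, p, quiet_cell(leak_nS = 0))
  out3 <- offline_linear_subtract(sw3, c(0, 100))
  expect_lt(max(abs(out3$i_pA - sw3$i_pA)), 0.6)
  expect_lt(max(abs(out3$i_pA - sw3$i_pA)) / max(abs(sw3$i_pA)), 5e-3)
  # pooled family-level estimate recovers the leak conductance
  est <- estimate_leak(list(sw), windows = c(0, 100))
  expect_equal(unname(est[["g"]]), 2, tolerance = 1e-9)
})

test_that("peak extraction: sign, density and capacitance invariance", {
  p <- preset_gating("WT+b3")
  prot <- protocol(data.frame(duration_ms = c(20, 25, 20),
                              v_mV = c(-89, -10, -89)))
  # flat zero trace -> 0
  flat <- simulate_sweep(protocol(data.frame(duration_ms = 10, v_mV = 0)),
                         preset_gating("WT+b3"),
                         quiet_cell(leak_nS = 0))
  flat$i_pA[] <- 0
  expect_equal(peak_current(flat)$amplitude_pA, 0)
  # synthetic -500 pA peak with 20 pF -> -25 pA/pF
  sw <- simulate_sweep(prot, p, quiet_cell(leak_nS = 0))
  sw$i_pA[1000] <- -500
  pk <- peak_current(sw)
  expect_equal(pk$amplitude_pA, -500)
  expect_equal(pk$density_pA_pF, -25)
  expect_error(peak_current(sw, window = c(500, 600)), "empty")
  # density is capacitance-invariant for scaled cells
  d <- vapply(c(10, 20, 40), function(cap) {
    cellx <- cell_model(capacitance_pF = cap, leak_nS = 0, noise_sd_pA = 0)
    peak_current(simulate_sweep(prot, p, cellx))$density_pA_pF
  }, 0)
  expect_equal(d[1], d[2], tolerance = 1e-12)
  expect_equal(d[2], d[3], tolerance = 1e-12)
})

test_that("run-down regression recovers the generating slope", {
  # constant series -> slope 0
  const <- data.frame(t_min = 0:9, peak_pA = rep(-400, 10))
  expect_equal(fit_rundown(const)$slope, 0, tolerance = 1e-12)
  expect_error(fit_rundown(const[1:2, ]), "at least 3")
  # noise-free series generated at the published WT+b3 slope
  slope <- -1.5383
  t_min <- (0:29) * 10 / 60
  peaks <- data.frame(t_min = t_min,
                      peak_pA = -400 * (1 + slope / 100 * t_min))
  rd <- fit_rundown(peaks)
  expect_equal(rd$slope, slope, tolerance = 1e-10)
  # noisy series: estimate within 4 standard errors of truth
  withr::with_seed(11, {
    noisy <- peaks
    noisy$peak_pA <- noisy$peak_pA + rnorm(30, sd = 4)
    rdn <- fit_rundown(noisy)
    se <- tidy(rdn)$std.error[2]
    expect_lt(abs(rdn$slope - slope), 4 * se)
  })
})

test_that("run-down correction yields calibrated inhibition", {
  slope <- -1.5383
  t_min <- (0:29) * 10 / 60
  trend <- 1 + slope / 100 * t_min
  rd <- fit_rundown(data.frame(t_min = t_min, peak_pA = -400 * trend))
  # no drug: ~0% inhibition at all times
  none <- data.frame(t_min = t_min, peak_pA = -400 * trend, conc_nM = 0)
  expect_equal(rundown_correct(none, rd)$inhibition_pct, rep(0, 30),
               tolerance = 1e-9)
  # full block -> 100%
  conc <- c(rep(0, 5), rep(3000, 25))
  blocked <- ifelse(conc > 0, 0, 1)
  full <- data.frame(t_min = t_min, peak_pA = -400 * trend * blocked,
                     conc_nM = conc)
  expect_equal(rundown_correct(full, rd)$inhibition_pct[6:30], rep(100, 25))
  # 30 nM against IC50 60 nM at equilibrium: 33.3% corrected inhibition
  conc2 <- c(rep(0, 5), rep(30, 25))
  frac <- ifelse(conc2 > 0, 1 - 30 / (30 + 60), 1)
  drugged <- data.frame(t_min = t_min, peak_pA = -400 * trend * frac,
                        conc_nM = conc2)
  expect_equal(rundown_correct(drugged, rd)$inhibition_pct[10],
               100 * 30 / 90, tolerance = 1e-9)
  bad <- data.frame(t_min = 100, peak_pA = -1, conc_nM = 0)
  expect_error(rundown_correct(bad, rd), "<= 0")
})
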