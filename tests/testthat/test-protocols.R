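test_that("I-V family builder counts sweeps and holds at -89 mV", {
  fam <- build_iv_family(v_start = -79, v_stop = -74, step = 5)
  expect_length(fam, 2)
  expect_equal(fam$varied, c(-79, -74))
  # default holding potential
  expect_equal(fam$protocols[[1]]$v_mV[1], -89)
  # degenerate range: one sweep
  expect_length(build_iv_family(v_start = -20, v_stop = -20), 1)
  # step not dividing the range clips the last pulse with a warning
  expect_warning(fam2 <- build_iv_family(v_start = 0, v_stop = 7, step = 5),
                 "clipped")
  expect_equal(fam2$varied, c(0, 5))
})

test_that("SSI family uses 30-s sweep intervals and the 20-75 ms envelope", {
  fam <- build_ssi_family(v_test = -10, cond_start = -89, cond_stop = -79,
                          step = 10)
  expect_length(fam, 2)
  expect_equal(attr(fam$protocols[[1]], "inter_sweep_s"), 30)
  expect_error(build_ssi_family(v_test = -10, control_ms = 10), "20-75")
  expect_error(build_ssi_family(v_test = -10, control_ms = 80), "20-75")
})

test_that("recovery family is sampled at 10 kHz over the stated gap range", {
  fam <- build_recovery_family(v_test = -10, gaps_s = 0.001)
  expect_length(fam, 1)
  expect_equal(attr(fam$protocols[[1]], "sampling_rate_hz"), 10000)
  # pre + gap + test = 2000 + 1 + 25 = 2026 ms of defined protocol
  p <- fam$protocols[[1]]
  expect_equal(sum(p$duration_ms[2:4]), 2026)
  expect_error(build_recovery_family(v_test = -10, gaps_s = 25), "within")
  expect_error(build_recovery_family(v_test = -10, gaps_s = 1e-4), "within")
  lad <- recovery_gap_ladder()
  expect_length(lad, 15)
  expect_equal(range(lad), c(0.001, 20))
})

test_that("tail family defaults include the -69 and -49 mV repolarizations", {
  fam <- build_tail_family(v_rev = 62.8)
  expect_true(all(c(-69, -49) %in% fam$varied))
  expect_error(build_tail_family(v_rev = 62.8, repol_voltages = numeric(0)),
               "empty")
})

test_that("pharmacology train and 5-s protocols have the stated timing", {
  p <- build_pharm_protocol(v_test = -10)
  expect_equal(attr(p, "inter_sweep_s"), 10)   # 0.1 Hz
  expect_equal(p$duration_ms[2], 100)
  p5 <- build_inact5s_protocol(v_test = -10)
  expect_equal(p5$duration_ms[2], 5000)
  # 5-s pulse at 50 kHz = 250000 samples
  expect_equal(round(p5$duration_ms[2] * attr(p5, "sampling_rate_hz") / 1000),
               250000)
})

test_that("every builder output is sample-grid aligned", {
  fams <- list(build_iv_family(v_start = -40, v_stop = -20),
               build_ssi_family(v_test = -10, cond_stop = -69),
               build_recovery_family(v_test = -10, gaps_s = c(0.0013, 0.57)),
               build_tail_family(v_rev = 60, repol_voltages = -69))
  for (fam in fams) {
    for (p in fam$protocols) {
      rate <- attr(p, "sampling_rate_hz")
      n <- p$duration_ms * rate / 1000
      expect_equal(n, round(n), tolerance = 1e-9)
      expect_equal(nrow(as_stimulus(p)), sum(round(n)))
    }
  }
  expect_error(protocol(data.frame(duration_ms = 0, v_mV = -89)), "zero-length")
  expect_error(protocol(data.frame(duration_ms = 10, v_mV = NaN)), "non-finite")
})

test_that("junction correction is a -9.3 mV shift applied exactly once", {
  expect_equal(junction_correct(0), -9.3)
  expect_equal(junction_correct(-79.7), -89)
  prot <- protocol(data.frame(duration_ms = c(10, 10), v_mV = c(-79.7, 0)),
                   jp_corrected = FALSE)
  cor1 <- junction_correct(prot)
  expect_equal(cor1$v_mV, c(-89, -9.3))
  # double correction is a bookkeeping error
  expect_error(junction_correct(cor1), "already")
  fam <- build_iv_family(v_start = -20, v_stop = -20, jp_corrected = FALSE)
  fam2 <- junction_correct(fam)
  expect_equal(fam2$protocols[[1]]$v_mV[2], -29.3)
})

test_that("P/4 sub-sweeps scale the waveform by -1/4", {
  prot <- protocol(data.frame(duration_ms = c(20, 25, 20),
                              v_mV = c(-89, -49, -89)))
  sub <- p4_leak_pulses(prot)
  expect_length(sub$protocols, 4)
  # +40 mV excursion -> four -10 mV excursions
  expect_equal(sub$protocols[[1]]$v_mV, c(-89, -99, -89))
  # zero excursion -> flat sub-sweeps
  flat <- protocol(data.frame(duration_ms = c(20, 25), v_mV = c(-89, -89)))
  expect_equal(unique(p4_leak_pulses(flat)$protocols[[1]]$v_mV), -89)
})
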