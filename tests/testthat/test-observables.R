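test_that("trajectory percent conversion matches elementwise division", {
  r <- standard_rates()
  traj <- simulate_exchange(r, times = seq(0, 400, 10))
  pair <- trajectory_to_percent(traj, "pairing")
  disp <- trajectory_to_percent(traj, "displacement")
  expect_equal(pair$percent[1], 100)
  expect_equal(disp$percent[1], 0)
  # brute-force elementwise oracle
  for (i in seq_len(nrow(traj))) {
    expect_identical(pair$percent[i], 100 * traj$A[i] / attr(traj, "A0"))
    expect_identical(disp$percent[i], 100 * traj$E[i] / attr(traj, "B0"))
  }
  # half conversion: A = 18 with A0 = 36 reads 50%
  half <- structure(tibble::tibble(time_s = 0, A = 18, B = 18, C1 = 0,
                                   C2 = 0, D = 18, E = 18),
                    A0 = 36, B0 = 36, scheme = "three_step")
  expect_equal(trajectory_to_percent(half, "pairing")$percent, 50)
})

test_that("FRET calibration maps fluorescence to percent and back", {
  calib <- fret_calibration(E_max = 0.6, F0 = 1)
  expect_equal(fluorescence_to_percent(1, calib, "pairing"), 100)
  expect_equal(fluorescence_to_percent(0.4, calib, "pairing"), 0)
  expect_equal(fluorescence_to_percent(0.7, calib, "pairing"), 50)
  expect_equal(fluorescence_to_percent(1, calib, "displacement"), 0)

  # round trip is the identity on [0, 100] for any valid calibration
  for (em in c(0.2, 0.6, 0.95)) for (f0 in c(0.5, 3)) {
    cal <- fret_calibration(em, f0)
    pct <- seq(0, 100, 5)
    for (assay in c("pairing", "displacement")) {
      back <- fluorescence_to_percent(percent_to_fluorescence(pct, cal, assay),
                                      cal, assay)
      expect_equal(back, pct, tolerance = 1e-12)
    }
  }
  expect_error(fret_calibration(0), class = "strandex_calibration_error")
  expect_error(fret_calibration(1.2), class = "strandex_calibration_error")
})

test_that("2AP conversion is the affine map anchored at the quench fraction", {
  expect_equal(two_ap_to_substrate_percent(1), 100)
  expect_equal(two_ap_to_substrate_percent(0.601), 0)
  expect_equal(two_ap_to_substrate_percent(0.8005), 50)
  # affine and strictly increasing
  f <- seq(0.62, 1, 0.02)
  pct <- two_ap_to_substrate_percent(f)
  expect_true(all(diff(pct) > 0))
  expect_lt(max(abs(diff(pct) / diff(f) - 100 / (1 - 0.601))), 1e-9)
  expect_error(two_ap_to_substrate_percent(0.8, quench_fraction = 1),
               class = "strandex_calibration_error")
  expect_error(two_ap_to_substrate_percent(-0.1), class = "strandex_invalid_input")
})

test_that("abortive quantification implements both SDS readings", {
  q <- abortive_quantify(60, 70, mode = "DSP")
  expect_equal(q$C2_plus_product_pct, 30)
  expect_equal(q$C1_pct, 10)
  # equivalently the substrate gain across SDS addition
  expect_equal(q$C1_pct, 70 - 60)

  q0 <- abortive_quantify(100, 100, mode = "DSP")
  expect_equal(unlist(q0), c(C1_pct = 0, C2_plus_product_pct = 0))

  qd <- abortive_quantify(60, 30, mode = "DSD")
  expect_equal(qd$C2_plus_product_pct, 30)
  expect_equal(qd$C1_pct, 10)

  # the printed (non-closing) reading stays available
  qp <- abortive_quantify(60, 30, mode = "DSD", c1_rule = "printed")
  expect_equal(qp$C1_pct, 30)

  # substrate dropping across SDS addition is physically inconsistent
  expect_warning(abortive_quantify(60, 50, mode = "DSP"),
                 class = "strandex_inconsistent_measurement")
  # small negative C1 from measurement noise is clamped to zero
  expect_equal(abortive_quantify(50, 51, mode = "DSD")$C1_pct, 0)
})

test_that("predicted intermediates close to 100% with substrate", {
  traj <- simulate_exchange(standard_rates(), times = seq(0, 900, 30))
  pred <- predict_intermediates(traj)
  expect_equal(unlist(pred[1, c("C1_pct", "C2_plus_product_pct")]),
               c(C1_pct = 0, C2_plus_product_pct = 0))
  substrate <- trajectory_to_percent(traj, "pairing")$percent
  closure <- substrate + pred$C1_pct + pred$C2_plus_product_pct
  expect_lt(max(abs(closure - 100)), 1e-9)
})

test_that("abortive quantification round-trips the simulated intermediates", {
  r <- standard_rates()
  quench <- c(150, 300, 600, 900)
  traj <- simulate_exchange(r, times = c(0, quench))
  pred <- predict_intermediates(traj)[-1, ]
  substrate_before <- trajectory_to_percent(traj, "pairing")$percent[-1]
  substrate_after <- substrate_before + pred$C1_pct
  product_after <- pred$C2_plus_product_pct
  dsp <- abortive_quantify(substrate_before, substrate_after, mode = "DSP")
  dsd <- abortive_quantify(substrate_before, product_after, mode = "DSD")
  expect_lt(max(abs(dsp$C2_plus_product_pct - dsd$C2_plus_product_pct)), 1e-9)
  expect_lt(max(abs(dsp$C1_pct - pred$C1_pct)), 1e-9)
  expect_lt(max(abs(dsp$C2_plus_product_pct - pred$C2_plus_product_pct)), 1e-9)
})
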