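# Velocity spectral peak pipeline: differentiation, PSD combination,
# peak descriptors and the rule-based classifier.

test_that("velocity estimation matches analytic derivatives", {
  fs <- 120
  t <- (0:1199) / fs
  # constant -> zero velocity
  expect_lt(max(abs(estimate_velocity(rep(7, 1200), fs))), 1e-9)
  # linear ramp at 10 mm/s -> 10 mm/s in the interior
  v_ramp <- estimate_velocity(10 * t, fs)
  expect_equal(median(v_ramp[100:1100]), 10, tolerance = 0.02)
  # sinusoid A sin(2 pi f t) -> velocity amplitude 2 pi f A
  A <- 2; f0 <- 5
  v_sin <- estimate_velocity(A * sin(2 * pi * f0 * t), fs)
  expect_equal(max(abs(v_sin[100:1100])), 2 * pi * f0 * A, tolerance = 0.02)
})

test_that("too-short signals are rejected", {
  expect_error(estimate_velocity(rnorm(8), 120), "too short")
})

test_that("axis combination follows the Euclidean norm of densities", {
  fs <- 120
  t <- (0:2399) / fs
  v <- 3 * sin(2 * pi * 6 * t)
  # energy on one axis only: combined equals that axis' smoothed PSD
  cx <- combined_velocity_psd(cbind(v, 0 * v, 0 * v), fs)
  wx <- welch_psd(v, fs)
  expect_equal(cx$psd, tremorkit:::smooth_log_psd(wx$psd),
               tolerance = 1e-10)
  # identical PSD on all three axes: combined = sqrt(3) * single
  call3 <- combined_velocity_psd(cbind(v, v, v), fs)
  expect_equal(call3$psd, sqrt(3) * cx$psd, tolerance = 1e-8)
  # argmax within one bin of the tone
  expect_lt(abs(cx$freq[which.max(cx$psd)] - 6), fs / 512 + 1e-9)
})

test_that("3 dB descriptors behave on constructed spectra", {
  freqs <- seq(0, 20, by = 0.05)
  # flat spectrum: no 3 dB crossing -> invalid
  flat <- extract_a1_features(freqs, rep(1, length(freqs)))
  expect_false(flat$valid_peak)
  # symmetric Gaussian bump: analytic 3 dB width, symmetric borders
  sigma <- 0.25
  bump <- 1e-6 + exp(-(freqs - 6)^2 / (2 * sigma^2))
  f <- extract_a1_features(freqs, bump)
  expect_true(f$valid_peak)
  expect_equal(f$F_CENTER, 6, tolerance = 0.051)
  bw_true <- 2 * sigma * sqrt(2 * log(2)) # power falls to 1/2
  expect_equal(f$BW, bw_true, tolerance = 0.02)
  expect_lt(abs(f$HI_POWER - f$LO_POWER), 0.1)
  expect_true(f$LO_F <= f$F_CENTER && f$F_CENTER <= f$HI_F)
  expect_gte(f$RELATIVE_POWER, 0)
  expect_lte(f$RELATIVE_POWER, 1)
  # all-zero PSD -> invalid
  expect_false(extract_a1_features(freqs, rep(0, length(freqs)))$valid_peak)
})

test_that("rules: narrow symmetric <=10 Hz peaks are tremor, others are not", {
  row <- function(fc, bw, hi = -3, lo = -3, amp = 1, valid = TRUE) {
    data.frame(F_CENTER = fc, AMPLITUDE_MM_P_S = amp, BW = bw,
               HI_F = fc + bw / 2, LO_F = fc - bw / 2, MAX_POWER = 0,
               HI_POWER = hi, LO_POWER = lo, RELATIVE_POWER = 0.5,
               valid_peak = valid)
  }
  expect_equal(classify_a1r(row(5, 1))$label, "present")
  expect_equal(classify_a1r(row(12, 1))$label, "absent")   # > 10 Hz
  expect_equal(classify_a1r(row(5, 3))$label, "absent")    # BW > 2 Hz
  expect_equal(classify_a1r(row(5, 1, hi = -1, lo = -8))$label, "absent")
  # winner-take-all: largest amplitude represents the extremity
  two <- rbind(row(5, 1, amp = 1), row(7, 1, amp = 10))
  out <- classify_a1r(two)
  expect_equal(out$label, "present")
  expect_equal(out$representative$AMPLITUDE_MM_P_S, 10)
  expect_error(classify_a1r(row(5, 1)[0, ]), "no marker")
})

test_that("time reversal leaves the velocity PSD unchanged (zero phase)", {
  # 1024 samples: Welch segments (512, 50% overlap) tile the signal, so
  # reversal permutes segments and the estimate must match exactly
  er <- make_tone_er(freq = 6, amp_xyz = c(1, 0.5, 0.2), duration = 1024 / 120)
  fwd <- combined_velocity_psd(
    estimate_velocity(er$data[, 1:3], 120), 120)
  rev <- combined_velocity_psd(
    estimate_velocity(er$data[nrow(er$data):1, 1:3], 120), 120)
  expect_equal(fwd$psd, rev$psd, tolerance = 1e-6)
})

test_that("scaling the trajectory scales amplitude and shifts power in dB", {
  er <- make_tone_er(freq = 5, duration = 10)
  base <- classify_a1r(er)$representative
  big <- er
  big$data <- er$data * 3.7
  scaled <- classify_a1r(big)$representative
  expect_equal(scaled$AMPLITUDE_MM_P_S / base$AMPLITUDE_MM_P_S, 3.7,
               tolerance = 1e-6)
  expect_equal(scaled$MAX_POWER - base$MAX_POWER, 20 * log10(3.7),
               tolerance = 1e-6)
})

test_that("pure voluntary motion is classified absent at any amplitude", {
  for (amp in c(5, 200)) {
    er <- simulate_extremity_recording(sim_config(
      duration_s = 15, voluntary_freqs_hz = c(0.7, 2.0),
      voluntary_amp_mm = c(amp, amp / 2), jitter_sd_mm = 0.05, seed = 21))
    expect_equal(classify_a1r(er)$label, "absent")
  }
})

test_that("injected tremor is recovered at its frequency", {
  for (f0 in c(4.5, 8)) {
    er <- simulate_extremity_recording(sim_config(
      duration_s = 20, tremor_present = TRUE, tremor_freq_hz = f0,
      tremor_amp_mm = 1, jitter_sd_mm = 0.05, seed = 31))
    out <- classify_a1r(er)
    expect_equal(out$label, "present")
    expect_lt(abs(out$representative$F_CENTER - f0), 120 / 512 + 1e-9)
  }
})
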