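test_that("moving-average smoothing obeys its closed forms", {
  x <- rnorm(100)
  expect_identical(smooth_trace(x, 1), x)
  expect_equal(smooth_trace(rep(3, 100), 11), rep(3, 100))
  # impulse of height h with window w spreads to a plateau of height h / w
  imp <- c(rep(0, 50), 7, rep(0, 49))
  sm <- smooth_trace(imp, 7)
  expect_equal(max(sm), 7 / 7)
  expect_equal(sum(sm > 0), 7)
  # direct convolution oracle in the interior
  w <- 5
  conv <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  expect_equal(smooth_trace(x, w)[3:98], conv[3:98])
  expect_error(smooth_trace(x, 4), "odd")
  expect_error(smooth_trace(x, 101), "shorter")
})

test_that("detrending annihilates ramps and preserves the template", {
  dt <- 0.05
  t <- seq(0, 20, by = dt)
  ramp <- ncs_trace(2 + 0.3 * t, dt, 2)
  out <- detrend_trace(ramp)
  expect_lt(max(abs(out$samples)), 1e-9 * max(abs(ramp$samples)))

  zero <- detrend_trace(ncs_trace(rep(0, length(t)), dt, 2))
  expect_identical(max(abs(zero$samples)), 0)

  template <- generate_trace(5, 0.3, 0.45, 15, negative_amp = 4,
                             negative_lag = 2)
  drifted <- template
  drifted$samples <- drifted$samples + 1.5 - 0.2 * drifted$time
  rec <- detrend_trace(drifted)
  expect_lt(max(abs(rec$samples - template$samples)), 0.02 * 15)

  shallow <- ncs_trace(rnorm(100), 0.05, 0.5)  # 10 pre-stimulus samples
  expect_error(detrend_trace(shallow), "16 samples")
})

test_that("critical points of a noiseless triangle land on its vertices", {
  tri <- triangle_trace(onset = 2, peak = 4, offset = 6, height = 10)
  cp <- detect_critical_points(tri, smooth_window = 1)
  lat <- tri$time[c(cp$onset_idx, cp$peak_idx, cp$offset_idx)] -
    tri$stimulus_time
  expect_equal(lat[1], 2, tolerance = 0.051)
  expect_equal(lat[2], 4, tolerance = 0.051)
  expect_equal(lat[3], 6, tolerance = 0.11)
  expect_true(cp$onset_idx < cp$peak_idx)
  expect_true(cp$peak_idx < cp$trough_idx)
  expect_true(cp$trough_idx <= cp$offset_idx)
})

test_that("noiseless biphasic onset lands at the template take-off", {
  tr <- generate_trace(5, 0.25, 0.35, 20, negative_amp = 6,
                       negative_lag = 1.5)
  cp <- detect_critical_points(tr, smooth_window = 1)
  # oracle: exhaustive scan for the first post-stimulus sample above 1% of
  # the peak
  onepct <- which(tr$samples > 0.01 * max(tr$samples) &
                    tr$time > tr$stimulus_time)[1]
  expect_lte(abs(cp$onset_idx - onepct), 2)
})

test_that("flat traces yield a no-response result, not an error", {
  flat <- ncs_trace(rnorm(400, sd = 0.3), 0.05, 2)
  cp <- detect_critical_points(flat)
  expect_false(cp$response)
  expect_true(is.na(cp$peak_idx))
  # no-response propagates to features as zero amplitude
  expect_identical(unname(amplitude_features(flat, cp)["Hmax"]), 0)
})

test_that("detection is shift-equivariant and amplitude-invariant", {
  base <- generate_trace(5, 0.25, 0.35, 20, negative_amp = 6,
                         negative_lag = 1.5)
  cp0 <- detect_critical_points(base)
  idx0 <- c(cp0$onset_idx, cp0$peak_idx, cp0$trough_idx, cp0$offset_idx)
  for (k_ms in c(1, 2.5)) {
    shifted <- generate_trace(5 + k_ms, 0.25, 0.35, 20, negative_amp = 6,
                              negative_lag = 1.5)
    cps <- detect_critical_points(shifted)
    idx <- c(cps$onset_idx, cps$peak_idx, cps$trough_idx, cps$offset_idx)
    expect_true(all(abs(idx - (idx0 + round(k_ms / 0.05))) <= 1))
  }
  for (c_amp in c(0.5, 2, 10)) {
    scaled <- base
    scaled$samples <- base$samples * c_amp
    cpc <- detect_critical_points(scaled,
                                  min_amplitude = 2 * min(c_amp, 1))
    expect_identical(c(cpc$onset_idx, cpc$peak_idx, cpc$trough_idx,
                       cpc$offset_idx), idx0)
  }
})

test_that("detection on noisy traces tracks the noiseless detection", {
  tr0 <- generate_trace(5, 0.25, 0.35, 20, negative_amp = 6,
                        negative_lag = 1.5)
  cp0 <- detect_critical_points(tr0)
  n_trials <- 200
  err <- matrix(NA_real_, n_trials, 4)
  for (i in seq_len(n_trials)) {
    # SNR 10: noise sd is a tenth of the peak amplitude
    trn <- generate_trace(5, 0.25, 0.35, 20, negative_amp = 6,
                          negative_lag = 1.5, noise_sd = 2, seed = i)
    cpn <- detect_critical_points(trn)
    err[i, ] <- c(cpn$onset_idx - cp0$onset_idx,
                  cpn$peak_idx - cp0$peak_idx,
                  cpn$trough_idx - cp0$trough_idx,
                  cpn$offset_idx - cp0$offset_idx)
  }
  expect_gte(mean(abs(err[, 1]) <= 3), 0.95)  # onset
  expect_gte(mean(abs(err[, 2]) <= 3), 0.95)  # peak
  # the trough bowl and the offset flat carry little curvature relative to
  # the noise at this SNR; their localisation is looser
  expect_gte(mean(abs(err[, 3]) <= 8), 0.90)
  expect_gte(mean(abs(err[, 4]) <= 8), 0.90)
})

test_that("cohort annotation emits ordered latencies per channel", {
  coh <- generate_cohort(sizes = c(1, 0, 0, 0), seed = 2, noise_scale = 0)
  ann <- annotate_cohort(coh)
  expect_equal(nrow(ann), 8)
  expect_true(all(ann$response))
  expect_true(all(ann$onset_ms < ann$peak_ms))
  expect_true(all(ann$trough_ms <= ann$offset_ms))
  expect_true(all(ann$onset_ms > 0))
})
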