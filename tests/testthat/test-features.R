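test_that("triangle geometry matches its closed forms", {
  tri <- triangle_trace(onset = 2, peak = 4, offset = 6, height = 10)
  cp <- triangle_cp(tri)
  ar <- area_features(tri, cp)
  # base b = 4 ms, height h = 10: A = bh/2, Upper = bh/8, Lower = 3bh/8,
  # UL = UR = bh/16, LL = LR = 3bh/16
  expect_equal(unname(ar["A"]), 20, tolerance = 0.02)
  expect_equal(unname(ar["Upper"]), 5, tolerance = 0.02)
  expect_equal(unname(ar["Lower"]), 15, tolerance = 0.02)
  expect_equal(unname(ar["Left"]), 10, tolerance = 0.02)
  expect_equal(unname(ar["Right"]), 10, tolerance = 0.02)
  expect_equal(unname(ar["UL"]), 2.5, tolerance = 0.02)
  expect_equal(unname(ar["UR"]), 2.5, tolerance = 0.02)
  expect_equal(unname(ar["LL"]), 7.5, tolerance = 0.02)
  expect_equal(unname(ar["LR"]), 7.5, tolerance = 0.02)
  expect_equal(unname(ar["r_Upper_Lower"]), 1 / 3, tolerance = 0.02)
  expect_equal(unname(ar["r_Aeabs_A"]), 1, tolerance = 1e-6)  # monophasic

  du <- duration_features(tri, cp)
  expect_equal(unname(du["D"]), 4, tolerance = 0.03)
  expect_equal(unname(du["Dh2"]), 2, tolerance = 0.03)

  amp <- amplitude_features(tri, cp)
  expect_equal(unname(amp["H"]), 10)
  expect_equal(unname(amp["Hmax"]), 10)
})

test_that("amplitude features on a trace with a trough", {
  tri <- triangle_trace(onset = 2, peak = 4, offset = 6, height = 10,
                        trough_depth = 2)
  cp <- detect_critical_points(tri, smooth_window = 1)
  amp <- amplitude_features(tri, cp)
  expect_equal(unname(amp["H"]), 10, tolerance = 0.03)
  expect_equal(unname(amp["Hmaxmin"]), 12, tolerance = 0.03)
  # voltage scaling doubles every amplitude
  tri2 <- tri
  tri2$samples <- 2 * tri$samples
  amp2 <- amplitude_features(tri2, cp)
  expect_equal(unname(amp2), unname(2 * amp))
})

test_that("latency features are stimulus-relative and shift-equivariant", {
  tri <- triangle_trace(onset = 2, peak = 3.2, offset = 6)
  cp <- triangle_cp(tri, onset = 2, peak = 3.2, offset = 6)
  lat <- latency_features(tri, cp)
  expect_equal(unname(lat["Lon"]), 2, tolerance = 0.03)
  expect_equal(unname(lat["Lpeak"]), 3.2, tolerance = 0.03)
  expect_equal(unname(lat["Lonpeak"]), 1.2, tolerance = 0.05)

  # moving stimulus and pulse together leaves latencies unchanged
  tri_s <- triangle_trace(onset = 2, peak = 3.2, offset = 6, stimulus = 3)
  cp_s <- triangle_cp(tri_s, onset = 2, peak = 3.2, offset = 6)
  expect_equal(latency_features(tri_s, cp_s), lat, tolerance = 1e-8)
})

test_that("conduction velocities follow distance over latency", {
  tri <- triangle_trace(onset = 2.8, peak = 4, offset = 6)
  cp <- triangle_cp(tri, onset = 2.8, peak = 4, offset = 6)
  expect_equal(conduction_velocity(tri, cp), 140 / 2.8, tolerance = 0.02)

  prox <- triangle_trace(onset = 8, peak = 10, offset = 13,
                         modality = "motor")
  prox$site <- "proximal"
  prox$segment_distance <- 230
  cpp <- triangle_cp(prox, onset = 8, peak = 10, offset = 13)
  expect_equal(conduction_velocity(prox, cpp, distal_onset_ms = 4), 57.5,
               tolerance = 0.02)
  expect_true(is.na(conduction_velocity(prox, cpp, distal_onset_ms = 9)))
})

test_that("rectangle and Gaussian durations match closed forms", {
  rc <- rect_trace(start = 3, width = 3, height = 10)
  cpr <- detect_critical_points(rc, smooth_window = 1)
  dur <- duration_features(rc, cpr)
  expect_equal(unname(dur["Dh2"]), 3, tolerance = 0.06 / 3)

  gs <- gauss_trace(center = 6, sd = 0.5)
  cpg <- detect_critical_points(gs, smooth_window = 1)
  dg <- duration_features(gs, cpg)
  expect_equal(unname(dg["Dh2"]), 2 * sqrt(2 * log(2)) * 0.5,
               tolerance = 0.02)
})

test_that("secant and regression slopes match hand arithmetic", {
  tri <- triangle_trace(onset = 2, peak = 4, offset = 7, height = 10)
  cp <- triangle_cp(tri, onset = 2, peak = 4, offset = 7)
  sl <- slope_features(tri, cp)
  expect_equal(unname(sl["tan_left"]), 5, tolerance = 0.02)
  expect_equal(unname(sl["tan_right"]), -10 / 3, tolerance = 0.02)
  # on a linear ramp the regression slope equals the secant slope
  expect_equal(unname(sl["fit_left"]), unname(sl["tan_left"]),
               tolerance = 0.02)
  expect_equal(unname(sl["fit_right"]), unname(sl["tan_right"]),
               tolerance = 0.02)
})

test_that("expanded absolute area adds the negative lobe", {
  tr <- generate_trace(5, 0.3, 0.4, 20, negative_amp = 5, negative_lag = 3)
  cp <- detect_critical_points(tr, smooth_window = 1)
  ar <- area_features(tr, cp)
  # the negative lobe is an asymmetric Gaussian of amplitude 5 and widths
  # (0.4, 0.6) ms: area = 5 * sqrt(pi/2) * (0.4 + 0.6)
  neg_area <- 5 * sqrt(pi / 2) * (0.4 + 0.6)
  expect_equal(unname(ar["Aeabs"] - ar["A"]), neg_area, tolerance = 0.05)
  expect_gte(unname(ar["Aeabs"]), unname(ar["A"]))
})

test_that("subarea partition conserves the total area on random pulses", {
  set.seed(42)
  for (i in 1:50) {
    tr <- generate_trace(peak_latency = runif(1, 3, 8),
                         rise_width = runif(1, 0.2, 0.8),
                         fall_width = runif(1, 0.3, 1.2),
                         positive_amp = runif(1, 5, 40),
                         negative_amp = runif(1, 0, 10),
                         negative_lag = runif(1, 1, 4),
                         noise_sd = runif(1, 0, 1), seed = i)
    cp <- detect_critical_points(tr)
    if (!cp$response) next
    ar <- area_features(tr, cp)
    A <- ar[["A"]]
    expect_lte(abs(ar[["UL"]] + ar[["LL"]] + ar[["UR"]] + ar[["LR"]] - A),
               1e-6 * A)
    expect_lte(abs(ar[["Left"]] + ar[["Right"]] - A), 1e-6 * A)
    expect_lte(abs(ar[["Upper"]] + ar[["Lower"]] - A), 1e-6 * A)
  }
})

test_that("feature scale behaviour: amplitudes scale, geometry does not", {
  tr <- generate_trace(5, 0.3, 0.4, 20, negative_amp = 5, negative_lag = 2)
  cp <- detect_critical_points(tr, smooth_window = 1)
  f1 <- trace_features(tr, cp)
  tr2 <- tr
  tr2$samples <- 3 * tr$samples
  f2 <- trace_features(tr2, cp)
  amp_like <- c("H", "Hmax", "Hmaxmin", "A", "Aeabs", "UL", "LL", "UR",
                "LR", "Left", "Right", "Upper", "Lower",
                "tan_left", "tan_right", "fit_left", "fit_right")
  keep <- setdiff(names(f1), amp_like)
  expect_equal(f2[amp_like], 3 * f1[amp_like], tolerance = 1e-8)
  expect_equal(f2[keep], f1[keep], tolerance = 1e-8)
})

test_that("order relations between features hold on generated pulses", {
  set.seed(7)
  for (i in 1:20) {
    tr <- generate_trace(peak_latency = runif(1, 3, 7),
                         rise_width = runif(1, 0.2, 0.6),
                         fall_width = runif(1, 0.3, 0.9),
                         positive_amp = runif(1, 5, 40),
                         negative_amp = runif(1, 0, 8),
                         negative_lag = runif(1, 1.5, 4))
    cp <- detect_critical_points(tr, smooth_window = 1)
    f <- trace_features(tr, cp)
    expect_gte(f[["Aeabs"]], f[["A"]] - 1e-9)
    expect_lte(f[["Dh2"]], f[["D"]] + 1e-9)
    expect_lte(f[["Lonpeak"]], f[["D"]] + 1e-9)
    expect_gte(f[["Hmaxmin"]], f[["Hmax"]] - 1e-9)
    expect_gte(f[["Hmax"]], f[["H"]] - 1e-9)
    expect_gte(f[["H"]], 0)
  }
})

test_that("the registries enumerate 34 per-trace and 302 per-hand names", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 34)
  expect_equal(sum(reg$class == "common"), 8)
  expect_equal(sum(reg$class == "novel"), 26)
  expect_false(anyDuplicated(reg$feature) > 0)

  hreg <- hand_feature_registry()
  expect_equal(nrow(hreg), 302)
  expect_equal(sum(hreg$channel %in% channel_montage()$channel), 272)
  expect_equal(sum(startsWith(hreg$channel, "diff_")), 30)
  expect_false(anyDuplicated(hreg$column) > 0)
})

test_that("hand vectors have 302 entries and homologous diffs cancel", {
  hand <- generate_hand("A", seed = 4, noise_scale = 0)
  fv <- hand_features(hand)
  expect_length(fv, 302)
  expect_identical(names(fv), hand_feature_registry()$column)

  # identical median and ulnar traces make every difference feature zero
  hand$traces$ulnar_sensory_digit4 <- hand$traces$median_sensory_digit4
  hand$traces$ulnar_sensory_digit4$nerve <- "ulnar"
  hand$traces$ulnar_motor_distal <- hand$traces$median_motor_distal
  hand$traces$ulnar_motor_distal$nerve <- "ulnar"
  hand$traces$ulnar_motor_proximal <- hand$traces$median_motor_proximal
  hand$traces$ulnar_motor_proximal$nerve <- "ulnar"
  fv0 <- hand_features(hand)
  diffs <- fv0[startsWith(names(fv0), "diff_")]
  expect_true(all(abs(diffs) < 1e-9))

  hand$traces$median_motor_distal <- NULL
  expect_error(hand_features(hand), "missing channel")
})
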