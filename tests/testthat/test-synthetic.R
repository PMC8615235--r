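test_that("noiseless template reproduces its pulse parameters exactly", {
  tr <- generate_trace(peak_latency = 3, rise_width = 0.3, fall_width = 0.4,
                       positive_amp = 20, negative_amp = 0)
  expect_equal(max(tr$samples), 20, tolerance = 1e-4)
  expect_equal(tr$time[which.max(tr$samples)] - tr$stimulus_time, 3,
               tolerance = 0.051)
  expect_true(all(tr$samples >= 0))

  # well-separated negative lobe reaches its drawn depth
  tr2 <- generate_trace(peak_latency = 3, rise_width = 0.3, fall_width = 0.4,
                        positive_amp = 20, negative_amp = 5,
                        negative_lag = 3)
  expect_equal(min(tr2$samples), -5, tolerance = 1e-3)
  expect_gt(tr2$time[which.min(tr2$samples)], tr2$time[which.max(tr2$samples)])
})

test_that("trace generation is byte-identical under a fixed seed", {
  a <- generate_trace(3, 0.3, 0.4, 20, noise_sd = 2, seed = 7)
  b <- generate_trace(3, 0.3, 0.4, 20, noise_sd = 2, seed = 7)
  expect_identical(a$samples, b$samples)
  c <- generate_trace(3, 0.3, 0.4, 20, noise_sd = 2, seed = 8)
  expect_false(identical(a$samples, c$samples))
})

test_that("invalid pulse parameters are rejected", {
  expect_error(generate_trace(3, 0.3, 0.4, 20, duration = 4),
               "duration")
  expect_error(generate_trace(3, -0.3, 0.4, 20), "widths")
  expect_error(ncs_trace(rnorm(10), 0.05, 1), "64 samples")
  expect_error(ncs_trace(rnorm(100), -1, 1), "sample_interval")
})

test_that("baseline noise matches the configured SD within 20%", {
  tr <- generate_trace(10, 0.8, 1.2, 8, noise_sd = 0.5, duration = 60,
                       stimulus_time = 30, modality = "motor",
                       site = "distal", distance = 70, seed = 3)
  pre <- tr$samples[tr$time < tr$stimulus_time]
  expect_gte(length(pre), 500)
  expect_equal(sd(pre), 0.5, tolerance = 0.2)
})

test_that("generated hands sit inside their grade's defining region", {
  # noiseless grade A: normal conduction on the measured traces
  hA <- generate_hand("A", seed = 1, noise_scale = 0, margin = 0.2)
  fA <- hand_features(hA)
  expect_lt(attr(fA, "dml_ms"), 4.5)
  expect_gt(attr(fA, "sensory_cv"), 40)
  expect_true(attr(fA, "snap_present"))

  # noiseless grade B: slowed sensory conduction, preserved DML
  hB <- generate_hand("B", seed = 2, noise_scale = 0, margin = 0.2)
  fB <- hand_features(hB)
  expect_lt(attr(fB, "sensory_cv"), 40)
  expect_lt(attr(fB, "dml_ms"), 4.5)
  expect_lt(fB[["median_motor_distal.Lon"]], 4.5)

  # absent-SNAP severe hand: digit-2 sensory response below the floor
  params <- default_grade_params()
  params$D$snap_present_prob <- 0
  hD <- generate_hand("D", params = params, seed = 3, noise_scale = 0,
                      margin = 0.2)
  fD <- hand_features(hD)
  expect_false(attr(fD, "snap_present"))
  expect_identical(fD[["median_sensory_digit2.Hmax"]], 0)
  expect_true(is.na(fD[["median_sensory_digit2.Lon"]]))
})

test_that("cohort composition and clinical mapping follow the study design", {
  coh <- generate_cohort(sizes = c(A = 19, B = 10, C = 17, D = 19),
                         disagreement_rate = 0, seed = 11, noise_scale = 0)
  expect_length(coh, 65)
  cl <- table(vapply(coh, `[[`, "", "clinical_label"))
  expect_equal(unname(cl[c("control", "mild_moderate", "severe")]),
               c(19, 27, 19), ignore_attr = TRUE)
  single <- generate_cohort(sizes = c(0, 0, 0, 1), seed = 1)
  expect_length(single, 1)
  expect_identical(single[[1]]$clinical_label, "severe")
})

test_that("cohorts are reproducible and disagreement moves adjacent labels", {
  a <- generate_cohort(sizes = c(2, 2, 2, 2), seed = 5)
  b <- generate_cohort(sizes = c(2, 2, 2, 2), seed = 5)
  expect_identical(lapply(a, function(h) h$traces$median_motor_distal$samples),
                   lapply(b, function(h) h$traces$median_motor_distal$samples))

  coh <- generate_cohort(sizes = c(10, 5, 5, 10), seed = 9,
                         disagreement_rate = 0.3)
  moved <- vapply(coh, function(h) {
    h$clinical_label != unname(c(A = "control", B = "mild_moderate",
                                 C = "mild_moderate", D = "severe")[h$true_grade])
  }, NA)
  expect_equal(sum(moved), 9)  # round(0.3 * 30)
  # moved labels are adjacent: controls/severe may only become mild_moderate
  for (h in coh[moved]) {
    if (h$true_grade %in% c("A", "D")) {
      expect_identical(h$clinical_label, "mild_moderate")
    } else {
      expect_true(h$clinical_label %in% c("control", "severe"))
    }
  }
})

test_that("the text container round-trips a cohort", {
  coh <- generate_cohort(sizes = c(1, 0, 0, 1), seed = 21)
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_length(back, 2)
  expect_identical(back[[1]]$true_grade, coh[[1]]$true_grade)
  expect_identical(names(back[[1]]$traces), names(coh[[1]]$traces))
  tr0 <- coh[[1]]$traces$median_sensory_digit2
  tr1 <- back[[1]]$traces$median_sensory_digit2
  expect_equal(tr1$samples, tr0$samples, tolerance = 1e-6)
  expect_identical(tr1$distance, tr0$distance)
  unlink(dir, recursive = TRUE)
})
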