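#' @title The eight-channel montage
#' @description Canonical channel keys and geometry of the per-hand study:
#' sensory antidromic recordings of the median nerve at digits 2 and 4 and
#' the ulnar nerve at digits 4 and 5 (wrist-to-digit 140 mm), and motor
#' recordings of the median (APB) and ulnar nerves with distal (70 mm) and
#' proximal stimulation (elbow-wrist segment 230 mm). The ulnar channels are
#' the within-hand comparator: the ulnar nerve does not pass through the
#' carpal tunnel and is unaffected by CTS.
#' @return A data.frame with one row per channel: `channel`, `nerve`,
#'   `modality`, `site`, `distance`, `segment_distance`.
#' @export
channel_montage <- function() {
  data.frame(
    channel = c("median_sensory_digit2", "median_sensory_digit4",
                "ulnar_sensory_digit4", "ulnar_sensory_digit5",
                "median_motor_distal", "median_motor_proximal",
                "ulnar_motor_distal", "ulnar_motor_proximal"),
    nerve = c("median", "median", "ulnar", "ulnar",
              "median", "median", "ulnar", "ulnar"),
    modality = c("sensory", "sensory", "sensory", "sensory",
                 "motor", "motor", "motor", "motor"),
    site = c("digit2", "digit4", "digit4", "digit5",
             "distal", "proximal", "distal", "proximal"),
    distance = c(140, 140, 140, 140, 70, 300, 70, 300),
    segment_distance = c(NA, NA, NA, NA, NA, 230, NA, 230),
    stringsAsFactors = FALSE
  )
}

#' Grade-conditional generator parameters
#'
#' One parameter set per neurophysiological grade (A none, B mild, C
#' moderate, D severe). The distal motor latency (DML) and sensory
#' conduction velocity (CV) ranges sit inside the grading regions
#' (CV threshold 40 m/s; DML thresholds 4.5 and 6.5 ms); amplitude ranges,
#' pulse-width scaling (temporal dispersion grows with severity) and the
#' SNAP-present probability complete the clinical picture. Sensory noise is
#' higher than motor noise, as in real recordings.
#'
#' @param grade one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param dml_range distal motor latency range, ms.
#' @param sensory_cv_range median sensory CV range, m/s.
#' @param snap_present_prob probability that the median SNAP is present.
#' @param sensory_amp_range SNAP amplitude range, uV.
#' @param motor_amp_range CMAP amplitude range, mV.
#' @param width_scale multiplier on the pulse flank widths.
#' @param dml_range_absent DML range used when the SNAP is absent (grade D
#'   only; the severe rule then requires only DML > 4.5 ms).
#' @param noise_sd_sensory,noise_sd_motor additive noise SD in trace units
#'   (uV / mV); the sensory value must exceed the motor one.
#' @param drift_amplitude sinusoidal baseline-drift amplitude in sensory
#'   units (uV); motor traces use one tenth of it in mV.
#' @param drift_period drift period, ms.
#' @return A list of class `grade_params`.
#' @export
grade_params <- function(grade, dml_range, sensory_cv_range,
                         snap_present_prob, sensory_amp_range,
                         motor_amp_range, width_scale = 1,
                         dml_range_absent = NULL,
                         noise_sd_sensory = 0.8, noise_sd_motor = 0.05,
                         drift_amplitude = 0.3, drift_period = 120) {
  stopifnot(grade %in% c("A", "B", "C", "D"),
            diff(dml_range) > 0, diff(sensory_cv_range) > 0,
            snap_present_prob >= 0, snap_present_prob <= 1,
            diff(sensory_amp_range) > 0, diff(motor_amp_range) > 0,
            noise_sd_sensory > noise_sd_motor)
  structure(
    list(grade = grade, dml_range = dml_range,
         sensory_cv_range = sensory_cv_range,
         snap_present_prob = snap_present_prob,
         sensory_amp_range = sensory_amp_range,
         motor_amp_range = motor_amp_range,
         width_scale = width_scale,
         dml_range_absent = if (is.null(dml_range_absent)) dml_range
                            else dml_range_absent,
         noise_sd_sensory = noise_sd_sensory,
         noise_sd_motor = noise_sd_motor,
         drift_amplitude = drift_amplitude, drift_period = drift_period),
    class = "grade_params"
  )
}

#' Default grade-conditional parameter sets
#'
#' Grade A draws normal values (DML < 4.5 ms, sensory CV > 40 m/s), grade B
#' slowed sensory conduction with preserved DML, grade C prolonged DML with
#' a preserved SNAP, grade D markedly prolonged DML and, in half of the
#' hands, an absent SNAP. Amplitudes fall and pulse widths broaden with
#' severity (axonal loss and temporal dispersion).
#'
#' @return Named list of [grade_params()] objects, one per grade.
#' @export
default_grade_params <- function() {
  list(
    A = grade_params("A", dml_range = c(3.0, 4.4),
                     sensory_cv_range = c(42, 60), snap_present_prob = 1,
                     sensory_amp_range = c(20, 50),
                     motor_amp_range = c(6, 15), width_scale = 1.0),
    B = grade_params("B", dml_range = c(3.2, 4.4),
                     sensory_cv_range = c(28, 40), snap_present_prob = 1,
                     sensory_amp_range = c(8, 25),
                     motor_amp_range = c(5, 12), width_scale = 1.1),
    C = grade_params("C", dml_range = c(4.5, 6.5),
                     sensory_cv_range = c(24, 36), snap_present_prob = 1,
                     sensory_amp_range = c(4, 12),
                     motor_amp_range = c(3, 9), width_scale = 1.3),
    D = grade_params("D", dml_range = c(6.5, 9.5),
                     sensory_cv_range = c(18, 30), snap_present_prob = 0.5,
                     sensory_amp_range = c(2.5, 6),
                     motor_amp_range = c(1, 6), width_scale = 1.5,
                     dml_range_absent = c(4.5, 9.5))
  )
}

# shrink an interval symmetrically away from its endpoints by a fraction
# `margin` of its width (safety margin from the grading thresholds)
.shrink <- function(r, margin) {
  stopifnot(margin >= 0, margin < 0.5)
  w <- diff(r)
  c(r[1] + margin * w, r[2] - margin * w)
}

.runif_in <- function(r) stats::runif(1, r[1], r[2])

# base pulse-shape constants per modality (widths in ms)
.shape_const <- function(modality) {
  if (modality == "sensory") {
    list(rise = 0.25, fall = 0.35, neg_frac = 0.30, neg_lag = 1.5,
         duration = 20, stimulus_time = 2, probe_peak = 8)
  } else {
    list(rise = 0.80, fall = 1.20, neg_frac = 0.25, neg_lag = 4.5,
         duration = 50, stimulus_time = 5, probe_peak = 12)
  }
}

# Deterministic onset calibration: measure, on the noiseless template, the
# offset between the detector's onset and the nominal take-off
# (peak - 3 * rise_width), so that the generator can place a pulse whose
# *measured* onset latency equals the requested one. Memoised.
.cal_cache <- new.env(parent = emptyenv())

.onset_calibration <- function(rise, fall, modality) {
  key <- sprintf("%s|%.5f|%.5f", modality, rise, fall)
  hit <- .cal_cache[[key]]
  if (!is.null(hit)) return(hit)
  sc <- .shape_const(modality)
  probe <- generate_trace(
    peak_latency = sc$probe_peak, rise_width = rise, fall_width = fall,
    positive_amp = if (modality == "sensory") 20 else 8,
    negative_amp = 0, negative_lag = sc$neg_lag,
    duration = sc$duration, stimulus_time = sc$stimulus_time,
    modality = modality,
    site = if (modality == "sensory") "digit2" else "distal",
    distance = if (modality == "sensory") 140 else 70
  )
  cp <- detect_critical_points(probe)
  detected <- probe$time[cp$onset_idx] - probe$stimulus_time
  delta <- detected - (sc$probe_peak - 3 * rise)
  .cal_cache[[key]] <- delta
  delta
}

# one generated channel; `onset_latency` is the latency the detector will
# measure (up to one sample) on the noiseless trace
.make_channel <- function(info, onset_latency, amp, width_scale,
                          noise_sd, drift_amplitude, drift_period) {
  sc <- .shape_const(info$modality)
  rise <- sc$rise * width_scale
  fall <- sc$fall * width_scale
  delta <- .onset_calibration(rise, fall, info$modality)
  generate_trace(
    peak_latency = onset_latency + 3 * rise - delta,
    rise_width = rise, fall_width = fall,
    positive_amp = amp, negative_amp = sc$neg_frac * amp,
    negative_lag = sc$neg_lag * width_scale,
    noise_sd = noise_sd, drift_amplitude = drift_amplitude,
    drift_period = drift_period,
    duration = sc$duration, stimulus_time = sc$stimulus_time,
    nerve = info$nerve, modality = info$modality, site = info$site,
    distance = info$distance,
    segment_distance = if (is.na(info$segment_distance)) NULL
                       else info$segment_distance
  )
}

#' Generate one synthetic hand
#'
#' Draws the median-channel latency, conduction-velocity and amplitude
#' parameters inside the requested grade's defining region (with a
#' configurable safety margin from each grading threshold) and the ulnar
#' channels from normal distributions for every grade, then synthesises the
#' eight-channel montage. With `noise_scale = 0` and a positive margin,
#' grading the features extracted from the generated traces returns the
#' requested grade.
#'
#' @param grade target neurophysiological grade, `"A"`..`"D"`.
#' @param params named list of [grade_params()]; see
#'   [default_grade_params()].
#' @param seed optional integer for a self-contained reproducible draw.
#' @param noise_scale multiplier on both the additive noise SD and the
#'   baseline-drift amplitude; 0 gives the pure analytic templates.
#' @param margin fraction (0 to < 0.5) by which the grade-defining DML and
#'   CV intervals are shrunk away from the thresholds.
#' @param hand_id opaque label.
#' @return A list of class `ncs_hand` with fields `hand_id`, `traces`
#'   (named list of eight [ncs_trace] objects), `true_grade`,
#'   `clinical_label`, `snap_present`.
#' @export
generate_hand <- function(grade, params = default_grade_params(),
                          seed = NULL, noise_scale = 1, margin = 0.1,
                          hand_id = "hand") {
  stopifnot(grade %in% c("A", "B", "C", "D"))
  if (!is.null(seed)) {
    return(.with_seed(seed, generate_hand(grade, params, NULL, noise_scale,
                                          margin, hand_id)))
  }
  gp <- params[[grade]]
  mont <- channel_montage()
  rownames(mont) <- mont$channel
  ns_s <- gp$noise_sd_sensory * noise_scale
  ns_m <- gp$noise_sd_motor * noise_scale
  dr_s <- gp$drift_amplitude * noise_scale
  dr_m <- 0.1 * gp$drift_amplitude * noise_scale

  snap_present <- stats::runif(1) < gp$snap_present_prob
  dml <- .runif_in(.shrink(if (snap_present) gp$dml_range
                           else gp$dml_range_absent, margin))
  s_cv <- .runif_in(.shrink(gp$sensory_cv_range, margin))
  s_amp <- .runif_in(gp$sensory_amp_range)
  m_amp <- .runif_in(gp$motor_amp_range)
  med_seg_cv <- stats::runif(1, 48, 60)
  wj <- function() stats::runif(1, 0.92, 1.08)   # mild per-trace width jitter

  # ulnar channels are unaffected by CTS: normal values for every grade
  uln_s_cv <- stats::runif(1, 45, 60)
  uln_s_amp <- stats::runif(1, 15, 45)
  uln_dml <- stats::runif(1, 2.2, 3.4)
  uln_m_amp <- stats::runif(1, 6, 14)
  uln_seg_cv <- stats::runif(1, 50, 62)

  ws <- gp$width_scale
  traces <- list()

  # median sensory: absent SNAP -> sub-threshold stump below the 2 uV floor
  s_amp_eff <- if (snap_present) s_amp else stats::runif(1, 0.2, 1.0)
  cv_jitter <- stats::runif(1, 0.95, 1.05)
  traces$median_sensory_digit2 <- .make_channel(
    mont["median_sensory_digit2", ], 140 / s_cv, s_amp_eff,
    ws * wj(), ns_s, dr_s, gp$drift_period)
  traces$median_sensory_digit4 <- .make_channel(
    mont["median_sensory_digit4", ], 140 / (s_cv * cv_jitter),
    if (snap_present) s_amp * stats::runif(1, 0.85, 1.05)
    else stats::runif(1, 0.2, 1.0),
    ws * wj(), ns_s, dr_s, gp$drift_period)
  traces$ulnar_sensory_digit4 <- .make_channel(
    mont["ulnar_sensory_digit4", ], 140 / uln_s_cv, uln_s_amp,
    wj(), ns_s, dr_s, gp$drift_period)
  traces$ulnar_sensory_digit5 <- .make_channel(
    mont["ulnar_sensory_digit5", ], 140 / (uln_s_cv * stats::runif(1, 0.95, 1.05)),
    uln_s_amp * stats::runif(1, 0.85, 1.05), wj(), ns_s, dr_s, gp$drift_period)

  traces$median_motor_distal <- .make_channel(
    mont["median_motor_distal", ], dml, m_amp, ws * wj(), ns_m, dr_m,
    gp$drift_period)
  traces$median_motor_proximal <- .make_channel(
    mont["median_motor_proximal", ], dml + 230 / med_seg_cv,
    m_amp * stats::runif(1, 0.85, 0.98), ws * wj(), ns_m, dr_m,
    gp$drift_period)
  traces$ulnar_motor_distal <- .make_channel(
    mont["ulnar_motor_distal", ], uln_dml, uln_m_amp, wj(), ns_m, dr_m,
    gp$drift_period)
  traces$ulnar_motor_proximal <- .make_channel(
    mont["ulnar_motor_proximal", ], uln_dml + 230 / uln_seg_cv,
    uln_m_amp * stats::runif(1, 0.85, 0.98), wj(), ns_m, dr_m,
    gp$drift_period)

  structure(
    list(hand_id = hand_id, traces = traces, true_grade = grade,
         clinical_label = .grade_to_clinical(grade),
         snap_present = snap_present),
    class = "ncs_hand"
  )
}

.grade_to_clinical <- function(grade) {
  unname(c(A = "control", B = "mild_moderate", C = "mild_moderate",
           D = "severe")[grade])
}

#' @export
print.ncs_hand <- function(x, ...) {
  cat(sprintf("<ncs_hand> %s: grade %s, clinical %s, SNAP %s\n",
              x$hand_id, x$true_grade, x$clinical_label,
              if (x$snap_present) "present" else "absent"))
  invisible(x)
}

#' Generate a synthetic cohort of hands
#'
#' Draws `sizes` hands per grade (defaults 19/10/17/19, the study-design
#' group sizes), assigns the three-level clinical label mapped from the
#' grade (A = control, B/C = mild_moderate, D = severe) and then moves a
#' fraction `disagreement_rate` of hands to a neighbouring clinical label,
#' emulating the imperfect clinic-to-NCS correlation.
#'
#' @param sizes integer vector of length 4 (grades A, B, C, D).
#' @param disagreement_rate fraction in `[0, 1]` of hands whose clinical
#'   label is moved to an adjacent class.
#' @param seed optional integer; identical seeds give bit-identical cohorts.
#' @inheritParams generate_hand
#' @return A list of class `ncs_cohort` of `ncs_hand` records.
#' @export
generate_cohort <- function(sizes = c(A = 19, B = 10, C = 17, D = 19),
                            disagreement_rate = 0, seed = NULL,
                            params = default_grade_params(),
                            noise_scale = 1, margin = 0.1) {
  stopifnot(length(sizes) == 4L, all(sizes >= 0),
            disagreement_rate >= 0, disagreement_rate <= 1)
  if (!is.null(seed)) {
    return(.with_seed(seed, generate_cohort(sizes, disagreement_rate, NULL,
                                            params, noise_scale, margin)))
  }
  grades <- rep(c("A", "B", "C", "D"), times = sizes)
  n <- length(grades)
  hands <- vector("list", n)
  for (i in seq_len(n)) {
    hands[[i]] <- generate_hand(grades[i], params, seed = NULL,
                                noise_scale = noise_scale, margin = margin,
                                hand_id = sprintf("h%03d", i))
  }
  if (disagreement_rate > 0 && n > 0) {
    n_flip <- round(disagreement_rate * n)
    flip <- if (n_flip > 0) sample.int(n, n_flip) else integer(0)
    for (i in flip) {
      lab <- hands[[i]]$clinical_label
      hands[[i]]$clinical_label <- switch(
        lab,
        control = "mild_moderate",
        severe = "mild_moderate",
        mild_moderate = sample(c("control", "severe"), 1)
      )
    }
  }
  structure(hands, class = "ncs_cohort")
}

#' @export
print.ncs_cohort <- function(x, ...) {
  g <- table(factor(vapply(x, `[[`, "", "true_grade"),
                    levels = c("A", "B", "C", "D")))
  cl <- table(factor(vapply(x, `[[`, "", "clinical_label"),
                     levels = c("control", "mild_moderate", "severe")))
  cat(sprintf("<ncs_cohort> %d hands; grades A/B/C/D = %s; clinical = %s\n",
              length(x), paste(g, collapse = "/"),
              paste(cl, collapse = "/")))
  invisible(x)
}

#' Write a cohort to a plain-text directory container
#'
#' One directory per hand holding one tab-delimited file per channel
#' (`time_ms`, `value`) plus a JSON sidecar with the channel metadata, and
#' a top-level `manifest.csv` (`hand_id`, `true_grade`, `clinical_label`,
#' `path`).
#'
#' @param cohort an `ncs_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(
    hand_id = vapply(cohort, `[[`, "", "hand_id"),
    true_grade = vapply(cohort, `[[`, "", "true_grade"),
    clinical_label = vapply(cohort, `[[`, "", "clinical_label"),
    path = vapply(cohort, `[[`, "", "hand_id"),
    stringsAsFactors = FALSE
  )
  for (hand in cohort) {
    hd <- file.path(dir, hand$hand_id)
    dir.create(hd, showWarnings = FALSE)
    for (ch in names(hand$traces)) {
      tr <- hand$traces[[ch]]
      utils::write.table(
        data.frame(time_ms = tr$time, value = tr$samples),
        file.path(hd, paste0(ch, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE
      )
      meta <- list(nerve = tr$nerve, modality = tr$modality, site = tr$site,
                   distance = tr$distance,
                   segment_distance = tr$segment_distance,
                   sample_interval = tr$sample_interval,
                   stimulus_time = tr$stimulus_time)
      jsonlite::write_json(meta, file.path(hd, paste0(ch, ".json")),
                           auto_unbox = TRUE, null = "null", digits = NA)
    }
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `manifest.csv` and one subdirectory per
#'   hand.
#' @return An `ncs_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  hands <- lapply(seq_len(nrow(manifest)), function(i) {
    hd <- file.path(dir, manifest$path[i])
    chans <- sub("\\.tsv$", "", list.files(hd, pattern = "\\.tsv$"))
    traces <- lapply(chans, function(ch) {
      dat <- utils::read.delim(file.path(hd, paste0(ch, ".tsv")))
      meta <- jsonlite::read_json(file.path(hd, paste0(ch, ".json")))
      ncs_trace(dat$value,
                sample_interval = as.numeric(meta$sample_interval),
                stimulus_time = as.numeric(meta$stimulus_time),
                nerve = meta$nerve, modality = meta$modality,
                site = meta$site, distance = as.numeric(meta$distance),
                segment_distance = if (is.null(meta$segment_distance)) NULL
                                   else as.numeric(meta$segment_distance))
    })
    names(traces) <- chans
    structure(
      list(hand_id = manifest$hand_id[i],
           traces = traces[channel_montage()$channel],
           true_grade = manifest$true_grade[i],
           clinical_label = manifest$clinical_label[i],
           snap_present = NA),
      class = "ncs_hand"
    )
  })
  structure(hands, class = "ncs_cohort")
}
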