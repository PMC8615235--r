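.COMMON_FEATURES <- c("H", "Hmax", "Hmaxmin", "Lon", "Lpeak", "Lonpeak",
                      "CV", "A")
.NOVEL_FEATURES <- c(
  "Aeabs", "D", "Dh2",
  "UL", "LL", "UR", "LR", "Left", "Right", "Upper", "Lower",
  "r_Left_Right", "r_Upper_Lower", "r_UL_LL", "r_UR_LR", "r_UL_UR",
  "r_LL_LR", "r_Left_A", "r_Right_A", "r_Upper_A", "r_Lower_A",
  "r_Aeabs_A",
  "tan_left", "tan_right", "fit_left", "fit_right"
)
.DIFF_FEATURES <- c("Lon", "Lpeak", "CV", "H", "A", "D", "Dh2",
                    "tan_left", "tan_right", "Aeabs")
.DIFF_PAIRS <- list(
  diff_sensory_digit4 = c("median_sensory_digit4", "ulnar_sensory_digit4"),
  diff_motor_distal = c("median_motor_distal", "ulnar_motor_distal"),
  diff_motor_proximal = c("median_motor_proximal", "ulnar_motor_proximal")
)

#' The canonical per-trace feature registry
#'
#' Thirty-four named features per trace: eight common clinical measures
#' (onset-to-peak height H, peak height above baseline Hmax, peak-to-trough
#' Hmaxmin, onset/peak/onset-to-peak latencies, conduction velocity, and
#' positive-lobe area A) and twenty-six geometric ones (expanded absolute
#' area, duration, full duration at half maximum, the four half-maximum
#' subareas and their four sums, eleven area ratios, and the two secant and
#' two regression slopes). The eleven ratios keep one ratio per
#' geometrically distinct comparison, which closes the registry at exactly
#' 34 names.
#'
#' @return A data.frame with columns `feature`, `class` (`"common"` /
#'   `"novel"`) and `units`.
#' @export
feature_registry <- function() {
  units <- c(
    H = "amp", Hmax = "amp", Hmaxmin = "amp", Lon = "ms", Lpeak = "ms",
    Lonpeak = "ms", CV = "m/s", A = "amp*ms",
    Aeabs = "amp*ms", D = "ms", Dh2 = "ms",
    UL = "amp*ms", LL = "amp*ms", UR = "amp*ms", LR = "amp*ms",
    Left = "amp*ms", Right = "amp*ms", Upper = "amp*ms", Lower = "amp*ms",
    r_Left_Right = "1", r_Upper_Lower = "1", r_UL_LL = "1", r_UR_LR = "1",
    r_UL_UR = "1", r_LL_LR = "1", r_Left_A = "1", r_Right_A = "1",
    r_Upper_A = "1", r_Lower_A = "1", r_Aeabs_A = "1",
    tan_left = "amp/ms", tan_right = "amp/ms",
    fit_left = "amp/ms", fit_right = "amp/ms"
  )
  feats <- c(.COMMON_FEATURES, .NOVEL_FEATURES)
  data.frame(
    feature = feats,
    class = c(rep("common", length(.COMMON_FEATURES)),
              rep("novel", length(.NOVEL_FEATURES))),
    units = unname(units[feats]),
    stringsAsFactors = FALSE
  )
}

#' The 302-column per-hand feature registry
#'
#' The per-hand vector concatenates the 34 trace features for each of the
#' eight montage channels (channel-major order, 272 columns) and 30
#' median-minus-ulnar difference features: for each homologous channel pair
#' (sensory digit 4, motor distal, motor proximal) the differences of
#' Lon, Lpeak, CV, H, A, D, Dh2, tan_left, tan_right and the expanded
#' absolute area. Difference columns inherit the class of their parent
#' trace feature.
#'
#' @return A data.frame with columns `column`, `channel`, `feature`,
#'   `class`.
#' @export
hand_feature_registry <- function() {
  reg <- feature_registry()
  chans <- channel_montage()$channel
  per_trace <- do.call(rbind, lapply(chans, function(ch) {
    data.frame(column = paste(ch, reg$feature, sep = "."),
               channel = ch, feature = reg$feature, class = reg$class,
               stringsAsFactors = FALSE)
  }))
  cls <- stats::setNames(reg$class, reg$feature)
  diffs <- do.call(rbind, lapply(names(.DIFF_PAIRS), function(p) {
    data.frame(column = paste(p, .DIFF_FEATURES, sep = "."),
               channel = p, feature = .DIFF_FEATURES,
               class = unname(cls[.DIFF_FEATURES]),
               stringsAsFactors = FALSE)
  }))
  rbind(per_trace, diffs)
}

.trapz <- function(t, y) if (length(t) < 2L) 0 else pracma::trapz(t, y)

.guard_ratio <- function(num, den) {
  if (is.na(num) || is.na(den) || abs(den) < 1e-12) NA_real_ else num / den
}

#' Amplitude features of a trace
#'
#' `H` = onset-to-peak height, `Hmax` = peak above baseline, `Hmaxmin` =
#' peak minus trough. All in trace units; all zero for a "no response"
#' trace (absent SNAP).
#'
#' @param trace an [ncs_trace].
#' @param cp its [critical_points()].
#' @return Named numeric vector `H`, `Hmax`, `Hmaxmin`.
#' @export
amplitude_features <- function(trace, cp) {
  if (!cp$response) return(c(H = 0, Hmax = 0, Hmaxmin = 0))
  x <- trace$samples
  c(H = x[cp$peak_idx] - x[cp$onset_idx],
    Hmax = x[cp$peak_idx] - cp$baseline,
    Hmaxmin = x[cp$peak_idx] - x[cp$trough_idx])
}

#' Latency features of a trace
#'
#' Onset latency `Lon`, peak latency `Lpeak` and rise time `Lonpeak`
#' (all ms, measured from the stimulus). Undefined (`NA`) when there is no
#' response.
#'
#' @inheritParams amplitude_features
#' @return Named numeric vector `Lon`, `Lpeak`, `Lonpeak`.
#' @export
latency_features <- function(trace, cp) {
  if (!cp$response) return(c(Lon = NA_real_, Lpeak = NA_real_,
                             Lonpeak = NA_real_))
  lon <- trace$time[cp$onset_idx] - trace$stimulus_time
  lpk <- trace$time[cp$peak_idx] - trace$stimulus_time
  c(Lon = lon, Lpeak = lpk, Lonpeak = lpk - lon)
}

#' Conduction velocity of a trace
#'
#' Sensory and motor-distal CV = distance / onset latency; the motor
#' segment CV (assigned to the proximal trace) = segment distance /
#' (proximal minus distal onset latency). mm/ms equals m/s, so no unit
#' conversion is needed. Nonpositive latency (difference) or a missing
#' response gives `NA`.
#'
#' @inheritParams amplitude_features
#' @param distal_onset_ms onset latency of the paired distal motor trace
#'   (required for proximal motor traces).
#' @return CV in m/s, or `NA`.
#' @export
conduction_velocity <- function(trace, cp, distal_onset_ms = NULL) {
  if (!cp$response) return(NA_real_)
  lon <- trace$time[cp$onset_idx] - trace$stimulus_time
  if (trace$modality == "motor" && trace$site == "proximal") {
    if (is.null(distal_onset_ms) || is.na(distal_onset_ms)) return(NA_real_)
    if (is.null(trace$segment_distance)) return(NA_real_)
    dl <- lon - distal_onset_ms
    if (dl <= 0) return(NA_real_)
    return(trace$segment_distance / dl)
  }
  if (lon <= 0) return(NA_real_)
  trace$distance / lon
}

#' Area features and their ratios
#'
#' `A` is the trapezoidal integral of the positive deviation from baseline
#' between onset and offset, `Aeabs` the integral of the absolute
#' deviation (positive plus repolarization lobe). The positive lobe is
#' partitioned by the horizontal half-maximum line (baseline + Hmax / 2)
#' and the vertical through the peak into `UL`, `LL`, `UR`, `LR`, summed
#' into `Left`, `Right`, `Upper`, `Lower`; the partition conserves `A`
#' exactly up to floating point. Eleven guarded ratios complete the set;
#' a denominator below 1e-12 yields `NA`.
#'
#' @inheritParams amplitude_features
#' @return Named numeric vector of the 20 area features.
#' @export
area_features <- function(trace, cp) {
  nm <- c("A", "Aeabs", "UL", "LL", "UR", "LR", "Left", "Right",
          "Upper", "Lower",
          "r_Left_Right", "r_Upper_Lower", "r_UL_LL", "r_UR_LR",
          "r_UL_UR", "r_LL_LR", "r_Left_A", "r_Right_A", "r_Upper_A",
          "r_Lower_A", "r_Aeabs_A")
  if (!cp$response) {
    out <- stats::setNames(rep(0, length(nm)), nm)
    out[grepl("^r_", nm)] <- NA_real_
    return(out)
  }
  t <- trace$time
  x <- trace$samples
  b <- cp$baseline
  seg <- cp$onset_idx:cp$offset_idx
  left <- cp$onset_idx:cp$peak_idx
  right <- cp$peak_idx:cp$offset_idx
  y <- x - b
  half <- (x[cp$peak_idx] - b) / 2
  pos <- function(idx) .trapz(t[idx], pmax(y[idx], 0))
  upp <- function(idx) .trapz(t[idx], pmax(y[idx] - half, 0))
  low <- function(idx) .trapz(t[idx], pmax(pmin(y[idx], half), 0))

  A <- pos(seg)
  Aeabs <- .trapz(t[seg], abs(y[seg]))
  UL <- upp(left); UR <- upp(right)
  LL <- low(left); LR <- low(right)
  Left <- pos(left); Right <- pos(right)
  Upper <- UL + UR; Lower <- LL + LR
  c(A = A, Aeabs = Aeabs, UL = UL, LL = LL, UR = UR, LR = LR,
    Left = Left, Right = Right, Upper = Upper, Lower = Lower,
    r_Left_Right = .guard_ratio(Left, Right),
    r_Upper_Lower = .guard_ratio(Upper, Lower),
    r_UL_LL = .guard_ratio(UL, LL), r_UR_LR = .guard_ratio(UR, LR),
    r_UL_UR = .guard_ratio(UL, UR), r_LL_LR = .guard_ratio(LL, LR),
    r_Left_A = .guard_ratio(Left, A), r_Right_A = .guard_ratio(Right, A),
    r_Upper_A = .guard_ratio(Upper, A), r_Lower_A = .guard_ratio(Lower, A),
    r_Aeabs_A = .guard_ratio(Aeabs, A))
}

#' Duration features
#'
#' `D` = offset minus onset time; `Dh2` = full duration at half maximum,
#' from the linearly interpolated crossings of baseline + Hmax / 2 nearest
#' the peak on each side. A truncated wave whose half-maximum level is
#' never crossed on one side gives `Dh2 = NA`.
#'
#' @inheritParams amplitude_features
#' @return Named numeric vector `D`, `Dh2` (ms).
#' @export
duration_features <- function(trace, cp) {
  if (!cp$response) return(c(D = NA_real_, Dh2 = NA_real_))
  t <- trace$time
  x <- trace$samples
  level <- cp$baseline + (x[cp$peak_idx] - cp$baseline) / 2
  D <- t[cp$offset_idx] - t[cp$onset_idx]

  cross_left <- NA_real_
  for (i in seq.int(cp$peak_idx, cp$onset_idx)) {
    if (x[i] < level) {
      cross_left <- t[i] + (t[i + 1L] - t[i]) *
        (level - x[i]) / (x[i + 1L] - x[i])
      break
    }
  }
  cross_right <- NA_real_
  if (cp$peak_idx < cp$offset_idx) {
    for (i in seq.int(cp$peak_idx, cp$offset_idx)) {
      if (x[i] < level) {
        cross_right <- t[i - 1L] + (t[i] - t[i - 1L]) *
          (level - x[i - 1L]) / (x[i] - x[i - 1L])
        break
      }
    }
  }
  c(D = D, Dh2 = cross_right - cross_left)
}

#' Secant and regression slopes
#'
#' `tan_left` = (f(peak) - f(onset)) / (t(peak) - t(onset)) and
#' `tan_right` = (f(offset) - f(peak)) / (t(offset) - t(peak)), the secant
#' slopes of the two flanks; `fit_left` / `fit_right` are the least-squares
#' regression slopes over all samples of each flank, which makes them
#' robust to small onset/offset placement errors. Units: trace units
#' per ms.
#'
#' @inheritParams amplitude_features
#' @return Named numeric vector `tan_left`, `tan_right`, `fit_left`,
#'   `fit_right`.
#' @export
slope_features <- function(trace, cp) {
  if (!cp$response) return(c(tan_left = NA_real_, tan_right = NA_real_,
                             fit_left = NA_real_, fit_right = NA_real_))
  t <- trace$time
  x <- trace$samples
  secant <- function(i, j) {
    if (j <= i) return(NA_real_)
    (x[j] - x[i]) / (t[j] - t[i])
  }
  ols <- function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    tm <- t[idx] - mean(t[idx])
    sum(tm * (x[idx] - mean(x[idx]))) / sum(tm^2)
  }
  c(tan_left = secant(cp$onset_idx, cp$peak_idx),
    tan_right = secant(cp$peak_idx, cp$offset_idx),
    fit_left = ols(cp$onset_idx:cp$peak_idx),
    fit_right = ols(cp$peak_idx:cp$offset_idx))
}

#' All 34 features of one trace
#'
#' Composes the amplitude, latency, conduction-velocity, area, duration and
#' slope feature groups in the canonical registry order.
#'
#' @inheritParams conduction_velocity
#' @return Named numeric vector of length 34 (see [feature_registry()]).
#' @export
trace_features <- function(trace, cp, distal_onset_ms = NULL) {
  amp <- amplitude_features(trace, cp)
  lat <- latency_features(trace, cp)
  cv <- conduction_velocity(trace, cp, distal_onset_ms)
  ar <- area_features(trace, cp)
  du <- duration_features(trace, cp)
  sl <- slope_features(trace, cp)
  out <- c(amp["H"], amp["Hmax"], amp["Hmaxmin"],
           lat["Lon"], lat["Lpeak"], lat["Lonpeak"],
           CV = unname(cv), ar["A"],
           ar["Aeabs"], du["D"], du["Dh2"],
           ar["UL"], ar["LL"], ar["UR"], ar["LR"],
           ar["Left"], ar["Right"], ar["Upper"], ar["Lower"],
           ar["r_Left_Right"], ar["r_Upper_Lower"], ar["r_UL_LL"],
           ar["r_UR_LR"], ar["r_UL_UR"], ar["r_LL_LR"], ar["r_Left_A"],
           ar["r_Right_A"], ar["r_Upper_A"], ar["r_Lower_A"],
           ar["r_Aeabs_A"],
           sl["tan_left"], sl["tan_right"], sl["fit_left"], sl["fit_right"])
  stats::setNames(out, c(.COMMON_FEATURES, .NOVEL_FEATURES))
}

#' The 302-entry feature vector of one hand
#'
#' Detrends every channel, detects its critical points, computes the 34
#' trace features per channel (272 entries, channel-major order) and
#' appends the 30 median-minus-ulnar difference features. Missing values
#' (absent responses, truncated waves, degenerate ratios) propagate as
#' `NA`.
#'
#' @param hand an `ncs_hand` record with all eight montage channels.
#' @param ... passed on to [detect_critical_points()].
#' @return Named numeric vector of length 302, with attributes
#'   `snap_present` (median digit-2 SNAP detectable), `dml_ms` (median
#'   motor distal onset latency) and `sensory_cv` (median digit-2 sensory
#'   CV).
#' @export
hand_features <- function(hand, ...) {
  chans <- channel_montage()$channel
  missing <- setdiff(chans, names(hand$traces))
  if (length(missing)) {
    stop("hand record is missing channel(s): ", paste(missing, collapse = ", "))
  }
  cps <- list()
  traces <- list()
  for (ch in chans) {
    traces[[ch]] <- detrend_trace(hand$traces[[ch]])
    cps[[ch]] <- detect_critical_points(traces[[ch]], ...)
  }
  onset_ms <- function(ch) {
    cp <- cps[[ch]]
    if (!cp$response) return(NA_real_)
    traces[[ch]]$time[cp$onset_idx] - traces[[ch]]$stimulus_time
  }
  per <- lapply(chans, function(ch) {
    dist_lon <- if (ch == "median_motor_proximal") onset_ms("median_motor_distal")
                else if (ch == "ulnar_motor_proximal") onset_ms("ulnar_motor_distal")
                else NULL
    trace_features(traces[[ch]], cps[[ch]], distal_onset_ms = dist_lon)
  })
  names(per) <- chans
  flat <- unlist(lapply(chans, function(ch) {
    stats::setNames(per[[ch]], paste(ch, names(per[[ch]]), sep = "."))
  }))
  diffs <- unlist(lapply(names(.DIFF_PAIRS), function(p) {
    pair <- .DIFF_PAIRS[[p]]
    stats::setNames(per[[pair[1]]][.DIFF_FEATURES] -
                      per[[pair[2]]][.DIFF_FEATURES],
                    paste(p, .DIFF_FEATURES, sep = "."))
  }))
  out <- c(flat, diffs)
  attr(out, "snap_present") <- cps[["median_sensory_digit2"]]$response
  attr(out, "dml_ms") <- onset_ms("median_motor_distal")
  attr(out, "sensory_cv") <-
    per[["median_sensory_digit2"]][["CV"]]
  out
}

#' Feature table of a whole cohort
#'
#' @param cohort an `ncs_cohort`.
#' @param ... passed on to [detect_critical_points()].
#' @return A data.frame with `hand_id`, `true_grade`, `clinical_label`,
#'   `snap_present`, `dml_ms`, `sensory_cv` and the 302 feature columns of
#'   [hand_feature_registry()].
#' @export
extract_features <- function(cohort, ...) {
  rows <- lapply(cohort, function(hand) {
    fv <- hand_features(hand, ...)
    meta <- data.frame(hand_id = hand$hand_id,
                       true_grade = hand$true_grade,
                       clinical_label = hand$clinical_label,
                       snap_present = attr(fv, "snap_present"),
                       dml_ms = attr(fv, "dml_ms"),
                       sensory_cv = attr(fv, "sensory_cv"),
                       stringsAsFactors = FALSE)
    cbind(meta, as.data.frame(as.list(fv), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature columns of a feature table
#'
#' @param features a data.frame from [extract_features()].
#' @param set `"all"`, `"common"` or `"novel"`.
#' @return Character vector of column names.
#' @export
feature_columns <- function(features, set = c("all", "common", "novel")) {
  set <- match.arg(set)
  reg <- hand_feature_registry()
  cols <- if (set == "all") reg$column else reg$column[reg$class == set]
  intersect(cols, names(features))
}
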