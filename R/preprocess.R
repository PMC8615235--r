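#' Moving-average smoothing
#'
#' Centred moving average with shrinking windows at the edges, so the output
#' has the same length as the input. Used to suppress high-frequency noise
#' before critical-point detection; sensory traces are noisier than motor
#' ones and get a wider default window elsewhere in the package.
#'
#' @param trace an [ncs_trace] or a plain numeric vector.
#' @param window_samples odd window length in samples, >= 1 and shorter than
#'   the trace.
#' @return Same type as the input, with smoothed samples.
#' @export
smooth_trace <- function(trace, window_samples) {
  x <- if (inherits(trace, "ncs_trace")) trace$samples else as.numeric(trace)
  n <- length(x)
  w <- as.integer(window_samples)
  if (length(w) != 1L || is.na(w) || w < 1L || w %% 2L == 0L) {
    stop("`window_samples` must be a single odd integer >= 1")
  }
  if (w >= n) stop("smoothing window must be shorter than the trace")
  if (w == 1L) {
    sm <- x
  } else {
    h <- (w - 1L) %/% 2L
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  if (inherits(trace, "ncs_trace")) {
    trace$samples <- sm
    trace
  } else {
    sm
  }
}

#' Remove isoelectric-line drift
#'
#' Estimates the slow drift of the isoelectric line as the least-squares
#' line fitted to the baseline regions of the sweep (the pre-stimulus
#' segment and the final tenth of the trace, where no response is present),
#' subtracts it, and re-zeroes the result to a zero pre-stimulus mean.
#' A pure linear ramp is annihilated to numerical zero.
#'
#' @param trace an [ncs_trace]; its pre-stimulus segment must hold at least
#'   16 samples.
#' @return The detrended [ncs_trace].
#' @export
detrend_trace <- function(trace) {
  stopifnot(inherits(trace, "ncs_trace"))
  pre <- .prestim_idx(trace)
  if (length(pre) < 16L) {
    stop("detrending needs a pre-stimulus segment of at least 16 samples")
  }
  n <- length(trace$samples)
  tail_idx <- seq.int(from = n - max(16L, n %/% 10L) + 1L, to = n)
  idx <- union(pre, tail_idx)
  fit <- stats::lm.fit(cbind(1, trace$time[idx]), trace$samples[idx])
  line <- fit$coefficients[1] + fit$coefficients[2] * trace$time
  y <- trace$samples - line
  trace$samples <- y - mean(y[pre])
  trace
}

#' Construct a critical-points object
#'
#' Holds the detected onset, peak, trough and offset sample positions of one
#' trace, plus the baseline reference voltage. Mostly produced by
#' [detect_critical_points()]; the constructor is exported so features can
#' be computed on analytically known pulses.
#'
#' @param onset_idx,peak_idx,trough_idx,offset_idx sample indices (1-based)
#'   into the original trace, ordered onset < peak < trough <= offset
#'   (for monophasic waves trough may equal peak + 1 and offset).
#' @param baseline reference voltage in trace units.
#' @param response logical; `FALSE` marks a "no response" trace (absent
#'   SNAP), in which case the indices may be `NA`.
#' @param baseline_sd standard deviation of the pre-stimulus segment.
#' @return An object of class `ncs_cpoints`.
#' @export
critical_points <- function(onset_idx, peak_idx, trough_idx, offset_idx,
                            baseline = 0, response = TRUE, baseline_sd = 0) {
  if (response) {
    if (!(onset_idx < peak_idx && peak_idx < trough_idx &&
          trough_idx <= offset_idx)) {
      stop("critical points must be ordered onset < peak < trough <= offset")
    }
  }
  structure(
    list(onset_idx = onset_idx, peak_idx = peak_idx,
         trough_idx = trough_idx, offset_idx = offset_idx,
         baseline = baseline, baseline_sd = baseline_sd,
         response = response),
    class = "ncs_cpoints"
  )
}

#' @export
print.ncs_cpoints <- function(x, ...) {
  if (!x$response) {
    cat("<ncs_cpoints> no response (absent potential)\n")
  } else {
    cat(sprintf(
      "<ncs_cpoints> onset %d, peak %d, trough %d, offset %d; baseline %.4g\n",
      x$onset_idx, x$peak_idx, x$trough_idx, x$offset_idx, x$baseline
    ))
  }
  invisible(x)
}

# One-sided least-squares slope of y ending (trailing) or starting
# (leading) at index i, over h further samples, clipped to range. Fitting
# on the raw series over a one-sided span keeps the estimate local to the
# flank being scanned while averaging i.i.d. noise at the n^(3/2) rate.
.local_slope <- function(t, y, i, h, forward = FALSE) {
  if (forward) {
    lo <- i
    hi <- min(length(y), i + h)
  } else {
    lo <- max(1L, i - h)
    hi <- i
  }
  if (hi <= lo) return(0)
  tt <- t[lo:hi]
  yy <- y[lo:hi]
  tm <- tt - mean(tt)
  sum(tm * (yy - mean(yy))) / sum(tm^2)
}

#' Detect onset, peak, trough and offset of an evoked potential
#'
#' Detection runs on the smoothed signal and the peak and trough are then
#' projected back onto the original one (extremum within half a window of
#' the smoothed position); onset and offset keep their smoothed positions.
#' The peak is the maximum of the post-stimulus smoothed samples and the
#' trough the minimum after the peak. Starting from the peak and moving
#' backward, the onset is placed where the local slope (least-squares fit
#' over a short span) falls below `slope_threshold` times the secant slope
#' from that sample to the peak — a relative rule, one common constant for
#' all signals, which makes the detected indices invariant to amplitude
#' scaling. The offset is found by the symmetric forward scan from the
#' trough, once the signal has recovered at least halfway back to baseline;
#' the scan is capped at three rise durations beyond the trough.
#'
#' If no post-stimulus sample exceeds the detection floor
#' (`min_amplitude` above baseline, or 3 pre-stimulus SDs if larger) the
#' result is a "no response" object, used for absent SNAPs, not an error.
#'
#' @param trace an [ncs_trace] (detrend first if the sweep drifts).
#' @param smooth_window odd moving-average window in samples; default 11
#'   for sensory and 5 for motor traces.
#' @param slope_threshold relative slope threshold; default 0.05.
#' @param min_amplitude detection floor above baseline in trace units;
#'   default 2 (uV) for sensory and 0.5 (mV) for motor traces.
#' @param blank_ms dead time after the stimulus excluded from the search
#'   (stimulus artifact), in ms.
#' @param max_offset_factor cap of the offset scan: at most this multiple
#'   of the onset-to-peak duration beyond the trough.
#' @return An `ncs_cpoints` object (see [critical_points()]).
#' @export
detect_critical_points <- function(trace, smooth_window = NULL,
                                   slope_threshold = 0.05,
                                   min_amplitude = NULL, blank_ms = 0.5,
                                   max_offset_factor = 3) {
  stopifnot(inherits(trace, "ncs_trace"))
  if (is.null(smooth_window)) {
    smooth_window <- if (trace$modality == "sensory") 11L else 5L
  }
  if (is.null(min_amplitude)) {
    min_amplitude <- if (trace$modality == "sensory") 2 else 0.5
  }
  x <- trace$samples
  t <- trace$time
  n <- length(x)
  pre <- .prestim_idx(trace)
  baseline <- if (length(pre)) mean(x[pre]) else 0
  baseline_sd <- if (length(pre) > 1L) stats::sd(x[pre]) else 0

  s <- smooth_trace(x, smooth_window)
  post0 <- which(t >= trace$stimulus_time + blank_ms)[1]
  if (is.na(post0)) stop("no samples after the stimulus blanking period")

  floor_amp <- max(min_amplitude, 3 * baseline_sd)
  if (max(s[post0:n]) - baseline < floor_amp) {
    return(critical_points(NA_integer_, NA_integer_, NA_integer_,
                           NA_integer_, baseline, response = FALSE,
                           baseline_sd = baseline_sd))
  }

  peak_s <- post0 - 1L + which.max(s[post0:n])
  if (peak_s >= n) peak_s <- n - 1L
  trough_s <- peak_s + which.min(s[(peak_s + 1L):n])

  # Span of the one-sided local-slope fit on the raw series, tied to the
  # smoothing window. An OLS slope over n i.i.d.-noise samples has sd
  # sigma * sqrt(12 / (n^3 dt^2)), so the 4x-window span keeps the slope
  # estimate stable at the noise levels the window itself is sized for,
  # and the same span is used at every noise level so that detections on
  # noisy and clean copies of a trace agree.
  h <- max(4L, 4L * smooth_window)
  # baseline-crossing guard: smoothed baseline noise level
  bl_eps <- 3 * baseline_sd / sqrt(smooth_window)

  # --- onset: backward scan from the peak ---------------------------------
  onset_s <- post0
  peak_amp <- s[peak_s] - baseline
  run <- 0L
  found <- FALSE
  if (peak_s - 1L >= post0) {
    for (i in seq.int(peak_s - 1L, post0)) {
      if (s[i] <= baseline - bl_eps) { onset_s <- i; found <- TRUE; break }
      if (s[i] - baseline > 0.6 * peak_amp) { run <- 0L; next }
      secant <- (s[peak_s] - s[i]) / (t[peak_s] - t[i])
      if (secant <= 0) { run <- 0L; next }
      if (.local_slope(t, x, i, h, forward = FALSE) <
            slope_threshold * secant) {
        run <- run + 1L
        if (run >= 2L || i == post0) { onset_s <- i + run - 1L; found <- TRUE; break }
      } else {
        run <- 0L
      }
    }
  }
  if (!found) onset_s <- post0

  # --- offset: forward scan from the trough -------------------------------
  rise_dur <- t[peak_s] - t[onset_s]
  cap <- min(n, trough_s +
               max(3L, as.integer(round(max_offset_factor * rise_dur /
                                          trace$sample_interval))))
  ref_slope <- (s[peak_s] - s[trough_s]) / (t[trough_s] - t[peak_s])
  trough_depth <- baseline - s[trough_s]   # > 0 for a genuine negative lobe
  offset_s <- cap
  run <- 0L
  if (trough_s + 1L <= cap) {
    for (i in seq.int(trough_s + 1L, cap)) {
      recovered <- trough_depth <= 0 ||
        (s[i] - s[trough_s]) >= 0.5 * trough_depth
      if (s[i] >= baseline + bl_eps && recovered) { offset_s <- i; break }
      if (recovered &&
          abs(.local_slope(t, x, i, h, forward = TRUE)) <
            slope_threshold * ref_slope) {
        run <- run + 1L
        if (run >= 2L) { offset_s <- i - run + 1L; break }
      } else {
        run <- 0L
      }
    }
  } else {
    offset_s <- trough_s
  }

  # --- project peak/trough back onto the raw trace ------------------------
  hw <- (smooth_window - 1L) %/% 2L
  pk_lo <- max(onset_s + 1L, peak_s - hw)
  pk_hi <- min(trough_s - 1L, peak_s + hw)
  if (pk_hi < pk_lo) { pk_lo <- peak_s; pk_hi <- peak_s }
  peak_r <- pk_lo - 1L + which.max(x[pk_lo:pk_hi])
  tr_lo <- max(peak_r + 1L, trough_s - hw)
  tr_hi <- min(offset_s, trough_s + hw)
  if (tr_hi < tr_lo) { tr_lo <- min(peak_r + 1L, n); tr_hi <- tr_lo }
  trough_r <- tr_lo - 1L + which.min(x[tr_lo:tr_hi])
  offset_f <- max(offset_s, trough_r)

  critical_points(onset_s, peak_r, trough_r, offset_f,
                  baseline = baseline, baseline_sd = baseline_sd)
}

#' Annotate every channel of a cohort with its critical points
#'
#' Runs [detrend_trace()] and [detect_critical_points()] on all eight
#' channels of each hand and returns a long-format table, one row per
#' channel, with latencies in ms relative to the stimulus.
#'
#' @param cohort a list of hand records from [generate_cohort()] or
#'   [read_cohort()].
#' @param ... passed on to [detect_critical_points()].
#' @return A data.frame with columns `hand_id`, `channel`, `response`,
#'   `onset_ms`, `peak_ms`, `trough_ms`, `offset_ms`, `baseline`.
#' @export
annotate_cohort <- function(cohort, ...) {
  rows <- lapply(cohort, function(hand) {
    chans <- lapply(names(hand$traces), function(ch) {
      tr <- detrend_trace(hand$traces[[ch]])
      cp <- detect_critical_points(tr, ...)
      lat <- function(i) if (cp$response) tr$time[i] - tr$stimulus_time else NA_real_
      data.frame(hand_id = hand$hand_id, channel = ch,
                 response = cp$response,
                 onset_ms = lat(cp$onset_idx), peak_ms = lat(cp$peak_idx),
                 trough_ms = lat(cp$trough_idx),
                 offset_ms = lat(cp$offset_idx),
                 baseline = cp$baseline,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, chans)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
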