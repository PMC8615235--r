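#' Construct a nerve conduction trace object
#'
#' A trace is one sampled evoked-potential channel: a sensory nerve action
#' potential (SNAP, microvolts) or a compound muscle action potential
#' (CMAP, millivolts), together with the stimulus time and the anatomical
#' metadata needed for latency and conduction-velocity measurements.
#' The package-wide polarity convention is positive lobe up.
#'
#' @param samples numeric vector of sampled voltages (uV for sensory,
#'   mV for motor); length must be at least 64.
#' @param sample_interval time per sample in ms; must be positive.
#' @param stimulus_time stimulation time in ms on the sweep time axis;
#'   defines t = 0 of all latency measurements.
#' @param nerve `"median"` or `"ulnar"`.
#' @param modality `"sensory"` or `"motor"`.
#' @param site recording/stimulation site: one of `"digit2"`, `"digit4"`,
#'   `"digit5"`, `"distal"`, `"proximal"`.
#' @param distance stimulus-to-recording distance in mm; must be positive.
#' @param segment_distance distal-proximal inter-stimulus distance in mm
#'   (motor proximal traces only), or `NULL`.
#' @return An object of class `ncs_trace`: a list with the fields above plus
#'   `time` (sample times in ms, starting at 0).
#' @export
ncs_trace <- function(samples, sample_interval, stimulus_time,
                      nerve = c("median", "ulnar"),
                      modality = c("sensory", "motor"),
                      site = c("digit2", "digit4", "digit5", "distal", "proximal"),
                      distance = 140, segment_distance = NULL) {
  nerve <- match.arg(nerve)
  modality <- match.arg(modality)
  site <- match.arg(site)
  samples <- as.numeric(samples)
  if (!is.numeric(sample_interval) || length(sample_interval) != 1L ||
      sample_interval <= 0) {
    stop("`sample_interval` must be a single positive number (ms)")
  }
  if (length(samples) < 64L) {
    stop("a trace needs at least 64 samples")
  }
  if (!is.numeric(distance) || distance <= 0) {
    stop("`distance` must be positive (mm)")
  }
  if (stimulus_time < 0 || stimulus_time >= length(samples) * sample_interval) {
    stop("`stimulus_time` must fall inside the sweep")
  }
  structure(
    list(
      samples = samples,
      time = seq_along(samples) * sample_interval - sample_interval,
      sample_interval = sample_interval,
      stimulus_time = stimulus_time,
      nerve = nerve,
      modality = modality,
      site = site,
      distance = distance,
      segment_distance = segment_distance
    ),
    class = "ncs_trace"
  )
}

#' @export
print.ncs_trace <- function(x, ...) {
  unit <- if (x$modality == "sensory") "uV" else "mV"
  cat(sprintf(
    "<ncs_trace> %s %s %s: %d samples @ %.3f ms, stimulus at %.2f ms, %g mm\n",
    x$nerve, x$modality, x$site, length(x$samples), x$sample_interval,
    x$stimulus_time, x$distance
  ))
  cat(sprintf("  range [%.3g, %.3g] %s\n",
              min(x$samples), max(x$samples), unit))
  invisible(x)
}

#' @export
plot.ncs_trace <- function(x, ...) {
  unit <- if (x$modality == "sensory") "uV" else "mV"
  graphics::plot(x$time, x$samples, type = "l",
                 xlab = "time (ms)", ylab = paste0("amplitude (", unit, ")"),
                 main = paste(x$nerve, x$modality, x$site), ...)
  graphics::abline(v = x$stimulus_time, lty = 2, col = "grey50")
  invisible(x)
}

# Biphasic pulse template: an asymmetric Gaussian positive lobe minus a
# delayed, broader asymmetric Gaussian negative lobe (repolarization).
# Times in ms on the sweep axis; peak_time is the positive-lobe apex.
.pulse_template <- function(t, peak_time, rise_width, fall_width,
                            positive_amp, negative_amp, negative_lag) {
  sd_pos <- ifelse(t < peak_time, rise_width, fall_width)
  pos <- positive_amp * exp(-(t - peak_time)^2 / (2 * sd_pos^2))
  if (negative_amp > 0) {
    neg_time <- peak_time + negative_lag
    sd_neg <- ifelse(t < neg_time, fall_width, 1.5 * fall_width)
    neg <- negative_amp * exp(-(t - neg_time)^2 / (2 * sd_neg^2))
  } else {
    neg <- 0
  }
  pos - neg
}

#' Generate a synthetic evoked-potential trace
#'
#' Builds one SNAP- or CMAP-like waveform as an analytic biphasic template
#' (positive lobe minus delayed negative lobe, each an asymmetric Gaussian),
#' plus optional sinusoidal isoelectric-line drift and i.i.d. Gaussian noise.
#' With `noise_sd = 0` and `drift_amplitude = 0` the returned samples are the
#' analytic template exactly, which makes the generator usable as an oracle
#' for the detection and feature-extraction stages.
#'
#' @param peak_latency positive-lobe apex time in ms after the stimulus.
#' @param rise_width,fall_width Gaussian widths (ms) of the rising and
#'   falling flank of the positive lobe; both must be positive.
#' @param positive_amp positive-lobe amplitude (trace units); must be > 0.
#' @param negative_amp negative-lobe amplitude (>= 0); the negative lobe is
#'   centred `negative_lag` ms after the peak.
#' @param negative_lag delay of the negative lobe apex after the positive
#'   peak, in ms.
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (trace units).
#' @param drift_amplitude,drift_period amplitude (trace units) and period
#'   (ms) of a sinusoidal baseline drift; `drift_amplitude = 0` disables it.
#' @param sample_interval sampling step in ms (default 0.05 ms, i.e. 20 kHz).
#' @param duration sweep length in ms; must cover
#'   `stimulus_time + peak_latency + 5 * fall_width`.
#' @param stimulus_time stimulus position on the sweep (ms); the samples
#'   before it are the pre-stimulus baseline segment.
#' @param seed optional integer; when given, the noise is drawn from a local
#'   RNG stream so repeated calls are byte-identical.
#' @inheritParams ncs_trace
#' @return An [ncs_trace] object.
#' @export
generate_trace <- function(peak_latency, rise_width, fall_width, positive_amp,
                           negative_amp = 0, negative_lag = 1.5,
                           noise_sd = 0, drift_amplitude = 0,
                           drift_period = 100,
                           sample_interval = 0.05, duration = 20,
                           stimulus_time = 2,
                           nerve = "median", modality = "sensory",
                           site = "digit2", distance = 140,
                           segment_distance = NULL, seed = NULL) {
  if (rise_width <= 0 || fall_width <= 0 || positive_amp <= 0 ||
      negative_amp < 0 || negative_lag <= 0) {
    stop("pulse widths, lag and positive amplitude must be > 0; negative amplitude >= 0")
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (stimulus_time + peak_latency + 5 * fall_width > duration) {
    stop("`duration` too short: it must cover peak_latency + 5 * fall_width ",
         "after the stimulus")
  }
  t <- seq(0, duration, by = sample_interval)
  y <- .pulse_template(t, stimulus_time + peak_latency, rise_width,
                       fall_width, positive_amp, negative_amp, negative_lag)
  if (drift_amplitude != 0) {
    y <- y + drift_amplitude * sin(2 * pi * t / drift_period)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      y <- y + .with_seed(seed, stats::rnorm(length(t), sd = noise_sd))
    } else {
      y <- y + stats::rnorm(length(t), sd = noise_sd)
    }
  }
  ncs_trace(y, sample_interval, stimulus_time, nerve, modality, site,
            distance, segment_distance)
}

# Evaluate a local RNG stream without disturbing the caller's .Random.seed.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Indices of the pre-stimulus baseline segment of a trace.
.prestim_idx <- function(trace) {
  which(trace$time < trace$stimulus_time)
}
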