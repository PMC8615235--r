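# Analytic fixture pulses built in code: traces whose critical points and
# geometric features have closed forms.

# symmetric triangle: baseline 0, onset/peak/offset at fixed times (ms
# after stimulus), sampled at `dt`
triangle_trace <- function(onset = 2, peak = 4, offset = 6, height = 10,
                           trough_depth = 0, dt = 0.05, stimulus = 2,
                           duration = 20, modality = "sensory") {
  t <- seq(0, duration, by = dt)
  tt <- t - stimulus
  y <- ifelse(tt > onset & tt <= peak,
              height * (tt - onset) / (peak - onset),
              ifelse(tt > peak & tt < offset,
                     height * (offset - tt) / (offset - peak), 0))
  if (trough_depth > 0) {
    # short dip right after the offset
    y <- y - ifelse(tt >= offset & tt < offset + 1,
                    trough_depth * sin(pi * (tt - offset)), 0)
  }
  ncs_trace(y, dt, stimulus, modality = modality,
            site = if (modality == "sensory") "digit2" else "distal",
            distance = if (modality == "sensory") 140 else 70)
}

# indices of the exact critical points of a triangle_trace
triangle_cp <- function(trace, onset = 2, peak = 4, offset = 6) {
  idx <- function(ms) which.min(abs(trace$time - (trace$stimulus_time + ms)))
  tr <- idx(offset) + 1L
  critical_points(idx(onset), idx(peak), max(tr, idx(peak) + 1L),
                  max(idx(offset), tr), baseline = 0)
}

rect_trace <- function(start = 3, width = 3, height = 10, dt = 0.05,
                       stimulus = 2, duration = 20) {
  t <- seq(0, duration, by = dt)
  tt <- t - stimulus
  y <- ifelse(tt >= start & tt <= start + width, height, 0)
  ncs_trace(y, dt, stimulus)
}

gauss_trace <- function(center = 6, sd = 0.5, height = 10, dt = 0.05,
                        stimulus = 2, duration = 20) {
  t <- seq(0, duration, by = dt)
  y <- height * exp(-(t - stimulus - center)^2 / (2 * sd^2))
  ncs_trace(y, dt, stimulus)
}

# separable two-class table: three informative columns with a wide margin
# plus two pure-noise columns
sep_table <- function(n = 40, offset = 4, sd_inf = 0.5, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), each = n / 2))
  mu <- ifelse(y == "A", 0, offset)
  X <- cbind(f1 = rnorm(n, mu, sd_inf), f2 = rnorm(n, mu, sd_inf),
             f3 = rnorm(n, mu, sd_inf), n1 = rnorm(n), n2 = rnorm(n))
  list(X = X, y = y)
}
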