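#' Construct a breathing trace
#'
#' A breathing trace is a time-sampled sequence of scaled platform
#' displacements using the motion-platform encoding: values lie in `[0, 2]`
#' where 0, 1 and 2 are the minimum, home (middle) and maximum vertical
#' positions. Each sample advances time by `sample_interval_s` (30 ms by
#' default). The physical meaning of the scaled values is carried by the two
#' scale parameters: value 2 maps to `up_scale_cm` above home, value 0 to
#' `down_scale_cm` below home, value 1 to home. The platform can travel at
#' most 4 cm either side of home, so each scale is capped at 4 cm.
#'
#' @param values numeric vector of scaled displacements in `[0, 2]`.
#' @param sample_interval_s time step between samples in seconds (> 0).
#' @param up_scale_cm cm of anterior travel encoded by value 2 (0 to 4).
#' @param down_scale_cm cm of posterior travel encoded by value 0 (0 to 4).
#' @param label free-text description.
#' @param loop logical; if `TRUE` the trace repeats seamlessly when evaluated
#'   beyond its duration (used for patient-like traces that loop during long
#'   acquisitions).
#' @return an object of class `breathing_trace`.
#' @export
breathing_trace <- function(values, sample_interval_s = 0.030,
                            up_scale_cm = 0, down_scale_cm = 0,
                            label = "", loop = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values))
    stop("trace values must be a non-empty numeric vector without NAs")
  if (any(values < -1e-9) || any(values > 2 + 1e-9))
    stop("trace values must lie in [0, 2] (platform encoding)")
  values <- pmin(pmax(values, 0), 2)
  if (!is.numeric(sample_interval_s) || length(sample_interval_s) != 1L ||
      sample_interval_s <= 0)
    stop("sample_interval_s must be a positive scalar")
  if (up_scale_cm < 0 || down_scale_cm < 0)
    stop("displacement scales must be non-negative")
  if (up_scale_cm > 4 + 1e-9 || down_scale_cm > 4 + 1e-9)
    stop("platform limit exceeded: displacement scales are capped at 4 cm from home")
  structure(list(values = values,
                 sample_interval_s = sample_interval_s,
                 up_scale_cm = up_scale_cm,
                 down_scale_cm = down_scale_cm,
                 label = label,
                 loop = isTRUE(loop)),
            class = "breathing_trace")
}

#' @export
print.breathing_trace <- function(x, ...) {
  cat(sprintf("<breathing_trace> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  %d samples @ %g ms (%.1f s), scales +%.2f/-%.2f cm, loop=%s\n",
              length(x$values), 1000 * x$sample_interval_s, trace_duration(x),
              x$up_scale_cm, x$down_scale_cm, x$loop))
  invisible(x)
}

#' Trace sample times and total duration
#'
#' `trace_times()` returns the time stamp of every sample (first sample at
#' t = 0); `trace_duration()` returns the loop duration
#' `n * sample_interval_s` in seconds.
#'
#' @param trace a [breathing_trace()].
#' @return numeric vector / scalar of seconds.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$values) - 1) * trace$sample_interval_s
}

#' @rdname trace_times
#' @export
trace_duration <- function(trace) {
  length(trace$values) * trace$sample_interval_s
}

#' Generate a sinusoidal breathing trace
#'
#' Samples `1 + sin(2*pi*t/period + phase)` every 30 ms and renormalizes the
#' samples to span `[0, 2]` exactly (full-range normalization, so the trace
#' attains the platform minimum and maximum encodings even when the sampling
#' grid misses the analytic extrema). The physical scales are symmetric:
#' value 2 maps to +RoM/2 and value 0 to -RoM/2 about home.
#'
#' @param period_s breathing period in seconds (> 0).
#' @param range_of_motion_cm peak-to-trough displacement in cm (0 < RoM <= 8).
#' @param duration_s trace length in seconds; must cover at least one period.
#' @param start_phase_deg phase offset in degrees; 0 starts at home moving
#'   anteriorly (inhale direction).
#' @param sample_interval_s sampling step, seconds.
#' @return a [breathing_trace()] with `round(duration_s / sample_interval_s)`
#'   samples.
#' @export
make_sinusoid <- function(period_s, range_of_motion_cm, duration_s,
                          start_phase_deg = 0, sample_interval_s = 0.030) {
  if (!is.numeric(period_s) || period_s <= 0)
    stop("period_s must be positive")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  if (duration_s < period_s)
    stop("duration_s must cover at least one full period")
  if (!is.numeric(range_of_motion_cm) || range_of_motion_cm <= 0 ||
      range_of_motion_cm > 8)
    stop("range_of_motion_cm must lie in (0, 8] cm")
  n <- round(duration_s / sample_interval_s)
  t <- (seq_len(n) - 1) * sample_interval_s
  raw <- 1 + sin(2 * pi * t / period_s + start_phase_deg * pi / 180)
  raw <- 2 * (raw - min(raw)) / (max(raw) - min(raw))
  breathing_trace(raw, sample_interval_s,
                  up_scale_cm = range_of_motion_cm / 2,
                  down_scale_cm = range_of_motion_cm / 2,
                  label = sprintf("sinusoid T=%gs RoM=%gcm", period_s,
                                  range_of_motion_cm))
}

#' Specification of an irregular patient-like breathing trace
#'
#' Summary statistics the generator is constrained to reproduce: a trace of
#' `duration_s` seconds that loops seamlessly, contains exactly `n_cycles`
#' detectable breath cycles with jittered periods, and after full-range
#' normalization maps its extremes to `max_up_cm` above and `max_down_cm`
#' below home (so the physical peak-to-trough range is their sum). Occasional
#' short noise bursts emulate stutters and coughs. Defaults match a sample
#' lung SBRT breathing record: 153 s, 43 cycles, +1.28/-1.62 cm (2.90 cm
#' peak-to-trough).
#'
#' @param duration_s loop duration in seconds.
#' @param n_cycles number of breath cycles in one loop (>= 1).
#' @param max_up_cm,max_down_cm physical excursion above/below home, cm.
#' @param period_jitter_frac fractional spread of per-cycle periods.
#' @param noise_burst_rate_per_min expected noise bursts per minute.
#' @param noise_burst_amp_cm physical amplitude of a noise burst, cm.
#' @param seed integer RNG seed; the trace is reproducible given the seed.
#' @param sample_interval_s sampling step, seconds.
#' @return a list of class `patient_trace_spec`.
#' @export
patient_trace_spec <- function(duration_s = 153, n_cycles = 43,
                               max_up_cm = 1.28, max_down_cm = 1.62,
                               period_jitter_frac = 0.12,
                               noise_burst_rate_per_min = 2,
                               noise_burst_amp_cm = 0.3,
                               seed = 1L, sample_interval_s = 0.030) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (duration_s <= 0) stop("duration_s must be positive")
  # a human breath cycle cannot plausibly be shorter than ~1.2 s
  if (duration_s / n_cycles < 1.2)
    stop("infeasible spec: n_cycles x minimum plausible period exceeds duration")
  if (max_up_cm < 0 || max_down_cm < 0 || max_up_cm > 4 || max_down_cm > 4)
    stop("excursions must lie in [0, 4] cm (platform limit)")
  if (period_jitter_frac < 0 || period_jitter_frac >= 0.5)
    stop("period_jitter_frac must lie in [0, 0.5)")
  structure(list(duration_s = duration_s, n_cycles = n_cycles,
                 max_up_cm = max_up_cm, max_down_cm = max_down_cm,
                 period_jitter_frac = period_jitter_frac,
                 noise_burst_rate_per_min = noise_burst_rate_per_min,
                 noise_burst_amp_cm = noise_burst_amp_cm,
                 seed = as.integer(seed),
                 sample_interval_s = sample_interval_s),
            class = "patient_trace_spec")
}

#' Generate an irregular patient-like breathing trace
#'
#' Builds `n_cycles` trough-anchored cycles whose jittered periods are
#' rescaled to sum exactly to the loop duration. Each cycle is a
#' `sin^4(pi*s)` pulse (sharp inhale peak, long exhale plateau) with a
#' per-cycle peak height, plus a slow seam-free baseline wander and sparse
#' damped-oscillation noise bursts placed in the exhale plateau. The result
#' is full-range normalized to `[0, 2]` and loops seamlessly (both ends sit
#' on the exhale plateau with near-zero velocity).
#'
#' @param spec a [patient_trace_spec()].
#' @return a looping [breathing_trace()] with `up_scale_cm = max_up_cm` and
#'   `down_scale_cm = max_down_cm`, so the physical peak-to-trough range is
#'   exactly `max_up_cm + max_down_cm`.
#' @export
make_patient_like <- function(spec = patient_trace_spec()) {
  if (!inherits(spec, "patient_trace_spec"))
    stop("spec must be a patient_trace_spec")
  dt <- spec$sample_interval_s
  n <- round(spec$duration_s / dt)
  t <- (seq_len(n) - 1) * dt
  with_seed(spec$seed, {
    nc <- spec$n_cycles
    mean_T <- spec$duration_s / nc
    periods <- mean_T * (1 + spec$period_jitter_frac * runif(nc, -1, 1))
    periods <- periods * spec$duration_s / sum(periods)
    bounds <- c(0, cumsum(periods))
    bounds[nc + 1] <- spec$duration_s  # guard rounding
    ci <- findInterval(t, bounds, rightmost.closed = TRUE)
    ci[ci > nc] <- nc
    s <- (t - bounds[ci]) / periods[ci]
    peak <- runif(nc, 0.75, 1.0)
    raw <- peak[ci] * sin(pi * s)^4
    # slow wander with an integer number of periods over the loop -> seamless
    raw <- raw + 0.04 * sin(2 * pi * 3 * t / spec$duration_s)
    # sparse stutter/cough transients in the early exhale plateau
    burst_amp <- spec$noise_burst_amp_cm /
      max(spec$max_up_cm + spec$max_down_cm, 1e-6) * 2
    n_burst <- rpois(1, spec$noise_burst_rate_per_min * spec$duration_s / 60)
    if (n_burst > 0) {
      cyc <- sample.int(nc, n_burst, replace = TRUE)
      s0 <- runif(n_burst, 0.10, 0.30)
      tc <- bounds[cyc] + s0 * periods[cyc]
      amp <- burst_amp * runif(n_burst, 0.6, 1.0)
      for (b in seq_len(n_burst)) {
        u <- t - tc[b]
        raw <- raw - amp[b] * exp(-(u / 0.15)^2) * cos(2 * pi * u / 0.25)
      }
    }
    raw <- 2 * (raw - min(raw)) / (max(raw) - min(raw))
    breathing_trace(raw, dt,
                    up_scale_cm = spec$max_up_cm,
                    down_scale_cm = spec$max_down_cm,
                    label = sprintf("patient-like %gs/%d cycles (seed %d)",
                                    spec$duration_s, spec$n_cycles, spec$seed),
                    loop = TRUE)
  })
}

#' Map scaled trace values to physical AP displacement
#'
#' The platform encoding is piecewise linear about home: a value `v >= 1`
#' maps to `(v - 1) * up_scale_cm` and `v < 1` to `(v - 1) * down_scale_cm`,
#' so value 1 is 0 cm, value 2 is `+up_scale_cm` and value 0 is
#' `-down_scale_cm`. A single linear factor cannot represent asymmetric
#' excursions such as +1.28/-1.62 cm while keeping home at value 1, hence the
#' piecewise map.
#'
#' @param trace a [breathing_trace()].
#' @param values optional scaled values to convert; defaults to the trace's
#'   own samples.
#' @return displacement in cm, positive anterior, relative to home.
#' @export
to_physical <- function(trace, values = NULL) {
  v <- values %||% trace$values
  ifelse(v >= 1, (v - 1) * trace$up_scale_cm, (v - 1) * trace$down_scale_cm)
}

#' Evaluate a trace at arbitrary times
#'
#' Linear interpolation between samples. Looping traces wrap modulo their
#' duration (the sample after the last is the first); non-looping traces
#' error when evaluated beyond their last sample.
#'
#' @param trace a [breathing_trace()].
#' @param t_s times in seconds (>= 0).
#' @return `trace_value_at()` gives scaled values in `[0, 2]`;
#'   `physical_at()` gives cm of AP displacement.
#' @export
trace_value_at <- function(trace, t_s) {
  dt <- trace$sample_interval_s
  v <- trace$values
  n <- length(v)
  dur <- n * dt
  if (any(t_s < -1e-9)) stop("times must be non-negative")
  if (trace$loop) {
    t_s <- t_s %% dur
  } else if (any(t_s > (n - 1) * dt + 1e-9)) {
    stop("time beyond trace end and trace does not loop")
  }
  i0 <- pmin(floor(t_s / dt), n - 1)
  frac <- t_s / dt - i0
  nxt <- ifelse(i0 + 2 > n, 1L, i0 + 2)  # wrap for looping traces
  v[i0 + 1] * (1 - frac) + v[nxt] * frac
}

#' @rdname trace_value_at
#' @export
physical_at <- function(trace, t_s) {
  to_physical(trace, trace_value_at(trace, t_s))
}

#' Detect breath cycles in a trace
#'
#' Inhale peaks are local maxima above `min_peak_height` separated by at
#' least `refractory_s` (no plausible breath is shorter than ~1 s). Peak
#' times are refined to sub-sample accuracy by parabolic interpolation
#' through the three samples around each maximum, so that for a noiseless
#' sinusoid the measured mean period is accurate well within one sample
#' interval.
#'
#' @param trace a [breathing_trace()].
#' @param refractory_s minimum separation between peaks, seconds.
#' @param min_peak_height minimum scaled value of a peak; the default (1,
#'   the home position) rejects small secondary maxima in the exhale plateau
#'   such as noise bursts.
#' @return a list with `peak_times_s`, per-cycle `periods_s` (differences of
#'   successive peak times), `mean_period_s` and `n_cycles` (the peak count).
#' @export
detect_cycles <- function(trace, refractory_s = 1.0, min_peak_height = 1.0) {
  v <- trace$values
  dt <- trace$sample_interval_s
  pk <- pracma::findpeaks(v, minpeakheight = min_peak_height,
                          minpeakdistance = max(1L, round(refractory_s / dt)))
  if (is.null(pk) || nrow(pk) < 2)
    stop("fewer than 2 breathing peaks detected")
  idx <- sort(pk[, 2])
  refine <- function(i) {
    if (i <= 1L || i >= length(v)) return((i - 1) * dt)
    den <- v[i - 1] - 2 * v[i] + v[i + 1]
    d <- if (abs(den) < 1e-12) 0 else 0.5 * (v[i - 1] - v[i + 1]) / den
    (i - 1 + max(-0.5, min(0.5, d))) * dt
  }
  times <- vapply(idx, refine, numeric(1))
  periods <- diff(times)
  list(peak_times_s = times, periods_s = periods,
       mean_period_s = mean(periods), n_cycles = length(times))
}

#' Read and write breathing traces as CSV
#'
#' The format is a plain-text CSV with metadata comment lines
#' (`# key: value` for the sample interval, scales, label and loop flag)
#' followed by a `time_s,value` header and one row per sample. Values are
#' written with six decimal places, so `write_trace()` followed by
#' `read_trace()` reproduces the samples to 1e-6.
#'
#' @param path file path.
#' @param trace a [breathing_trace()].
#' @return `read_trace()` returns a [breathing_trace()]; `write_trace()`
#'   returns `path` invisibly.
#' @export
write_trace <- function(path, trace) {
  meta <- c(sprintf("# sample_interval_s: %.6f", trace$sample_interval_s),
            sprintf("# up_scale_cm: %.6f", trace$up_scale_cm),
            sprintf("# down_scale_cm: %.6f", trace$down_scale_cm),
            sprintf("# label: %s", trace$label),
            sprintf("# loop: %s", if (trace$loop) "true" else "false"))
  rows <- sprintf("%.6f,%.6f", trace_times(trace), trace$values)
  writeLines(c(meta, "time_s,value", rows), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- lines[is_meta]
  body <- lines[!is_meta]
  get_meta <- function(key, default = NULL) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  if (!length(body) || trimws(body[1]) != "time_s,value")
    stop("malformed trace file: missing 'time_s,value' header")
  if (length(body) < 2) stop("malformed trace file: no samples")
  parts <- strsplit(body[-1], ",", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("malformed trace file: expected two columns")
  vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(vals)) stop("malformed trace file: non-numeric values")
  if (any(vals < -1e-9 | vals > 2 + 1e-9))
    stop("trace file contains values outside [0, 2]")
  breathing_trace(vals,
                  sample_interval_s = as.numeric(get_meta("sample_interval_s", "0.030")),
                  up_scale_cm = as.numeric(get_meta("up_scale_cm", "0")),
                  down_scale_cm = as.numeric(get_meta("down_scale_cm", "0")),
                  label = get_meta("label", ""),
                  loop = identical(get_meta("loop", "false"), "true"))
}
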