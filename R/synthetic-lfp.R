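#' Generate a synthetic DC-coupled LFP trace with known events
#'
#' Builds a Gaussian-noise baseline at `baseline_mean` and superimposes
#' (a) spreading depolarizations (SDs) as smooth negative DC deflections —
#' a raised-cosine fall over `ramp_s` seconds, a plateau at the stated
#' amplitude, and a raised-cosine recovery filling the `[onset, onset +
#' duration]` footprint — and (b) post-ischemic potential (PIP) bursts as
#' band-limited oscillations with short raised-cosine onset/offset ramps.
#'
#' Alongside the nominal event footprint, the ground-truth table reports for
#' each SD the definition-consistent onset and end times computed
#' analytically from the noiseless waveform: `onset_rule_s` is where the
#' deflection first exceeds `10 * baseline_sd` and `end_rule_s` where the
#' trace recovers to 80 percent of the baseline mean.  These are the times
#' an ideal noise-free detector applying the SD definition would measure,
#' and are the reference for detector-accuracy checks.
#'
#' @param duration Trace length in seconds.
#' @param fs Sampling rate in Hz.
#' @param baseline_mean,baseline_sd Baseline mean and noise SD in mV.
#' @param sd_specs `NULL` or a data frame with columns `onset_s`,
#'   `amplitude_mV`, `duration_s` and optionally `location`.
#' @param pip_specs `NULL` or a data frame with columns `onset_s`,
#'   `duration_s`, `freq_hz`, `rel_amplitude` (oscillation RMS as a multiple
#'   of `baseline_sd`).
#' @param seed Integer seed for the noise stream.
#' @param ramp_s SD fall/recovery ramp length in seconds.
#' @param pip_ramp_s PIP envelope ramp length in seconds.
#' @return List with `trace` (an [lfp_trace()]) and `truth` (event table:
#'   `type`, `onset_s`, `end_s`, `duration_s`, `amplitude_mV`, `freq_hz`,
#'   `band`, `location`, `onset_rule_s`, `end_rule_s`).
#' @export
generate_lfp <- function(duration, fs = 10000, baseline_mean = 4,
                         baseline_sd = 0.1, sd_specs = NULL, pip_specs = NULL,
                         seed = 1, ramp_s = 5, pip_ramp_s = 0.25) {
  stopifnot(duration > 0, fs > 0, baseline_sd >= 0, ramp_s > 0)
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1L) / fs

  x <- rep(baseline_mean, n)
  truth <- list()

  if (!is.null(sd_specs) && nrow(sd_specs) > 0L) {
    sd_specs <- as.data.frame(sd_specs)
    stopifnot(all(c("onset_s", "amplitude_mV", "duration_s") %in% names(sd_specs)))
    ord <- order(sd_specs$onset_s)
    sd_specs <- sd_specs[ord, , drop = FALSE]
    ends <- sd_specs$onset_s + sd_specs$duration_s
    if (any(sd_specs$onset_s < 0) || any(ends > duration)) {
      stop("SD event windows must lie within [0, duration]", call. = FALSE)
    }
    if (nrow(sd_specs) > 1L &&
        any(sd_specs$onset_s[-1L] < ends[-nrow(sd_specs)])) {
      stop("overlapping SD specifications are not allowed", call. = FALSE)
    }
    for (i in seq_len(nrow(sd_specs))) {
      on <- sd_specs$onset_s[i]; A <- sd_specs$amplitude_mV[i]
      dur <- sd_specs$duration_s[i]
      if (dur <= 2 * ramp_s) {
        stop("SD duration must exceed twice the ramp length (", 2 * ramp_s,
             " s)", call. = FALSE)
      }
      x <- x - A * sd_deflection_shape(t, on, dur, ramp_s)
      rule <- sd_rule_times(on, A, dur, ramp_s,
                            thr_on = 10 * baseline_sd,
                            thr_off = 0.2 * baseline_mean)
      truth[[length(truth) + 1L]] <- data.frame(
        type = "sd", onset_s = on, end_s = on + dur, duration_s = dur,
        amplitude_mV = A, freq_hz = NA_real_, band = NA_character_,
        location = if ("location" %in% names(sd_specs))
          as.character(sd_specs$location[i]) else "unknown",
        onset_rule_s = rule[1L], end_rule_s = rule[2L],
        stringsAsFactors = FALSE)
    }
  }

  if (!is.null(pip_specs) && nrow(pip_specs) > 0L) {
    pip_specs <- as.data.frame(pip_specs)
    stopifnot(all(c("onset_s", "duration_s", "freq_hz", "rel_amplitude") %in%
                    names(pip_specs)))
    if (fs < 2 * max(pip_specs$freq_hz)) {
      stop("fs must be at least twice the highest PIP frequency", call. = FALSE)
    }
    if (any(pip_specs$onset_s < 0) ||
        any(pip_specs$onset_s + pip_specs$duration_s > duration)) {
      stop("PIP event windows must lie within [0, duration]", call. = FALSE)
    }
    bands <- default_bands()
    for (i in seq_len(nrow(pip_specs))) {
      on <- pip_specs$onset_s[i]; dur <- pip_specs$duration_s[i]
      f0 <- pip_specs$freq_hz[i]
      amp <- pip_specs$rel_amplitude[i] * baseline_sd * sqrt(2)
      env <- tukey_envelope(t, on, dur, pip_ramp_s)
      x <- x + amp * env * sin(2 * pi * f0 * (t - on))
      in_band <- bands$name[bands$f_low < f0 & f0 <= bands$f_high]
      if (f0 == bands$f_low[1L]) in_band <- bands$name[1L]
      truth[[length(truth) + 1L]] <- data.frame(
        type = "pip", onset_s = on, end_s = on + dur, duration_s = dur,
        amplitude_mV = amp, freq_hz = f0,
        band = if (length(in_band)) in_band[1L] else NA_character_,
        location = "unknown", onset_rule_s = NA_real_, end_rule_s = NA_real_,
        stringsAsFactors = FALSE)
    }
  }

  if (baseline_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(n, 0, baseline_sd))
  }

  truth <- if (length(truth)) do.call(rbind, truth) else empty_event_truth()
  truth <- truth[order(truth$onset_s), , drop = FALSE]
  rownames(truth) <- NULL
  list(trace = lfp_trace(x, fs = fs), truth = truth)
}

empty_event_truth <- function() {
  data.frame(type = character(), onset_s = numeric(), end_s = numeric(),
             duration_s = numeric(), amplitude_mV = numeric(),
             freq_hz = numeric(), band = character(), location = character(),
             onset_rule_s = numeric(), end_rule_s = numeric(),
             stringsAsFactors = FALSE)
}

# Unit-amplitude deflection: raised-cosine fall over ramp_s, plateau, and
# raised-cosine recovery, supported on [onset, onset + duration].
sd_deflection_shape <- function(t, onset, duration, ramp_s) {
  u <- numeric(length(t))
  fall <- t >= onset & t < onset + ramp_s
  u[fall] <- 0.5 * (1 - cos(pi * (t[fall] - onset) / ramp_s))
  plateau <- t >= onset + ramp_s & t <= onset + duration - ramp_s
  u[plateau] <- 1
  rise <- t > onset + duration - ramp_s & t <= onset + duration
  u[rise] <- 0.5 * (1 - cos(pi * (onset + duration - t[rise]) / ramp_s))
  u
}

# Analytic threshold-crossing times on the noiseless deflection: depth first
# exceeds thr_on on the fall ramp; depth last falls below thr_off on the
# recovery ramp.  Returns c(NA, NA) when the amplitude never reaches thr_on.
sd_rule_times <- function(onset, amplitude, duration, ramp_s, thr_on, thr_off) {
  if (amplitude <= thr_on) return(c(NA_real_, NA_real_))
  u_on <- acos(1 - 2 * min(1, thr_on / amplitude)) / pi
  t_on <- onset + ramp_s * u_on
  u_off <- acos(1 - 2 * min(1, thr_off / amplitude)) / pi
  t_off <- onset + duration - ramp_s * u_off
  c(t_on, t_off)
}

# Flat-top envelope with raised-cosine ramps of ramp_s at both ends.
tukey_envelope <- function(t, onset, duration, ramp_s) {
  ramp_s <- min(ramp_s, duration / 2)
  env <- numeric(length(t))
  core <- t >= onset + ramp_s & t <= onset + duration - ramp_s
  env[core] <- 1
  up <- t >= onset & t < onset + ramp_s
  env[up] <- 0.5 * (1 - cos(pi * (t[up] - onset) / ramp_s))
  down <- t > onset + duration - ramp_s & t <= onset + duration
  env[down] <- 0.5 * (1 - cos(pi * (onset + duration - t[down]) / ramp_s))
  env
}
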