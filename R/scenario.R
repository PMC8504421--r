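#' Configuration of a synthetic focal-ischemia scenario
#'
#' Describes one emulated endothelin-1 (ET-1) experiment: a pre-injection
#' baseline, a rapid arteriolar velocity drop to `peak_drop_fraction` of
#' baseline, a slow creep, a fast "volley" recovery transiently exceeding
#' 80 percent of baseline, and a final plateau at `plateau_fraction`.
#' Spreading depolarizations (SDs) occur only while the velocity is below
#' `sd_trigger_fraction` of baseline, and post-ischemic potentials (PIPs)
#' begin only after the final SD has ended.
#'
#' @param duration Total scenario length in seconds.
#' @param injection_time ET-1 injection time in seconds.
#' @param baseline_duration Pre-injection span used for baseline statistics
#'   (must not exceed `injection_time`).
#' @param baseline_vrbc Baseline RBC velocity in mm/s.
#' @param peak_drop_fraction Fraction of baseline velocity remaining at the
#'   nadir, in `[0, 1)`.
#' @param drop_duration Seconds from injection to the nadir.
#' @param recovery_onset_time Start of the fast recovery volley (s); must be
#'   later than `injection_time`.
#' @param recovery_ramp Volley rise time in seconds.
#' @param transient_peak_fraction Transient recovery peak as a fraction of
#'   baseline (> 0.8 so a partial-recovery period exists).
#' @param plateau_fraction Late plateau as a fraction of baseline; must
#'   exceed `peak_drop_fraction`.
#' @param sd_trigger_fraction SDs may start only while velocity is below
#'   this fraction of baseline (default 0.35).
#' @param lfp_fs LFP sampling rate in Hz.
#' @param lfp_baseline_mean,lfp_baseline_sd LFP baseline mean and noise SD
#'   in mV.
#' @param n_sds Number of SDs to place.
#' @param sd_amplitude_range SD plateau amplitudes in mV (min, max).
#' @param sd_duration SD footprint duration in seconds.
#' @param pip_rate_post_sd Mean PIP rate after the last SD, events/min.
#' @param velocity_dt Sampling interval of the synthetic velocity trace (s).
#' @param velocity_noise_sd Velocity measurement noise SD in mm/s.
#' @param kymo_pixels,kymo_line_period Kymograph rendering geometry.
#' @param seed Integer seed; a fixed config and seed give bit-identical
#'   output.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(duration = 900, injection_time = 60,
                            baseline_duration = injection_time,
                            baseline_vrbc = 6,
                            peak_drop_fraction = 0.2, drop_duration = 90,
                            recovery_onset_time = 500, recovery_ramp = 20,
                            transient_peak_fraction = 0.95,
                            plateau_fraction = 0.35,
                            sd_trigger_fraction = 0.35,
                            lfp_fs = 10000, lfp_baseline_mean = 4,
                            lfp_baseline_sd = 0.1,
                            n_sds = 2, sd_amplitude_range = c(15, 25),
                            sd_duration = 60, pip_rate_post_sd = 2,
                            velocity_dt = 1, velocity_noise_sd = 0.15,
                            kymo_pixels = 64, kymo_line_period = 1.25,
                            seed = 1) {
  cfg <- list(
    duration = duration, injection_time = injection_time,
    baseline_duration = baseline_duration, baseline_vrbc = baseline_vrbc,
    peak_drop_fraction = peak_drop_fraction, drop_duration = drop_duration,
    recovery_onset_time = recovery_onset_time, recovery_ramp = recovery_ramp,
    transient_peak_fraction = transient_peak_fraction,
    plateau_fraction = plateau_fraction,
    sd_trigger_fraction = sd_trigger_fraction,
    lfp_fs = lfp_fs, lfp_baseline_mean = lfp_baseline_mean,
    lfp_baseline_sd = lfp_baseline_sd,
    n_sds = as.integer(n_sds), sd_amplitude_range = sd_amplitude_range,
    sd_duration = sd_duration, pip_rate_post_sd = pip_rate_post_sd,
    velocity_dt = velocity_dt, velocity_noise_sd = velocity_noise_sd,
    kymo_pixels = as.integer(kymo_pixels),
    kymo_line_period = kymo_line_period,
    seed = as.integer(seed))
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  with(cfg, {
    if (!(peak_drop_fraction >= 0 && peak_drop_fraction < plateau_fraction &&
          plateau_fraction <= 1)) {
      stop("need 0 <= peak_drop_fraction < plateau_fraction <= 1",
           call. = FALSE)
    }
    if (injection_time >= recovery_onset_time) {
      stop("injection_time must precede recovery_onset_time", call. = FALSE)
    }
    if (baseline_duration > injection_time || baseline_duration <= 0) {
      stop("baseline_duration must lie in (0, injection_time]", call. = FALSE)
    }
    if (injection_time + drop_duration >= recovery_onset_time) {
      stop("the velocity nadir must precede recovery_onset_time", call. = FALSE)
    }
    if (recovery_onset_time + recovery_ramp >= duration) {
      stop("recovery must complete before the end of the scenario", call. = FALSE)
    }
    if (transient_peak_fraction <= 0.8) {
      stop("transient_peak_fraction must exceed 0.8 for a partial-recovery ",
           "period to exist", call. = FALSE)
    }
    if (baseline_vrbc <= 0) stop("baseline_vrbc must be positive", call. = FALSE)
  })
  invisible(cfg)
}

# Creep geometry after the nadir: a brisk early rebound (the microvascular
# relaxation right after the constriction peak) followed by a slow drift
# toward f_creep until the recovery volley.  The sharp V around the nadir
# keeps the velocity minimum well localized in time.
creep_params <- function(cfg) {
  f_nadir <- cfg$peak_drop_fraction
  f_creep <- min(cfg$plateau_fraction, f_nadir + 0.12)
  t_nadir <- cfg$injection_time + cfg$drop_duration
  span <- cfg$recovery_onset_time - t_nadir
  t_fast <- min(40, span / 2)
  f_mid <- f_nadir + (f_creep - f_nadir) * 2 / 3
  list(t_nadir = t_nadir, t_fast = t_fast, span = span,
       f_nadir = f_nadir, f_mid = f_mid, f_creep = f_creep)
}

# Velocity profile (mm/s) as a function of time for a scenario config.
# Piecewise: baseline 1.0 -> cosine drop to peak_drop_fraction -> two-phase
# linear creep -> cosine volley to transient_peak_fraction -> 20 s hold ->
# cosine decay to plateau_fraction -> plateau.
scenario_velocity_profile <- function(cfg) {
  v0 <- cfg$baseline_vrbc
  t_inj <- cfg$injection_time
  cp <- creep_params(cfg)
  t_nadir <- cp$t_nadir
  t_volley <- cfg$recovery_onset_time
  ramp <- cfg$recovery_ramp
  f_peak <- cfg$transient_peak_fraction
  hold <- 20
  decay <- 60
  t_decay_end <- min(cfg$duration, t_volley + ramp + hold + decay)
  f_plateau <- cfg$plateau_fraction

  function(t) {
    frac <- numeric(length(t))
    frac[t < t_inj] <- 1
    i <- t >= t_inj & t < t_nadir
    frac[i] <- cp$f_nadir + (1 - cp$f_nadir) *
      0.5 * (1 + cos(pi * (t[i] - t_inj) / (t_nadir - t_inj)))
    i <- t >= t_nadir & t < t_nadir + cp$t_fast
    frac[i] <- cp$f_nadir + (cp$f_mid - cp$f_nadir) *
      (t[i] - t_nadir) / cp$t_fast
    i <- t >= t_nadir + cp$t_fast & t < t_volley
    frac[i] <- cp$f_mid + (cp$f_creep - cp$f_mid) *
      (t[i] - t_nadir - cp$t_fast) / (cp$span - cp$t_fast)
    i <- t >= t_volley & t < t_volley + ramp
    frac[i] <- cp$f_creep + (f_peak - cp$f_creep) *
      0.5 * (1 - cos(pi * (t[i] - t_volley) / ramp))
    i <- t >= t_volley + ramp & t < t_volley + ramp + hold
    frac[i] <- f_peak
    i <- t >= t_volley + ramp + hold & t < t_decay_end
    frac[i] <- f_plateau + (f_peak - f_plateau) *
      0.5 * (1 + cos(pi * (t[i] - (t_volley + ramp + hold)) /
                       (t_decay_end - (t_volley + ramp + hold))))
    frac[t >= t_decay_end] <- f_plateau
    v0 * frac
  }
}

# Analytic times at which the profile fraction crosses `level`:
# down-crossing on the drop ramp, up-crossing on the creep or volley.
# NA if never.
scenario_crossings <- function(cfg, level) {
  cp <- creep_params(cfg)
  f_peak <- cfg$transient_peak_fraction
  down <- NA_real_
  if (level < 1 && level > cp$f_nadir) {
    u <- acos(2 * (level - cp$f_nadir) / (1 - cp$f_nadir) - 1) / pi
    down <- cfg$injection_time + cfg$drop_duration * u
  }
  up <- NA_real_
  if (level <= cp$f_nadir) {
    up <- NA_real_  # never below level
  } else if (level <= cp$f_mid) {
    u <- (level - cp$f_nadir) / (cp$f_mid - cp$f_nadir)
    up <- cp$t_nadir + u * cp$t_fast
  } else if (level <= cp$f_creep) {
    u <- (level - cp$f_mid) / (cp$f_creep - cp$f_mid)
    up <- cp$t_nadir + cp$t_fast + u * (cp$span - cp$t_fast)
  } else if (level <= f_peak) {
    u <- acos(1 - 2 * (level - cp$f_creep) / (f_peak - cp$f_creep)) / pi
    up <- cfg$recovery_onset_time + cfg$recovery_ramp * u
  }
  c(down = down, up = up)
}

#' Generate a coupled kymograph / LFP ischemia scenario
#'
#' Produces a synthetic experiment with machine-readable ground truth: a
#' velocity trace (and optionally a rendered kymograph) following the
#' scenario profile, and an LFP trace whose SD onsets lie strictly inside
#' the interval where the ground-truth velocity is below
#' `sd_trigger_fraction * baseline`, with all PIP onsets strictly after the
#' last SD end.
#'
#' @param config A [scenario_config()].
#' @param components Character subset of `c("velocity", "lfp", "kymograph")`.
#'   Kymograph rendering is by far the most expensive part and can be
#'   skipped when only the electrophysiology or the segmentation is under
#'   study.
#' @return A list of class `nv_scenario` with elements `config`, `truth`
#'   (velocity profile function, event tables, analytic period boundaries),
#'   and the requested `velocity` ([velocity_trace()]), `lfp`
#'   ([lfp_trace()]) and `kymograph` ([kymograph()]) components.
#' @export
generate_scenario <- function(config = scenario_config(),
                              components = c("velocity", "lfp", "kymograph")) {
  stopifnot(inherits(config, "scenario_config"))
  components <- match.arg(components,
                          c("velocity", "lfp", "kymograph"),
                          several.ok = TRUE)
  cfg <- config
  profile <- scenario_velocity_profile(cfg)

  sub <- scenario_crossings(cfg, cfg$sd_trigger_fraction)
  if (cfg$n_sds > 0L && (is.na(sub["down"]) || is.na(sub["up"]))) {
    stop(sprintf(
      paste0("SD trigger unreachable: velocity never falls below %.0f%% of ",
             "baseline (minimum fraction %.0f%%)"),
      100 * cfg$sd_trigger_fraction, 100 * cfg$peak_drop_fraction),
      call. = FALSE)
  }

  # --- event placement (seeded, independent of the noise streams) ---------
  sd_events <- NULL
  pip_events <- NULL
  with_seed(cfg$seed, {
    if (cfg$n_sds > 0L) {
      t_lo <- sub[["down"]] + 5
      t_hi <- sub[["up"]] - 5
      gap <- 30
      # one slot per SD; the onset jitters inside its slot so consecutive
      # events always keep at least `gap` seconds of quiet between them
      slot <- (t_hi - t_lo) / cfg$n_sds
      if (slot < cfg$sd_duration + gap) {
        stop("sub-threshold interval too short for ", cfg$n_sds, " SDs",
             call. = FALSE)
      }
      onsets <- t_lo + (seq_len(cfg$n_sds) - 1L) * slot +
        stats::runif(cfg$n_sds, 0, slot - cfg$sd_duration - gap)
      amps <- stats::runif(cfg$n_sds, cfg$sd_amplitude_range[1L],
                           cfg$sd_amplitude_range[2L])
      sd_events <- data.frame(onset_s = onsets, amplitude_mV = amps,
                              duration_s = cfg$sd_duration,
                              location = "injection_site")
    }
    if (cfg$pip_rate_post_sd > 0) {
      t0 <- if (!is.null(sd_events))
        max(sd_events$onset_s + sd_events$duration_s) + 10 else
          cfg$recovery_onset_time
      onsets <- durs <- numeric(0)
      t_cur <- t0
      repeat {
        # events are spaced by at least 3 s of quiet after the previous one
        t_cur <- t_cur + stats::rexp(1L, rate = cfg$pip_rate_post_sd / 60) + 3
        if (t_cur > cfg$duration - 6) break
        # durations emulate the characteristic ~2.3 +/- 0.5 s events with a floor
        # at the > 2 s detectability limit implied by the PIP definition
        d <- min(max(stats::rnorm(1L, 2.3, 0.5), 2.3), 4)
        onsets <- c(onsets, t_cur)
        durs <- c(durs, d)
        t_cur <- t_cur + d
      }
      if (length(onsets)) {
        freqs <- sample(c(4, 6, 8, 11, 13), length(onsets), replace = TRUE,
                        prob = c(0.3, 0.3, 0.2, 0.1, 0.1))
        pip_events <- data.frame(onset_s = onsets, duration_s = durs,
                                 freq_hz = freqs, rel_amplitude = 4)
      }
    }
  })

  truth <- list(
    velocity_profile = profile,
    baseline_vrbc = cfg$baseline_vrbc,
    nadir_time_s = cfg$injection_time + cfg$drop_duration,
    recovery_crossing_s = scenario_crossings(cfg, 0.8)[["up"]],
    sub_threshold_interval_s = unname(sub),
    sd_events = sd_events,
    pip_events = pip_events)

  out <- list(config = cfg, truth = truth)

  if ("velocity" %in% components) {
    t <- seq(0, cfg$duration, by = cfg$velocity_dt)
    v <- profile(t)
    if (cfg$velocity_noise_sd > 0) {
      v <- v + with_seed(cfg$seed + 101L,
                         stats::rnorm(length(t), 0, cfg$velocity_noise_sd))
    }
    out$velocity <- velocity_trace(t, v)
  }

  if ("lfp" %in% components) {
    lfp <- generate_lfp(
      duration = cfg$duration, fs = cfg$lfp_fs,
      baseline_mean = cfg$lfp_baseline_mean,
      baseline_sd = cfg$lfp_baseline_sd,
      sd_specs = sd_events, pip_specs = pip_events,
      seed = cfg$seed + 202L)
    out$lfp <- lfp$trace
    out$lfp_truth <- lfp$truth
  }

  if ("kymograph" %in% components) {
    n_lines <- as.integer(floor(cfg$duration * 1000 / cfg$kymo_line_period))
    sim <- generate_kymograph(
      profile, n_lines = n_lines, n_pixels = cfg$kymo_pixels,
      line_period = cfg$kymo_line_period, pixel_size = 1,
      noise_sd = 0.03, seed = cfg$seed + 303L)
    out$kymograph <- sim$kymograph
    out$kymo_truth <- sim$truth
  }

  class(out) <- "nv_scenario"
  out
}

#' @export
print.nv_scenario <- function(x, ...) {
  cat(sprintf("<nv_scenario> %.0f s | injection @ %.0f s | %d SDs | %d PIPs\n",
              x$config$duration, x$config$injection_time,
              if (is.null(x$truth$sd_events)) 0L else nrow(x$truth$sd_events),
              if (is.null(x$truth$pip_events)) 0L else nrow(x$truth$pip_events)))
  invisible(x)
}

#' Write the ground-truth event table of a scenario as CSV
#'
#' @param scenario An `nv_scenario`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_scenario_truth <- function(scenario, path) {
  stopifnot(inherits(scenario, "nv_scenario"))
  if (is.null(scenario$lfp_truth)) {
    stop("scenario was generated without the 'lfp' component", call. = FALSE)
  }
  utils::write.csv(scenario$lfp_truth, path, row.names = FALSE)
  invisible(path)
}
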