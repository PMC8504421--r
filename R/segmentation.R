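#' Segment the experiment timeline from a velocity trace
#'
#' Splits the recording into "baseline" (pre-injection), "ischemia" (the
#' five minutes following the peak drop in vRBC) and "partial recovery"
#' (from the first sustained return of vRBC to 80 percent of the baseline
#' level to the end of the recording).  The velocity is smoothed with a
#' 30 s running median before locating the nadir and the threshold
#' crossing, so isolated single-window outliers cannot define either
#' boundary; the 80 percent crossing must persist for at least
#' `sustain_s` seconds to exclude transient spikes.
#'
#' @param trace A [velocity_trace()] spanning the injection with at least
#'   60 s of pre-injection data.
#' @param injection_time ET-1 injection time in seconds.
#' @param smooth_s Running-median window in seconds.
#' @param ischemia_s Ischemia period length in seconds (default 300).
#' @param recovery_fraction Recovery threshold as a fraction of baseline
#'   vRBC.
#' @param sustain_s Minimum persistence of the recovery crossing.
#' @return List of class `period_segmentation`: `baseline`, `ischemia`,
#'   `partial_recovery` (each `c(start_s, end_s)`; `partial_recovery` is
#'   `NULL` with `recovery_absent = TRUE` when the trace never re-crosses
#'   the threshold), `peak_drop_time`, `baseline_vrbc`.
#' @export
segment_periods <- function(trace, injection_time, smooth_s = 30,
                            ischemia_s = 300, recovery_fraction = 0.8,
                            sustain_s = 10) {
  stopifnot(inherits(trace, "velocity_trace"))
  t <- trace$time_s
  v <- trace$v_mm_s
  ok <- is.finite(v)
  t <- t[ok]; v <- v[ok]
  if (length(t) < 4L) stop("too few valid velocity samples", call. = FALSE)
  dt <- stats::median(diff(t))
  if (injection_time - t[1L] < 60 - 1.5 * dt) {
    stop("need at least 60 s of pre-injection data", call. = FALSE)
  }
  if (injection_time >= t[length(t)]) {
    stop("trace must span the injection time", call. = FALSE)
  }
  sm <- moving_median(v, smooth_s / dt)

  pre <- t < injection_time
  baseline_vrbc <- mean(v[pre])
  if (!is.finite(baseline_vrbc) || baseline_vrbc <= 0) {
    stop("baseline vRBC must be positive", call. = FALSE)
  }

  post <- which(t >= injection_time)
  if (min(sm[post]) > 0.9 * baseline_vrbc) {
    stop("no ischemic drop detected: post-injection velocity never falls ",
         "below 90% of baseline", call. = FALSE)
  }
  peak_drop_time <- t[post[which.min(sm[post])]]
  ischemia <- c(peak_drop_time, peak_drop_time + ischemia_s)

  after <- which(t >= ischemia[2L])
  recovery <- NULL
  recovery_absent <- TRUE
  if (length(after)) {
    mask <- sm[after] >= recovery_fraction * baseline_vrbc
    # brief dips (< 2 s) below the threshold do not break sustainment:
    # they are measurement noise at the scale of a single velocity window
    gaps <- true_runs(!mask)
    for (g in seq_len(nrow(gaps))) {
      if (t[after[gaps$end[g]]] - t[after[gaps$start[g]]] < 2 &&
          gaps$start[g] > 1L && gaps$end[g] < length(after)) {
        mask[gaps$start[g]:gaps$end[g]] <- TRUE
      }
    }
    runs <- true_runs(mask)
    if (nrow(runs)) {
      long_enough <- t[after[runs$end]] - t[after[runs$start]] >= sustain_s
      # a sustained run reaching the end of the trace also qualifies
      long_enough <- long_enough | runs$end == length(after)
      if (any(long_enough)) {
        i0 <- after[runs$start[which(long_enough)[1L]]]
        start <- t[i0]
        # sub-sample refinement: linear interpolation of the smoothed series
        # onto the threshold between the bracketing samples
        thr <- recovery_fraction * baseline_vrbc
        if (i0 > 1L && sm[i0 - 1L] < thr && sm[i0] > sm[i0 - 1L]) {
          start <- t[i0 - 1L] + (t[i0] - t[i0 - 1L]) *
            (thr - sm[i0 - 1L]) / (sm[i0] - sm[i0 - 1L])
        }
        recovery <- c(start, t[length(t)])
        recovery_absent <- FALSE
      }
    }
  }

  structure(list(
    baseline = c(t[1L], injection_time),
    ischemia = ischemia,
    partial_recovery = recovery,
    recovery_absent = recovery_absent,
    peak_drop_time = peak_drop_time,
    baseline_vrbc = baseline_vrbc,
    smooth_s = smooth_s
  ), class = "period_segmentation")
}

#' @export
print.period_segmentation <- function(x, ...) {
  fmt <- function(p) if (is.null(p)) "absent" else
    sprintf("[%.1f, %.1f] s", p[1L], p[2L])
  cat("<period_segmentation>\n",
      "  baseline        ", fmt(x$baseline), "\n",
      "  ischemia        ", fmt(x$ischemia), "\n",
      "  partial recovery", fmt(x$partial_recovery), "\n",
      sprintf("  peak drop @ %.1f s | baseline vRBC %.2f mm/s\n",
              x$peak_drop_time, x$baseline_vrbc), sep = "")
  invisible(x)
}

#' Distance travelled by RBCs over a period
#'
#' Trapezoidal integral of the velocity over the period, in mm (the area
#' under the product of vRBC and time).  Interior gaps are linearly
#' bridged; if gaps (including uncovered period edges) exceed
#' `max_gap_fraction` of the period, an error reports the coverage.
#'
#' @param trace A [velocity_trace()].
#' @param period `c(start_s, end_s)` within the trace.
#' @param max_gap_fraction Largest tolerated uncovered fraction.
#' @return Distance in mm.
#' @export
rbc_distance <- function(trace, period, max_gap_fraction = 0.2) {
  stopifnot(inherits(trace, "velocity_trace"))
  period <- as.numeric(period)
  if (period[2L] <= period[1L]) stop("period must satisfy start < end", call. = FALSE)
  ok <- is.finite(trace$v_mm_s)
  t <- trace$time_s[ok]; v <- trace$v_mm_s[ok]
  if (length(t) < 2L) stop("too few velocity samples", call. = FALSE)
  if (period[1L] < t[1L] - 1e-9 || period[2L] > t[length(t)] + 1e-9) {
    stop("period lies outside the velocity trace", call. = FALSE)
  }

  dt_med <- stats::median(diff(t))
  gap_tol <- max(2, 3 * dt_med)
  inside <- t >= period[1L] & t <= period[2L]
  ti <- t[inside]
  span <- diff(period)
  gaps <- sum(pmax(0, diff(c(period[1L], ti, period[2L])) - gap_tol))
  coverage <- 1 - gaps / span
  if (1 - coverage > max_gap_fraction) {
    stop(sprintf(
      "gaps cover %.0f%% of the period (coverage %.0f%%, tolerated %.0f%%)",
      100 * (1 - coverage), 100 * coverage, 100 * (1 - max_gap_fraction)),
      call. = FALSE)
  }
  # clip to the period, interpolating the boundary values
  vt <- stats::approx(t, v, xout = c(period[1L], ti, period[2L]),
                      rule = 2)$y
  trapz_integral(c(period[1L], ti, period[2L]), vt)
}

#' Relative band-power change between two windows
#'
#' `100 * (test - ref) / ref` per band, plus the 2--120 Hz total.
#'
#' @param power_ref,power_test [band_power()] summaries over the same band
#'   set.
#' @return Data frame `name`, `power_ref`, `power_test`, `change_pct`
#'   (bands plus a `total` row).  A band with zero reference power yields
#'   `NA` and a warning.
#' @export
power_change <- function(power_ref, power_test) {
  stopifnot(inherits(power_ref, "band_power_summary"),
            inherits(power_test, "band_power_summary"))
  if (!identical(power_ref$name, power_test$name)) {
    stop("band sets differ between the two summaries", call. = FALSE)
  }
  ref <- c(power_ref$power, attr(power_ref, "total_power"))
  test <- c(power_test$power, attr(power_test, "total_power"))
  change <- ifelse(ref > 0, 100 * (test - ref) / ref, NA_real_)
  if (any(ref <= 0)) {
    warning("zero reference power in at least one band; change undefined",
            call. = FALSE)
  }
  data.frame(name = c(power_ref$name, "total"),
             power_ref = ref, power_test = test, change_pct = change,
             stringsAsFactors = FALSE)
}

#' vRBC fraction of baseline at SD onset
#'
#' Smoothed velocity at each SD onset divided by the baseline vRBC of the
#' segmentation.  An onset falling in a data gap wider than `max_gap_s`
#' (no sample within `max_gap_s / 2`) is flagged undefined (`NA`).
#'
#' @param trace A [velocity_trace()].
#' @param segmentation A [segment_periods()] result.
#' @param sds SD event table ([detect_sds()]) or numeric onset times.
#' @param smooth_s Running-median window in seconds (matching the
#'   segmentation default).
#' @param max_gap_s Gap width beyond which the fraction is undefined.
#' @return Numeric vector of fractions, one per SD.
#' @export
vrbc_fraction_at_onset <- function(trace, segmentation, sds, smooth_s = 30,
                                   max_gap_s = 10) {
  stopifnot(inherits(trace, "velocity_trace"),
            inherits(segmentation, "period_segmentation"))
  onsets <- if (is.data.frame(sds)) sds$onset_s else as.numeric(sds)
  ok <- is.finite(trace$v_mm_s)
  t <- trace$time_s[ok]; v <- trace$v_mm_s[ok]
  dt <- stats::median(diff(t))
  sm <- moving_median(v, smooth_s / dt)
  vapply(onsets, function(on) {
    if (on < t[1L] || on > t[length(t)]) return(NA_real_)
    nearest <- min(abs(t - on))
    if (nearest > max_gap_s / 2) return(NA_real_)
    stats::approx(t, sm, xout = on, rule = 2)$y / segmentation$baseline_vrbc
  }, numeric(1))
}
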