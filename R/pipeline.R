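#' Run the full neurovascular analysis on one experiment
#'
#' Chains the pipeline stages: LS-PIV velocity estimation (when a kymograph
#' is supplied) and quality filtering, period segmentation, SD and PIP
#' detection on the raw LFP, per-period band power and power changes, and
#' report assembly.
#'
#' @param lfp Raw DC-coupled [lfp_trace()].
#' @param kymo Optional [kymograph()]; either `kymo` or `velocity` must be
#'   given.
#' @param velocity Optional precomputed [velocity_trace()].
#' @param injection_time ET-1 injection time in seconds.
#' @param baseline_window LFP baseline window `c(start_s, end_s)`; defaults
#'   to the 60 s preceding the injection.
#' @param window_lines,overlap_fraction,min_quality LS-PIV parameters.
#' @param combine PIP band-combination policy.
#' @param power_window_s Length of the per-period power windows in seconds
#'   (clipped to the available period).
#' @return An `nv_report` (see [build_report()]), with the intermediate
#'   `velocity`, `segmentation`, `sds` and `pips` attached as attributes.
#' @export
analyze_experiment <- function(lfp, kymo = NULL, velocity = NULL,
                               injection_time,
                               baseline_window = NULL,
                               window_lines = 32, overlap_fraction = 0.5,
                               min_quality = 0.3,
                               combine = "either_band",
                               power_window_s = 120) {
  stopifnot(inherits(lfp, "lfp_trace"))
  if (is.null(velocity)) {
    if (is.null(kymo)) stop("supply a kymograph or a velocity trace", call. = FALSE)
    velocity <- estimate_velocity(kymo, window_lines = window_lines,
                                  overlap_fraction = overlap_fraction)
    velocity <- quality_filter(velocity, min_quality)
  }
  baseline_window <- baseline_window %||%
    c(max(lfp$t0, injection_time - 60), injection_time)

  segmentation <- segment_periods(velocity, injection_time)
  sds <- detect_sds(lfp, baseline_window = baseline_window,
                    injection_time = injection_time)
  pips <- detect_pips(lfp, baseline_window = baseline_window,
                      combine = combine)

  power_changes <- NULL
  t_end <- lfp$t0 + length(lfp$samples) / lfp$fs
  pick_window <- function(period) {
    if (is.null(period)) return(NULL)
    w <- c(max(period[1L], lfp$t0), min(period[2L], t_end))
    if (diff(w) < 2) return(NULL)
    c(w[1L], min(w[2L], w[1L] + power_window_s))
  }
  wb <- pick_window(segmentation$baseline)
  wi <- pick_window(segmentation$ischemia)
  wr <- pick_window(segmentation$partial_recovery)
  if (!is.null(wb)) {
    pre <- preprocess_for_power(lfp)
    p_base <- suppress_short_window(band_power(pre, wb))
    if (!is.null(wi)) {
      power_changes <- list(
        ischemia_vs_baseline =
          power_change(p_base, suppress_short_window(band_power(pre, wi))))
    }
    if (!is.null(wr)) {
      power_changes <- c(power_changes, list(
        recovery_vs_baseline =
          power_change(p_base, suppress_short_window(band_power(pre, wr)))))
    }
  }

  report <- build_report(velocity, segmentation, sds, pips,
                         power_changes = power_changes,
                         injection_time = injection_time)
  attr(report, "velocity") <- velocity
  attr(report, "segmentation") <- segmentation
  attr(report, "sds") <- sds
  attr(report, "pips") <- pips
  report
}

suppress_short_window <- function(expr) {
  withCallingHandlers(expr, nv_short_window = function(w)
    invokeRestart("muffleWarning"))
}
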