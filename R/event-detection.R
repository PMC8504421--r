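#' Baseline statistics of a smoothed LFP segment
#'
#' SD detection operates on a lightly smoothed copy of the raw DC-coupled
#' trace (0.5 s moving average by default: SDs are multi-second DC events
#' and full-rate noise would chatter the threshold).  Baseline mean and SD
#' are therefore computed on the same smoothed series over an event-free
#' window.
#'
#' @param trace An [lfp_trace()].
#' @param window `c(start_s, end_s)` event-free baseline window.
#' @param smooth_s Moving-average length in seconds.
#' @return List with `mean`, `sd` (mV) and `window`.
#' @export
baseline_stats <- function(trace, window, smooth_s = 0.5) {
  stopifnot(inherits(trace, "lfp_trace"))
  idx <- window_indices(trace, window, "baseline_window")
  sm <- moving_average(trace$samples, smooth_s * trace$fs)
  list(mean = mean(sm[idx]), sd = stats::sd(sm[idx]), window = window)
}

#' Detect spreading depolarizations in a raw DC-coupled trace
#'
#' Implements the SD rule as a state machine on the smoothed trace: a
#' candidate opens when the trace drops below
#' `baseline_mean - threshold_k * baseline_sd`; it is confirmed once the
#' sub-threshold condition has persisted for more than `persist_s` seconds;
#' it closes when the trace recovers to `recovery_fraction` of the baseline
#' mean (i.e. rises to at least `0.8 * baseline_mean` for a positive
#' baseline).  After closure the baseline statistics are re-estimated from
#' the immediately following post-event segment before detection resumes,
#' so a second SD on a shifted baseline is still found.  Event amplitude is
#' the positive magnitude of the deflection measured on the raw trace:
#' `baseline_mean - min(raw)` within the event.
#'
#' @param trace Raw, unfiltered [lfp_trace()] (DC preserved).
#' @param baseline_window `c(start_s, end_s)` event-free window used for the
#'   initial baseline; detection starts at its end.
#' @param baseline Optional explicit baseline as `list(mean =, sd =)` in mV,
#'   overriding estimation from `baseline_window`.
#' @param threshold_k Threshold in baseline SDs (default 10).
#' @param persist_s Minimum sub-threshold persistence in seconds (default
#'   10; strictly greater than).
#' @param recovery_fraction Recovery level as a fraction of baseline mean.
#' @param smooth_s Pre-detection smoothing window in seconds.
#' @param rebaseline_s Length of the post-event segment used to re-estimate
#'   the baseline.
#' @param injection_time Optional ET-1 injection time (s) used to fill the
#'   `delay_min` column.
#' @return Data frame of class `sd_events`: `onset_s`, `end_s`,
#'   `duration_s`, `amplitude_mV`, `auc_mV_min`, `baseline_mean_mV`,
#'   `baseline_sd_mV`, `delay_min`, `location`, `truncated`.  An event still
#'   open at the end of the trace is emitted with `end_s` at the trace end
#'   and `truncated = TRUE`.
#' @export
detect_sds <- function(trace, baseline_window = NULL, baseline = NULL,
                       threshold_k = 10, persist_s = 10,
                       recovery_fraction = 0.8, smooth_s = 0.5,
                       rebaseline_s = 10, injection_time = NA_real_) {
  stopifnot(inherits(trace, "lfp_trace"))
  fs <- trace$fs
  x <- trace$samples
  n <- length(x)
  t <- lfp_time(trace)
  sm <- moving_average(x, smooth_s * fs)

  if (is.null(baseline)) {
    if (is.null(baseline_window)) baseline_window <- c(t[1L], min(t[1L] + 60, t[n]))
    bl <- baseline_stats(trace, baseline_window, smooth_s)
    scan_from <- max(window_indices(trace, baseline_window, "baseline_window")) + 1L
  } else {
    bl <- baseline
    scan_from <- 1L
  }
  if (!is.finite(bl$sd) || bl$sd <= 0) {
    stop("baseline sd is zero; cannot form the detection threshold",
         call. = FALSE)
  }

  persist_n <- as.integer(round(persist_s * fs))
  events <- list()
  pos <- scan_from
  b_mean <- bl$mean; b_sd <- bl$sd

  while (pos <= n) {
    thr <- b_mean - threshold_k * b_sd
    seg <- sm[pos:n]
    runs <- true_runs(seg < thr)
    runs <- runs[runs$end - runs$start + 1L > persist_n, , drop = FALSE]
    if (nrow(runs) == 0L) break
    onset_i <- pos + runs$start[1L] - 1L
    rec <- which(sm[onset_i:n] >= recovery_fraction * b_mean)
    # recovery closes the event any time after it is confirmed (i.e. after
    # the >persist_s sub-threshold qualification), even if the trace is
    # still below the candidate threshold: the two levels can be ordered
    # either way depending on the baseline variability
    rec <- rec[rec > persist_n]
    truncated <- length(rec) == 0L
    end_i <- if (truncated) n else onset_i + rec[1L] - 1L
    amp <- b_mean - min(x[onset_i:end_i])
    auc <- deflection_auc(t[onset_i:end_i], x[onset_i:end_i], b_mean)
    events[[length(events) + 1L]] <- data.frame(
      onset_s = t[onset_i], end_s = t[end_i],
      duration_s = t[end_i] - t[onset_i],
      amplitude_mV = amp, auc_mV_min = auc,
      baseline_mean_mV = b_mean, baseline_sd_mV = b_sd,
      delay_min = (t[onset_i] - injection_time) / 60,
      location = "unknown", truncated = truncated,
      stringsAsFactors = FALSE)
    if (truncated) break
    # re-baseline on the post-event segment
    rb_end <- min(n, end_i + as.integer(round(rebaseline_s * fs)))
    if (rb_end - end_i + 1L >= as.integer(fs)) {
      new_mean <- mean(sm[end_i:rb_end])
      new_sd <- stats::sd(sm[end_i:rb_end])
      b_mean <- new_mean
      if (is.finite(new_sd) && new_sd > 0) b_sd <- new_sd
    }
    pos <- rb_end + 1L
  }

  out <- if (length(events)) do.call(rbind, events) else data.frame(
    onset_s = numeric(), end_s = numeric(), duration_s = numeric(),
    amplitude_mV = numeric(), auc_mV_min = numeric(),
    baseline_mean_mV = numeric(), baseline_sd_mV = numeric(),
    delay_min = numeric(), location = character(), truncated = logical(),
    stringsAsFactors = FALSE)
  class(out) <- c("sd_events", "data.frame")
  out
}

# Trapezoidal integral of the positive deflection below baseline, mV*min.
deflection_auc <- function(t, x, baseline_mean) {
  trapz_integral(t, pmax(0, baseline_mean - x)) / 60
}

#' Area under the curve of one SD event
#'
#' Trapezoidal integral of `max(0, baseline_mean - trace)` over
#' `[onset, end]`, reported in mV*min.
#'
#' @param event One-row data frame with `onset_s` and `end_s` (as produced
#'   by [detect_sds()]), or a numeric `c(onset_s, end_s)` pair.
#' @param trace Raw [lfp_trace()].
#' @param baseline_mean Baseline mean in mV.
#' @return AUC in mV*min.
#' @export
sd_auc <- function(event, trace, baseline_mean) {
  stopifnot(inherits(trace, "lfp_trace"))
  win <- if (is.data.frame(event)) c(event$onset_s[1L], event$end_s[1L])
         else as.numeric(event)
  if (win[2L] <= win[1L]) return(0)
  idx <- window_indices(trace, win, "event window")
  t <- lfp_time(trace)
  deflection_auc(t[idx], trace$samples[idx], baseline_mean)
}

#' Detect post-ischemic potentials (PIPs)
#'
#' For each of the theta and alpha bands, thresholds the band-wise
#' continuous wavelet magnitude series ([cwt_band_series()]) at the
#' baseline mean plus `z_thresh` baseline SDs of that series;
#' supra-threshold runs longer than `min_duration_s` become events.  Events
#' from the two bands are then merged according to `combine`:
#' `"either_band"` keeps every event from either band, `"both_bands"` keeps
#' only events corroborated by an overlapping event in the other band.
#' Overlapping events (or events closer than `merge_gap_s`) are merged and
#' their band sets unioned.  Because the series derives from the
#' preprocessed (high-passed) trace, detection is invariant to a trace-wide
#' DC offset.
#'
#' @param trace An [lfp_trace()] (raw; preprocessing is applied internally).
#' @param baseline_window `c(start_s, end_s)` event-free baseline window of
#'   at least 10 s.
#' @param combine Band combination policy.
#' @param bands Band definitions; rows named `theta` and `alpha` are used.
#' @param z_thresh Threshold in baseline SDs of the magnitude series.
#' @param min_duration_s Minimum event duration in seconds (strictly
#'   greater than).
#' @param merge_gap_s Events separated by less than this are merged.
#' @return Data frame of class `pip_events`: `onset_s`, `end_s`,
#'   `duration_s`, `bands` (comma-joined), `peak_z`.
#' @export
detect_pips <- function(trace, baseline_window,
                        combine = c("either_band", "both_bands"),
                        bands = default_bands(), z_thresh = 2,
                        min_duration_s = 2, merge_gap_s = 0.5) {
  stopifnot(inherits(trace, "lfp_trace"))
  combine <- match.arg(combine)
  if (diff(baseline_window) < 10) {
    stop("baseline window shorter than 10 s gives unstable statistics",
         call. = FALSE)
  }
  pre <- preprocess_for_power(trace)

  per_band <- lapply(c("theta", "alpha"), function(bn) {
    series <- cwt_band_series(pre, get_band(bands, bn))
    tt <- series$time_s
    eps <- 0.5 / attr(series, "fs_out")
    bi <- tt >= baseline_window[1L] - eps & tt <= baseline_window[2L] + eps
    if (!any(bi)) stop("baseline window outside the trace", call. = FALSE)
    m <- mean(series$magnitude[bi]); s <- stats::sd(series$magnitude[bi])
    if (!is.finite(s) || s <= 0) {
      stop("degenerate baseline in ", bn, " band series", call. = FALSE)
    }
    z <- (series$magnitude - m) / s
    runs <- true_runs(z > z_thresh)
    if (nrow(runs)) {
      # The supra-threshold run defines the candidate; for strong bursts the
      # fixed 2-SD level sits deep in the wavelet magnitude tail and smears
      # the run well beyond the oscillation, so boundaries are refined at
      # half the event's peak z (a no-op when the peak is near threshold).
      ref <- lapply(seq_len(nrow(runs)), function(i) {
        seg <- runs$start[i]:runs$end[i]
        pk <- max(z[seg])
        thr <- max(z_thresh, pk / 2)
        ipk <- seg[which.max(z[seg])]
        above <- z[seg] >= thr
        sub <- true_runs(above)
        sub <- sub[sub$start <= (ipk - seg[1L] + 1L) &
                     sub$end >= (ipk - seg[1L] + 1L), , drop = FALSE]
        a <- seg[sub$start[1L]]; b <- seg[sub$end[1L]]
        data.frame(onset_s = tt[a], end_s = tt[b], band = bn, peak_z = pk,
                   stringsAsFactors = FALSE)
      })
      ev <- do.call(rbind, ref)
      ev <- ev[ev$end_s - ev$onset_s > min_duration_s, , drop = FALSE]
      ev
    } else {
      data.frame(onset_s = numeric(), end_s = numeric(), band = character(),
                 peak_z = numeric(), stringsAsFactors = FALSE)
    }
  })
  names(per_band) <- c("theta", "alpha")

  pool <- do.call(rbind, per_band)
  if (combine == "both_bands" && nrow(pool)) {
    keep <- vapply(seq_len(nrow(pool)), function(i) {
      other <- per_band[[setdiff(c("theta", "alpha"), pool$band[i])]]
      any(other$onset_s < pool$end_s[i] & other$end_s > pool$onset_s[i])
    }, logical(1))
    pool <- pool[keep, , drop = FALSE]
  }

  out <- merge_pip_events(pool, merge_gap_s)
  class(out) <- c("pip_events", "data.frame")
  out
}

merge_pip_events <- function(pool, merge_gap_s) {
  empty <- data.frame(onset_s = numeric(), end_s = numeric(),
                      duration_s = numeric(), bands = character(),
                      peak_z = numeric(), stringsAsFactors = FALSE)
  if (is.null(pool) || nrow(pool) == 0L) return(empty)
  pool <- pool[order(pool$onset_s), , drop = FALSE]
  merged <- list()
  cur <- list(onset = pool$onset_s[1L], end = pool$end_s[1L],
              bands = pool$band[1L], peak_z = pool$peak_z[1L])
  flush <- function(cur) data.frame(
    onset_s = cur$onset, end_s = cur$end, duration_s = cur$end - cur$onset,
    bands = paste(sort(unique(cur$bands)), collapse = ","),
    peak_z = cur$peak_z, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pool))[-1L]) {
    if (pool$onset_s[i] < cur$end + merge_gap_s) {
      cur$end <- max(cur$end, pool$end_s[i])
      cur$bands <- c(cur$bands, pool$band[i])
      cur$peak_z <- max(cur$peak_z, pool$peak_z[i])
    } else {
      merged[[length(merged) + 1L]] <- flush(cur)
      cur <- list(onset = pool$onset_s[i], end = pool$end_s[i],
                  bands = pool$band[i], peak_z = pool$peak_z[i])
    }
  }
  merged[[length(merged) + 1L]] <- flush(cur)
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Count SD events per recording location
#'
#' @param events_by_channel Named list mapping channel id to an SD event
#'   table ([detect_sds()] output).
#' @param channel_locations Named character vector mapping channel id to
#'   `"injection_site"` or `"peri_injection"`.  Channels without a tag have
#'   their events labeled `"unknown"` and excluded from the counts, with a
#'   warning.
#' @return List with `counts` (named integer vector over locations) and
#'   `events` (combined table with `channel` and `location` filled in).
#' @export
classify_event_locations <- function(events_by_channel, channel_locations) {
  stopifnot(is.list(events_by_channel))
  known <- c("injection_site", "peri_injection")
  all_events <- list()
  counts <- stats::setNames(integer(length(known)), known)
  for (ch in names(events_by_channel)) {
    ev <- events_by_channel[[ch]]
    if (is.null(ev) || nrow(ev) == 0L) next
    loc <- unname(channel_locations[ch])
    if (is.na(loc) || !loc %in% known) {
      warning("channel '", ch, "' has no location tag; its events are ",
              "labeled unknown and excluded from the counts", call. = FALSE)
      loc <- "unknown"
    } else {
      counts[loc] <- counts[loc] + nrow(ev)
    }
    ev$location <- loc
    ev$channel <- ch
    all_events[[length(all_events) + 1L]] <- ev
  }
  events <- if (length(all_events)) do.call(rbind, all_events) else NULL
  list(counts = counts, events = events)
}

#' Write a detected event table as CSV
#'
#' Serializes SD or PIP event tables with a shared column layout
#' (`type`, `onset_s`, `end_s`, `duration_s`, `amplitude_mV`,
#' `auc_mV_min`, `bands`, `location`, `truncated`).
#'
#' @param events An `sd_events` or `pip_events` data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  type <- if (inherits(events, "pip_events")) "pip" else "sd"
  n <- nrow(events)
  get0c <- function(col, default) {
    if (col %in% names(events)) events[[col]] else rep(default, n)
  }
  utils::write.csv(data.frame(
    type = rep(type, n),
    onset_s = get0c("onset_s", NA_real_),
    end_s = get0c("end_s", NA_real_),
    duration_s = get0c("duration_s", NA_real_),
    amplitude_mV = get0c("amplitude_mV", NA_real_),
    auc_mV_min = get0c("auc_mV_min", NA_real_),
    bands = get0c("bands", NA_character_),
    location = get0c("location", NA_character_),
    truncated = get0c("truncated", FALSE),
    stringsAsFactors = FALSE), path, row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' @param path CSV path.
#' @param type Optional filter, `"sd"` or `"pip"`.
#' @return Event data frame (classed `sd_events` / `pip_events` when
#'   filtered).
#' @export
read_events <- function(path, type = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(type)) {
    d <- d[d$type == type, , drop = FALSE]
    rownames(d) <- NULL
    class(d) <- c(if (type == "pip") "pip_events" else "sd_events",
                  "data.frame")
  }
  d
}
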