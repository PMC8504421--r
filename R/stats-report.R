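#' Chi-squared goodness-of-fit test against a uniform distribution
#'
#' Tests observed event counts (e.g. SDs at the injection site versus the
#' peri-injection zone) against the null hypothesis of uniform probability
#' across locations: statistic `sum((o - e)^2 / e)` with `e = total / k`,
#' `df = k - 1`, p-value from the chi-squared survival function.
#'
#' @param counts Non-negative integer counts, total > 0.
#' @param exact If `TRUE`, the p-value is computed by exhaustive
#'   enumeration of the uniform multinomial distribution
#'   (`P(X^2 >= observed)`) instead of the asymptotic chi-squared survival
#'   function.  Only sensible for small totals; the asymptotic p can differ
#'   substantially from the exact one at such sample sizes.
#' @return List of class `nv_test`: `statistic`, `df`, `p_value`, `method`.
#' @export
#' @examples
#' chi_squared_uniform(c(39, 18))
chi_squared_uniform <- function(counts, exact = FALSE) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L || any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be >= 0 with at least two categories", call. = FALSE)
  }
  if (sum(counts) == 0) stop("total count is zero", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts))
  p <- unname(ht$p.value)
  method <- "chi-squared goodness of fit (uniform)"
  if (exact) {
    p <- exact_uniform_p(counts)
    method <- paste(method, "- exact enumeration")
  }
  structure(list(statistic = unname(ht$statistic),
                 df = as.integer(ht$parameter),
                 p_value = p,
                 method = method),
            class = "nv_test")
}

# Exhaustive enumeration of P(X^2 >= observed) under a uniform multinomial:
# walk every composition of the total over k cells.
exact_uniform_p <- function(counts) {
  k <- length(counts)
  n <- sum(counts)
  if (n > 40 || k > 4) {
    stop("exact enumeration is limited to small tables (total <= 40, k <= 4)",
         call. = FALSE)
  }
  e <- n / k
  obs <- sum((counts - e)^2 / e)
  p <- 0
  rec <- function(cell, remaining, acc, logprob) {
    if (cell == k) {
      stat <- acc + (remaining - e)^2 / e
      if (stat >= obs - 1e-12) {
        p <<- p + exp(logprob - lfactorial(remaining))
      }
      return(invisible())
    }
    for (x in 0:remaining) {
      rec(cell + 1L, remaining - x, acc + (x - e)^2 / e,
          logprob - lfactorial(x))
    }
  }
  rec(1L, n, 0, lfactorial(n) - n * log(k))
  min(1, p)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List of class `nv_test`: `statistic` (r), `df` (n - 2),
#'   `p_value` (two-sided), `method`.
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  structure(list(statistic = unname(ht$estimate),
                 df = as.integer(ht$parameter),
                 p_value = unname(ht$p.value),
                 method = "Pearson correlation"),
            class = "nv_test")
}

#' @export
print.nv_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %d, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Assemble the per-experiment report
#'
#' Collects the period segmentation, per-period vRBC statistics and RBC
#' distances, the SD and PIP event tables, SD-location counts with the
#' uniform chi-squared test, band-power changes, and — when a multi-
#' experiment cohort table is supplied — the total-SD-AUC versus PIP-count
#' correlation.  The report is a plain list serializable to JSON with
#' [write_report()]; regenerating it from identical inputs yields an
#' identical document.
#'
#' @param velocity A [velocity_trace()].
#' @param segmentation A [segment_periods()] result.
#' @param sds SD event table ([detect_sds()]).
#' @param pips PIP event table ([detect_pips()]).
#' @param power_changes Optional [power_change()] table(s), named by
#'   comparison.
#' @param location_counts Optional named counts of SDs per location for the
#'   chi-squared test.
#' @param cohort Optional data frame with per-experiment columns
#'   `sd_auc_total` and `pip_count` (>= 3 rows) for the AUC--PIP
#'   correlation.
#' @param injection_time Injection time in seconds (metadata).
#' @return List of class `nv_report`.
#' @export
build_report <- function(velocity, segmentation, sds, pips,
                         power_changes = NULL, location_counts = NULL,
                         cohort = NULL, injection_time = NA_real_) {
  stopifnot(inherits(segmentation, "period_segmentation"))
  if (!is.na(injection_time) &&
      (injection_time < min(velocity$time_s) ||
       injection_time > max(velocity$time_s))) {
    stop("injection_time lies outside the velocity time base", call. = FALSE)
  }

  period_stats <- function(period) {
    if (is.null(period)) return(NULL)
    sel <- velocity$time_s >= period[1L] & velocity$time_s <= period[2L] &
      is.finite(velocity$v_mm_s)
    list(window_s = period,
         mean_v_mm_s = if (any(sel)) mean(velocity$v_mm_s[sel]) else NA_real_,
         rbc_distance_mm = tryCatch(rbc_distance(velocity, period),
                                    error = function(e) NA_real_))
  }

  chi <- if (!is.null(location_counts) && sum(location_counts) > 0) {
    unclass(chi_squared_uniform(location_counts))
  } else list(not_applicable = TRUE)

  auc_pip <- if (!is.null(cohort) && nrow(cohort) >= 3L &&
                 stats::var(cohort$sd_auc_total) > 0 &&
                 stats::var(cohort$pip_count) > 0) {
    unclass(pearson_correlation(cohort$sd_auc_total, cohort$pip_count))
  } else list(not_applicable = TRUE)

  report <- list(
    schema_version = "1.0",
    injection_time_s = injection_time,
    periods = list(
      baseline = period_stats(segmentation$baseline),
      ischemia = period_stats(segmentation$ischemia),
      partial_recovery = period_stats(segmentation$partial_recovery)),
    peak_drop_time_s = segmentation$peak_drop_time,
    baseline_vrbc_mm_s = segmentation$baseline_vrbc,
    recovery_absent = segmentation$recovery_absent,
    sd_events = as.data.frame(sds),
    pip_events = as.data.frame(pips),
    sd_count = nrow(sds),
    pip_count = nrow(pips),
    sd_total_auc_mV_min = if (nrow(sds)) sum(sds$auc_mV_min) else 0,
    vrbc_fraction_at_sd_onset = if (nrow(sds))
      vrbc_fraction_at_onset(velocity, segmentation, sds) else numeric(0),
    location_counts = as.list(location_counts),
    location_chi_squared = chi,
    auc_pip_correlation = auc_pip,
    power_changes = power_changes)
  class(report) <- "nv_report"
  report
}

#' Serialize a report to JSON
#'
#' @param report An [build_report()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "nv_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' @export
print.nv_report <- function(x, ...) {
  cat("<nv_report>\n")
  cat(sprintf("  baseline vRBC %.2f mm/s | peak drop @ %.1f s\n",
              x$baseline_vrbc_mm_s, x$peak_drop_time_s))
  for (p in names(x$periods)) {
    ps <- x$periods[[p]]
    if (is.null(ps)) {
      cat(sprintf("  %-16s absent\n", p))
    } else {
      cat(sprintf("  %-16s [%.1f, %.1f] s | mean v %.2f mm/s | distance %.1f mm\n",
                  p, ps$window_s[1L], ps$window_s[2L], ps$mean_v_mm_s,
                  ps$rbc_distance_mm))
    }
  }
  cat(sprintf("  SDs: %d (total AUC %.2f mV*min) | PIPs: %d\n",
              x$sd_count, x$sd_total_auc_mV_min, x$pip_count))
  if (length(x$vrbc_fraction_at_sd_onset)) {
    cat("  vRBC fraction at SD onsets:",
        paste(sprintf("%.2f", x$vrbc_fraction_at_sd_onset), collapse = ", "),
        "\n")
  }
  invisible(x)
}
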