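test_that("quiet traces and sub-threshold deflections yield no SD", {
  g <- generate_lfp(200, fs = 500, baseline_mean = 4, baseline_sd = 0.1,
                    seed = 1)
  expect_identical(nrow(detect_sds(g$trace, c(0, 60))), 0L)

  # 9 x baseline-sd for 60 s: below the 10-SD detection threshold
  fs <- 500
  x <- rep(4, 200 * fs)
  x[(100 * fs):(160 * fs)] <- 4 - 9 * 0.2
  ev <- detect_sds(lfp_trace(x, fs = fs), baseline = list(mean = 4, sd = 0.2))
  expect_identical(nrow(ev), 0L)
})

test_that("a deep deflection is measured against generator truth", {
  g <- generate_lfp(300, fs = 500, baseline_mean = 4, baseline_sd = 0.1,
                    sd_specs = data.frame(onset_s = 100, amplitude_mV = 20,
                                          duration_s = 60), seed = 3)
  ev <- detect_sds(g$trace, c(0, 60))
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$amplitude_mV - 20), 3 * 0.1 + 0.3)
  expect_lt(abs(ev$duration_s - 60), 2)
  expect_false(ev$truncated)
})

test_that("a trace that never recovers is emitted truncated", {
  fs <- 250
  x <- c(rep(4, 60 * fs), rep(4, 10 * fs), rep(-16, 100 * fs))
  x <- x + stats::rnorm(length(x), 0, 0.05)
  ev <- detect_sds(lfp_trace(x, fs = fs), c(0, 60))
  expect_identical(nrow(ev), 1L)
  expect_true(ev$truncated)
  expect_equal(ev$end_s, length(x) / fs, tolerance = 0.01)
})

test_that("detection re-baselines after each event (two-SD staircase)", {
  fs <- 250
  # first SD recovers to a shifted baseline (3.4 mV, above the 80% closure
  # level of the original 4 mV); the second SD is referenced to the new one
  seg <- c(rep(4, 70 * fs), rep(4 - 15, 40 * fs), rep(3.4, 60 * fs),
           rep(3.4 - 12, 40 * fs), rep(3.4, 60 * fs))
  x <- seg + stats::rnorm(length(seg), 0, 0.05)
  ev <- detect_sds(lfp_trace(x, fs = fs), c(0, 60))
  expect_identical(nrow(ev), 2L)
  expect_lt(abs(ev$amplitude_mV[1] - 15), 0.5)
  # second amplitude measured against the re-estimated 3 mV baseline
  expect_lt(abs(ev$amplitude_mV[2] - 12), 0.5)
  expect_lt(abs(ev$baseline_mean_mV[2] - 3.4), 0.2)
})

test_that("zero baseline variability is rejected", {
  tr <- lfp_trace(rep(4, 30000), fs = 500)
  expect_error(detect_sds(tr, c(0, 30)), "baseline sd is zero")
})

test_that("sd_auc integrates rectangles and trapezoids exactly", {
  fs <- 100
  # rectangle: 12 mV for 2 min
  x <- rep(4, 400 * fs)
  x[(100 * fs):(220 * fs)] <- 4 - 12
  tr <- lfp_trace(x, fs = fs)
  ev <- data.frame(onset_s = 100, end_s = 220)
  expect_equal(sd_auc(ev, tr, 4), 24, tolerance = 0.01)
  # degenerate zero-duration event
  expect_identical(sd_auc(data.frame(onset_s = 50, end_s = 50), tr, 4), 0)
  # trapezoid with 20 s linear ramps and 80 s plateau at 10 mV:
  # area = 10 * (80 + 100) / 2 / 60 mV*min... computed in closed form below
  t <- (seq_len(300 * fs) - 1) / fs
  # ramps 100-120 up, plateau 120-200 at 10 mV, down 200-220
  d <- pmin((t - 100) / 20, 1, (220 - t) / 20)
  d[t < 100 | t > 220] <- 0
  tr2 <- lfp_trace(4 - 10 * d, fs = fs)
  area_closed_form <- 10 * ((220 - 100) + (200 - 120)) / 2 / 60
  expect_equal(sd_auc(data.frame(onset_s = 100, end_s = 220), tr2, 4),
               area_closed_form, tolerance = 0.01 * area_closed_form)
})

test_that("PIP bursts are detected with the >2 s rule", {
  fs <- 500
  t <- seq(1 / fs, 300, by = 1 / fs)
  noise <- withr::with_seed(21, stats::rnorm(length(t), 0, 0.05))

  burst3 <- 4 * 0.05 * sqrt(2) * ifelse(t >= 150 & t <= 153, 1, 0) *
    sin(2 * pi * 6 * t)
  ev <- detect_pips(lfp_trace(4 + noise + burst3, fs = fs), c(0, 60))
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$duration_s - 3), 0.5)
  expect_match(ev$bands, "theta")
  expect_gt(ev$peak_z, 2)

  burst1 <- 4 * 0.05 * sqrt(2) * ifelse(t >= 150 & t <= 151, 1, 0) *
    sin(2 * pi * 6 * t)
  expect_identical(
    nrow(detect_pips(lfp_trace(4 + noise + burst1, fs = fs), c(0, 60))), 0L)
})

test_that("PIP detection ignores a trace-wide DC offset", {
  fs <- 500
  t <- seq(1 / fs, 200, by = 1 / fs)
  noise <- withr::with_seed(22, stats::rnorm(length(t), 0, 0.05))
  burst <- 4 * 0.05 * sqrt(2) * ifelse(t >= 100 & t <= 103, 1, 0) *
    sin(2 * pi * 8 * t)
  a <- detect_pips(lfp_trace(4 + noise + burst, fs = fs), c(0, 60))
  b <- detect_pips(lfp_trace(42 + noise + burst, fs = fs), c(0, 60))
  expect_equal(a$onset_s, b$onset_s)
  expect_equal(a$duration_s, b$duration_s)
})

test_that("the both_bands policy requires corroboration across bands", {
  fs <- 500
  t <- seq(1 / fs, 200, by = 1 / fs)
  noise <- withr::with_seed(23, stats::rnorm(length(t), 0, 0.05))
  theta_only <- 4 * 0.05 * sqrt(2) * ifelse(t >= 100 & t <= 103, 1, 0) *
    sin(2 * pi * 5 * t)
  tr <- lfp_trace(4 + noise + theta_only, fs = fs)
  expect_identical(nrow(detect_pips(tr, c(0, 60), combine = "either_band")), 1L)
  expect_identical(nrow(detect_pips(tr, c(0, 60), combine = "both_bands")), 0L)
})

test_that("a too-short PIP baseline window errors", {
  tr <- lfp_trace(rnorm(10000, 4, 0.05), fs = 500)
  expect_error(detect_pips(tr, c(0, 5)), "unstable")
})

test_that("events are counted per tagged location", {
  ev3 <- data.frame(onset_s = 1:3, end_s = 2:4)
  ev5 <- data.frame(onset_s = 1:5, end_s = 2:6)
  res <- classify_event_locations(
    list(ch1 = ev3, ch2 = ev5),
    c(ch1 = "injection_site", ch2 = "peri_injection"))
  expect_identical(res$counts,
                   c(injection_site = 3L, peri_injection = 5L))
  # empty inputs
  res0 <- classify_event_locations(list(), character())
  expect_true(all(res0$counts == 0L))
  # untagged channel: warned and excluded
  expect_warning(
    res2 <- classify_event_locations(list(chX = ev3), c(other = "injection_site")),
    "no location tag")
  expect_true(all(res2$counts == 0L))
  expect_identical(unique(res2$events$location), "unknown")
})

test_that("event tables round-trip through CSV", {
  g <- generate_lfp(300, fs = 250, baseline_mean = 4, baseline_sd = 0.1,
                    sd_specs = data.frame(onset_s = 100, amplitude_mV = 18,
                                          duration_s = 60), seed = 8)
  ev <- detect_sds(g$trace, c(0, 60))
  path <- file.path(withr::local_tempdir(), "events.csv")
  write_events(ev, path)
  back <- read_events(path, "sd")
  expect_equal(back$onset_s, ev$onset_s)
  expect_equal(back$auc_mV_min, ev$auc_mV_min)
})
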