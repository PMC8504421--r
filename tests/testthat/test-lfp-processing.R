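make_tone <- function(freq, dur = 30, fs = 1000, amp = 1, dc = 0) {
  t <- seq(1 / fs, dur, by = 1 / fs)
  lfp_trace(dc + amp * sin(2 * pi * freq * t), fs = fs)
}

test_that("preprocessing removes DC and the 60 Hz line, keeps the passband", {
  flat <- lfp_trace(rep(4, 5000), fs = 1000)
  expect_lt(max(abs(preprocess_for_power(flat)$samples)), 1e-9)

  hum <- make_tone(60)
  out <- preprocess_for_power(hum)
  expect_lt(mean(out$samples^2) / mean(hum$samples^2), 0.01)

  tone <- make_tone(20)
  out <- preprocess_for_power(tone)
  core <- 5000:25000  # avoid edges
  ratio <- sqrt(mean(out$samples[core]^2) / mean(tone$samples[core]^2))
  expect_lt(abs(ratio - 1), 0.05)

  expect_error(preprocess_for_power(lfp_trace(rnorm(100), fs = 100)),
               "too low")
})

test_that("preprocessing is idempotent in the passband", {
  tr <- make_tone(20, dur = 20)
  once <- preprocess_for_power(tr)
  twice <- preprocess_for_power(once)
  core <- 2000:18000
  expect_lt(sqrt(mean((twice$samples - once$samples)[core]^2)) /
              sqrt(mean(once$samples[core]^2)), 0.01)
})

test_that("band power concentrates a pure tone in its band", {
  bp <- expect_no_short_window_warning(
    band_power(make_tone(5), c(1, 29)))
  expect_gt(bp$power[bp$name == "theta"] / attr(bp, "total_power"), 0.95)

  zero <- lfp_trace(rep(0, 30000), fs = 1000)
  bp0 <- expect_no_short_window_warning(band_power(zero, c(1, 29)))
  expect_true(all(bp0$power == 0))
})

test_that("equal tones in different bands have equal power", {
  t <- seq(1 / 1000, 30, by = 1 / 1000)
  tr <- lfp_trace(sin(2 * pi * 5 * t) + sin(2 * pi * 40 * t), fs = 1000)
  bp <- expect_no_short_window_warning(band_power(tr, c(1, 29)))
  p <- bp$power
  expect_lt(abs(p[bp$name == "theta"] - p[bp$name == "low_gamma"]) /
              p[bp$name == "theta"], 0.02)
})

test_that("band powers partition the 2-120 Hz total (Parseval)", {
  set.seed(42)
  tr <- lfp_trace(rnorm(30000), fs = 1000)
  bp <- expect_no_short_window_warning(band_power(tr, c(1, 29)))
  expect_equal(sum(bp$power), attr(bp, "total_power"),
               tolerance = 0.01)
})

test_that("a boundary frequency is assigned to the lower band", {
  # the rule itself, on exact bin frequencies
  bands <- default_bands()
  expect_identical(
    neurovasc:::band_bin_assignment(c(2, 5, 10, 10.1, 15, 30, 80, 120, 121),
                                    bands),
    c(1L, 1L, 1L, 2L, 2L, 3L, 4L, 5L, 0L))
  # a 10 Hz tone lands mostly in theta (taper leakage spreads a little)
  bp <- expect_no_short_window_warning(band_power(make_tone(10), c(1, 29)))
  expect_gt(bp$power[bp$name == "theta"], 3 * bp$power[bp$name == "alpha"])
})

test_that("band_power validates its window and warns when short", {
  tr <- make_tone(5, dur = 150)
  expect_warning(band_power(tr, c(0.001, 30)), class = "nv_short_window")
  expect_silent(band_power(tr, c(0.001, 125)))
  expect_error(band_power(tr, c(100, 200)), "outside")
  expect_error(expect_no_short_window_warning(band_power(tr, c(0.001, 0.8))),
               "shorter than two periods")
})

test_that("the wavelet series localizes an in-band burst", {
  fs <- 1000
  t <- seq(1 / fs, 60, by = 1 / fs)
  theta <- get_band(default_bands(), "theta")

  # stationary tone: near-constant positive series
  tone <- lfp_trace(sin(2 * pi * 6 * t), fs = fs)
  cs <- cwt_band_series(tone, theta)
  core <- cs$magnitude[cs$time_s > 5 & cs$time_s < 55]
  expect_gt(min(core), 0.8 * max(core))

  # 3 s burst: elevated magnitude localized to the window +/- 0.5 s
  burst <- lfp_trace(ifelse(t >= 30 & t <= 33, sin(2 * pi * 6 * t), 0), fs = fs)
  cs <- cwt_band_series(burst, theta)
  sup <- range(cs$time_s[cs$magnitude > 0.5 * max(cs$magnitude)])
  expect_lt(abs(sup[1] - 30), 0.5)
  expect_lt(abs(sup[2] - 33), 0.5)

  # out-of-band tone: indistinguishable from silence away from the edges
  out <- cwt_band_series(lfp_trace(sin(2 * pi * 50 * t), fs = fs), theta)
  central <- out$magnitude[out$time_s > 5 & out$time_s < 55]
  expect_lt(max(central), 1e-4 * max(core))

  expect_error(
    cwt_band_series(lfp_trace(rnorm(1000), fs = 200),
                    get_band(default_bands(), "high_gamma")),
    "Nyquist")
})

test_that("the wavelet magnitude is linear in amplitude", {
  fs <- 1000
  t <- seq(1 / fs, 20, by = 1 / fs)
  theta <- get_band(default_bands(), "theta")
  base <- cwt_band_series(lfp_trace(sin(2 * pi * 6 * t), fs = fs), theta)
  big <- cwt_band_series(lfp_trace(100 * sin(2 * pi * 6 * t), fs = fs), theta)
  core <- base$time_s > 2 & base$time_s < 18
  ratio <- big$magnitude[core] / base$magnitude[core]
  expect_true(all(abs(ratio - 100) / 100 < 0.02))
})

test_that("band definitions come from YAML and are validated", {
  path <- file.path(withr::local_tempdir(), "bands.yaml")
  writeLines(c("theta: [2, 10]", "alpha: [10, 15]"), path)
  b <- bands_from_yaml(path)
  expect_identical(b$name, c("theta", "alpha"))
  expect_identical(b$f_high, c(10, 15))
  expect_error(band_definition("bad", 10, 5), "f_low < f_high")
})

test_that("LFP CSV round-trips", {
  tr <- make_tone(5, dur = 2)
  path <- file.path(withr::local_tempdir(), "lfp.csv")
  write_lfp(tr, path)
  back <- read_lfp(path)
  expect_equal(back$samples, tr$samples, tolerance = 1e-9)
  expect_equal(back$fs, tr$fs, tolerance = 1e-6)
})
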