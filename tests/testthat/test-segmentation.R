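# Piecewise trace with a drop at 600 s and an 80% re-crossing at 3300 s.
ramp_trace <- function(noise_sd = 0, seed = 1) {
  t <- seq(0, 3600, by = 1)
  v <- numeric(length(t))
  v[t < 540] <- 6
  drop <- t >= 540 & t < 600
  v[drop] <- 6 - (6 - 1.8) * (t[drop] - 540) / 60
  flat <- t >= 600 & t < 3240
  v[flat] <- 1.8 + 0.6 * (t[flat] - 600) / 2640
  rise <- t >= 3240 & t < 3360
  v[rise] <- 2.4 + (5.4 - 2.4) * (t[rise] - 3240) / 120  # crosses 4.8 at 3336
  v[t >= 3360] <- 5.4
  if (noise_sd > 0) v <- v + withr::with_seed(seed, rnorm(length(t), 0, noise_sd))
  velocity_trace(t, v)
}

test_that("period boundaries follow the drop and the 80% crossing", {
  tr <- ramp_trace()
  seg <- segment_periods(tr, injection_time = 540)
  expect_identical(seg$baseline, c(0, 540))
  expect_equal(seg$peak_drop_time, 600)
  expect_equal(seg$ischemia, c(600, 900))
  # noise-free crossing of 0.8 * 6 = 4.8 on the linear rise: t = 3336
  expect_equal(seg$partial_recovery[1], 3336, tolerance = 1)
  expect_false(seg$recovery_absent)
})

test_that("a constant trace has no ischemic drop", {
  t <- seq(0, 1000, by = 1)
  expect_error(segment_periods(velocity_trace(t, rep(6, length(t))), 500),
               "no ischemic drop")
})

test_that("a profile that never re-crosses 80% flags recovery absent", {
  t <- seq(0, 2000, by = 1)
  v <- ifelse(t < 600, 6, 2)
  seg <- segment_periods(velocity_trace(t, v), 600)
  expect_true(seg$recovery_absent)
  expect_null(seg$partial_recovery)
  expect_equal(seg$ischemia[2] - seg$ischemia[1], 300)
})

test_that("segmentation is invariant to uniform velocity rescaling", {
  tr <- ramp_trace(noise_sd = 0.1, seed = 3)
  seg1 <- segment_periods(tr, 540)
  tr2 <- velocity_trace(tr$time_s, tr$v_mm_s * 3.7, tr$quality)
  seg2 <- segment_periods(tr2, 540)
  expect_equal(seg1$peak_drop_time, seg2$peak_drop_time)
  expect_equal(seg1$ischemia, seg2$ischemia)
  expect_equal(seg1$partial_recovery, seg2$partial_recovery)
  expect_equal(seg2$baseline_vrbc / seg1$baseline_vrbc, 3.7, tolerance = 1e-9)
})

test_that("pre-injection coverage is required", {
  t <- seq(0, 500, by = 1)
  expect_error(segment_periods(velocity_trace(t, 6 - t / 100), 30),
               "pre-injection")
})

test_that("rbc_distance integrates velocity over the period", {
  t <- seq(0, 300, by = 0.5)
  expect_equal(rbc_distance(velocity_trace(t, rep(2, length(t))), c(0, 300)),
               600, tolerance = 1e-9)
  expect_identical(rbc_distance(velocity_trace(t, rep(0, length(t))),
                                c(0, 300)), 0)
  # the paper-mean ramp: 6 -> 2.6 mm/s over 300 s => (6+2.6)/2*300 = 1290 mm
  ramp <- velocity_trace(t, 6 - (6 - 2.6) * t / 300)
  expect_equal(rbc_distance(ramp, c(0, 300)), 1290, tolerance = 0.005 * 1290)
})

test_that("rbc_distance is additive over adjacent periods", {
  t <- seq(0, 600, by = 1)
  v <- 3 + sin(t / 40) + 0.3 * cos(t / 7)
  tr <- velocity_trace(t, v)
  expect_equal(rbc_distance(tr, c(0, 250)) + rbc_distance(tr, c(250, 600)),
               rbc_distance(tr, c(0, 600)), tolerance = 1e-9)
})

test_that("excessive gaps are rejected with the coverage fraction", {
  t <- c(seq(0, 50, 1), seq(250, 300, 1))
  tr <- velocity_trace(t, rep(2, length(t)))
  expect_error(rbc_distance(tr, c(0, 300)), "coverage")
  # small interior gaps are bridged
  t2 <- setdiff(seq(0, 300, 1), 100:110)
  expect_equal(rbc_distance(velocity_trace(t2, rep(2, length(t2))), c(0, 300)),
               600, tolerance = 1e-9)
})

test_that("power changes are relative per band and total", {
  tr <- lfp_trace(withr::with_seed(5, rnorm(150000, 0, 0.2)) +
                    sin(2 * pi * 6 * seq_len(150000) / 1000), fs = 1000)
  ref <- band_power(tr, c(5, 130))
  expect_identical(power_change(ref, ref)$change_pct,
                   rep(0, 6))
  # a test window with 1.425x the reference power in every band: +42.5%
  tr2 <- lfp_trace(tr$samples * sqrt(1.425), fs = 1000)
  test <- band_power(tr2, c(5, 130))
  pc <- power_change(ref, test)
  expect_equal(pc$change_pct[pc$name == "total"], 42.5, tolerance = 0.1)
  # zero test power: -100%
  zero <- band_power(lfp_trace(rep(0, 150000), fs = 1000), c(5, 130))
  expect_true(all(power_change(ref, zero)$change_pct == -100))
  expect_warning(power_change(zero, ref), "zero reference")
})

test_that("vRBC fractions at SD onset reflect the generator trigger", {
  cfg <- scenario_config(seed = 6)
  sc <- generate_scenario(cfg, components = "velocity")
  seg <- segment_periods(sc$velocity, cfg$injection_time)
  fr <- vrbc_fraction_at_onset(sc$velocity, seg, sc$truth$sd_events$onset_s)
  expect_true(all(fr < 0.45))
  # an onset during baseline reads ~1.0
  fr0 <- vrbc_fraction_at_onset(sc$velocity, seg, 30)
  expect_equal(fr0, 1, tolerance = 0.1)
  # an onset inside a masked gap is undefined
  keep <- sc$velocity$time_s < 200 | sc$velocity$time_s > 260
  gappy <- velocity_trace(sc$velocity$time_s[keep], sc$velocity$v_mm_s[keep])
  expect_true(is.na(vrbc_fraction_at_onset(gappy, seg, 230)))
})

test_that("scenario segmentation matches generator truth", {
  for (s in c(2, 9, 17)) {
    cfg <- scenario_config(seed = s)
    sc <- generate_scenario(cfg, components = "velocity")
    seg <- segment_periods(sc$velocity, cfg$injection_time)
    expect_equal(seg$ischemia[2], seg$ischemia[1] + 300)
    expect_lt(abs(seg$partial_recovery[1] - sc$truth$recovery_crossing_s),
              cfg$velocity_dt + 1e-9)
  }
})
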