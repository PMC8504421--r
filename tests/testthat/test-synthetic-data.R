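test_that("zero velocity renders perfectly vertical streaks", {
  sim <- generate_kymograph(0, n_lines = 128, n_pixels = 32, seed = 1,
                            streak_density = 3)
  img <- sim$kymograph$intensity
  # every line identical: no shift between consecutive lines
  expect_true(all(apply(img, 2, function(col) diff(range(col))) < 1e-12))
  expect_true(all(sim$truth$v_mm_s == 0))
})

test_that("streak slope equals the analytic v * dt / dx", {
  # slope measured by least squares on dip centroids, independent of LS-PIV
  for (v in c(0.5, 2, 7)) {
    sim <- generate_kymograph(v, n_lines = 200, n_pixels = 64,
                              line_period = 1, pixel_size = 1,
                              streak_density = 1, seed = 3)
    slope <- ls_slope_oracle(sim$kymograph$intensity)
    expect_equal(slope, v * 1 / 1, tolerance = 0.005)
  }
})

test_that("kymograph generation is seed-deterministic and seed-sensitive", {
  a <- generate_kymograph(2, n_lines = 64, n_pixels = 32, seed = 9,
                          noise_sd = 0.05)
  b <- generate_kymograph(2, n_lines = 64, n_pixels = 32, seed = 9,
                          noise_sd = 0.05)
  c <- generate_kymograph(2, n_lines = 64, n_pixels = 32, seed = 10,
                          noise_sd = 0.05)
  expect_identical(a$kymograph$intensity, b$kymograph$intensity)
  expect_false(identical(a$kymograph$intensity, c$kymograph$intensity))
})

test_that("super-Nyquist displacement is rejected as aliasing", {
  expect_error(
    generate_kymograph(20, n_lines = 64, n_pixels = 32, line_period = 1,
                       pixel_size = 1),
    "aliasing")
})

test_that("pure-noise LFP has the configured baseline", {
  g <- generate_lfp(60, fs = 1000, baseline_mean = 4, baseline_sd = 0.05,
                    seed = 1)
  se <- 0.05 / sqrt(length(g$trace$samples))
  expect_lt(abs(mean(g$trace$samples) - 4), 3 * se)
  expect_equal(nrow(g$truth), 0L)
})

test_that("an SD renders as a negative DC deflection of the stated depth", {
  g <- generate_lfp(200, fs = 500, baseline_mean = 4, baseline_sd = 0.05,
                    sd_specs = data.frame(onset_s = 60, amplitude_mV = 20,
                                          duration_s = 60), seed = 2)
  expect_lt(abs(min(g$trace$samples) - (4 - 20)), 5 * 0.05)
  expect_identical(g$truth$type, "sd")
  # rule-based truth times bracket the nominal footprint
  expect_gt(g$truth$onset_rule_s, 60)
  expect_lt(g$truth$end_rule_s, 120)
})

test_that("PIP burst energy is concentrated in its window", {
  g <- generate_lfp(60, fs = 1000, baseline_mean = 0, baseline_sd = 0.05,
                    pip_specs = data.frame(onset_s = 30, duration_s = 3,
                                           freq_hz = 6, rel_amplitude = 4),
                    seed = 1)
  # direct integration of the 2-10 Hz bandpassed energy, in vs out of window
  bp <- fft_bandpass_oracle(g$trace$samples, 1000, 2, 10)
  t <- lfp_time(g$trace)
  en <- window_energy(t, bp, c(29.5, 33.5))
  expect_gt(en["inside"] / (en["inside"] + en["outside"]), 0.95)
})

test_that("overlapping SD specifications are rejected", {
  specs <- data.frame(onset_s = c(10, 50), amplitude_mV = 20,
                      duration_s = c(60, 60))
  expect_error(generate_lfp(200, fs = 500, sd_specs = specs), "overlap")
  expect_error(
    generate_lfp(100, fs = 500,
                 sd_specs = data.frame(onset_s = 60, amplitude_mV = 20,
                                       duration_s = 60)),
    "within")
})

test_that("scenario SD onsets lie inside the sub-threshold interval", {
  cfg <- scenario_config(peak_drop_fraction = 0.3, sd_trigger_fraction = 0.35,
                         n_sds = 2, seed = 4)
  sc <- generate_scenario(cfg, components = "velocity")
  sub <- sc$truth$sub_threshold_interval_s
  prof <- sc$truth$velocity_profile
  for (on in sc$truth$sd_events$onset_s) {
    expect_gt(on, sub[1])
    expect_lt(on, sub[2])
    expect_lt(prof(on), 0.35 * cfg$baseline_vrbc)
  }
})

test_that("scenario PIPs strictly follow the last SD", {
  sc <- generate_scenario(scenario_config(seed = 5), components = "velocity")
  last_sd_end <- max(sc$truth$sd_events$onset_s + sc$truth$sd_events$duration_s)
  expect_true(all(sc$truth$pip_events$onset_s > last_sd_end))
})

test_that("an unreachable SD trigger errors", {
  cfg <- scenario_config(peak_drop_fraction = 0.6, plateau_fraction = 0.8,
                         n_sds = 1)
  expect_error(generate_scenario(cfg, components = "velocity"),
               "trigger unreachable")
})

test_that("the seed controls the noise stream, not the design", {
  s1 <- generate_scenario(scenario_config(seed = 1), components = "velocity")
  s2 <- generate_scenario(scenario_config(seed = 2), components = "velocity")
  expect_false(identical(s1$velocity$v_mm_s, s2$velocity$v_mm_s))
  expect_identical(nrow(s1$truth$sd_events), nrow(s2$truth$sd_events))
  # same config + same seed: bit-identical
  s1b <- generate_scenario(scenario_config(seed = 1), components = "velocity")
  expect_identical(s1$velocity, s1b$velocity)
})

test_that("config invariants are enforced", {
  expect_error(scenario_config(peak_drop_fraction = 0.5,
                               plateau_fraction = 0.35),
               "peak_drop_fraction")
  expect_error(scenario_config(injection_time = 600,
                               recovery_onset_time = 500),
               "precede")
})

test_that("event-free traces pass both detectors silently", {
  for (s in 1:10) {
    g <- generate_lfp(120, fs = 500, baseline_mean = 4, baseline_sd = 0.1,
                      seed = s)
    expect_identical(nrow(detect_sds(g$trace, c(0, 60))), 0L)
    expect_identical(nrow(detect_pips(g$trace, c(0, 60))), 0L)
  }
})
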