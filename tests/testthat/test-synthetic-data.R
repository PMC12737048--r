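test_that("default roster reproduces the 8 recorded worker-day sessions", {
  r <- default_roster()
  expect_equal(nrow(r), 8)
  expect_equal(r$duration_min[r$day == 1 & r$worker == 1], 29.2)
  expect_equal(r$worker[r$day == 5], 5)
  expect_equal(r$duration_min[r$day == 5], 33.0)
  # worker 3 did not perform on day 2; worker 4 has a single session
  expect_false(any(r$day == 2 & r$worker == 3))
  expect_equal(sum(r$worker == 4), 1)
  expect_true(all(r$duration_min >= 13))
  expect_false(anyDuplicated(paste(r$day, r$worker)) > 0)
})

test_that("invalid generator configurations are rejected naming the field", {
  expect_error(generator_config(nan_timestamp_rate = 1.5),
               "nan_timestamp_rate")
  expect_error(generator_config(effort_end = 7), "effort_end")
  expect_error(generator_config(freq_drift_per_effort = 0.2),
               "freq_drift_per_effort")
  expect_error(generator_config(jerk_gain_per_effort = -1),
               "jerk_gain_per_effort")
  expect_error(
    generator_config(base_peak_freqs = within(default_peak_freqs(),
                                              pelvis <- c(0.8, 30))),
    "Nyquist")
  expect_error(generator_config(roster = default_roster()[0, ]), "roster")
  expect_error(
    generator_config(roster = data.frame(day = 1, worker = 1,
                                         duration_min = 12)),
    "roster")
})

test_that("identical (config, entry, seed) reproduce a session exactly", {
  cfg <- generator_config(seed = 3)
  entry <- list(day = 1L, worker = 1L, duration_min = 13.2)
  s1 <- generate_session(cfg, entry, 99)
  s2 <- generate_session(cfg, entry, 99)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("a full study regenerates byte-identically from its master seed", {
  cfg <- small_config(seed = 21)
  expect_identical(serialize(generate_study(cfg), NULL),
                   serialize(generate_study(cfg), NULL))
})

test_that("self-reports are the rounded latent effort at start/middle/end", {
  s <- short_session(seed = 5)
  expect_equal(s$reports$effort, c(1, 2, 3))
  expect_equal(s$reports$time_s, c(0, s$duration_min * 60 / 2,
                                   s$duration_min * 60))
  # default endpoints keep reported levels within 1..3 for every session
  for (sess in default_study()$sessions) {
    expect_true(all(sess$reports$effort %in% 1:3))
  }
})

test_that("default study has one session per roster entry", {
  study <- default_study()
  expect_length(study$sessions, 8)
  expect_setequal(names(study$sessions),
                  sprintf("d%d_w%d", default_roster()$day,
                          default_roster()$worker))
  # streams span the roster duration
  for (sess in study$sessions) {
    dur <- sess$duration_min * 60
    for (st in sess$streams) {
      tmax <- max(st$timestamp, na.rm = TRUE)
      expect_lte(tmax, dur)
      expect_gt(tmax, dur - 1)
    }
  }
})

test_that("achieved sampling rates sit within jitter-implied tolerance", {
  cfg <- generator_config()
  for (sess in default_study()$sessions[c(1, 2, 8)]) {
    for (st in sess$streams) {
      tt <- st$timestamp[!is.na(st$timestamp)]
      n <- nrow(st)  # every sample, including the missing-timestamp markers
      est <- (n - 1) / (tt[length(tt)] - tt[1])
      tol <- 3 * cfg$sampling_rate_mean^2 * cfg$sampling_jitter_sd / sqrt(n - 1) +
        0.05  # edge samples lost to missing markers shorten the span slightly
      expect_lt(abs(est - cfg$sampling_rate_mean), tol)
    }
  }
})

test_that("missing-timestamp fraction obeys binomial 99% bounds", {
  cfg <- generator_config()
  n_total <- 0L; n_miss <- 0L
  for (sess in default_study()$sessions) {
    for (st in sess$streams) {
      n_total <- n_total + nrow(st)
      n_miss <- n_miss + sum(is.na(st$timestamp))
    }
  }
  bounds <- qbinom(c(0.005, 0.995), n_total, cfg$nan_timestamp_rate)
  expect_gte(n_miss, bounds[1])
  expect_lte(n_miss, bounds[2])
})

test_that("noise-free stationary sessions keep a constant dominant frequency", {
  cfg <- generator_config(seed = 3, noise_sd = 0, nan_timestamp_rate = 0,
                          freq_drift_per_effort = 0, jerk_gain_per_effort = 0)
  s <- generate_session(cfg, list(day = 1L, worker = 1L,
                                  duration_min = 15.3), 7)
  ser <- lowpass_filter(compute_total_acceleration(s$streams$pelvis))
  peaks <- vapply(make_windows(ser), function(w) {
    p <- welch_psd(w, ser$est_rate)
    p$freqs[which.max(p$power)]
  }, numeric(1))
  expect_equal(length(unique(peaks)), 1)
})

test_that("with negative drift and no noise the dominant peak never rises", {
  cfg <- generator_config(seed = 2, noise_sd = 0, nan_timestamp_rate = 0)
  s <- generate_session(cfg, list(day = 1L, worker = 1L,
                                  duration_min = 29.2), 42)
  ser <- lowpass_filter(compute_total_acceleration(s$streams$pelvis))
  peaks <- vapply(make_windows(ser), function(w) {
    p <- welch_psd(w, ser$est_rate)
    p$freqs[which.max(p$power)]
  }, numeric(1))
  expect_true(all(diff(peaks) <= 1e-9))
  expect_lt(peaks[length(peaks)], peaks[1])  # drift is actually visible
})

test_that("an empty roster cannot generate a study", {
  cfg <- generator_config()
  cfg$roster <- cfg$roster[0, ]
  expect_error(generate_study(cfg), "roster")
})
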