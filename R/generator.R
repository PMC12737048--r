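#' Default dominant movement frequencies per sensor site
#'
#' Each site carries a fundamental cadence plus harmonics. The legs and
#' pelvis oscillate near a walking cadence (~0.8-0.9 Hz during loaded
#' carrying); the arms move more slowly (lift-carry-lower cycles); trunk
#' sensors pick up both the step cadence and a higher harmonic.
#'
#' @return Named list, one numeric vector of frequencies (Hz) per site.
#' @export
default_peak_freqs <- function() {
  list(
    left_thigh      = c(0.85, 1.70, 2.55),
    right_thigh     = c(0.90, 1.80, 2.70),
    left_upper_arm  = c(0.60, 1.20, 2.40),
    right_upper_arm = c(0.65, 1.30, 2.60),
    sternum         = c(0.95, 1.90, 3.80),
    pelvis          = c(0.80, 1.60, 3.20)
  )
}

#' Configuration for the synthetic session generator
#'
#' Parameterizes statistically realistic hauling sessions: irregular ~45 Hz
#' sampling with occasional missing timestamps, cyclic site-specific motion,
#' and a latent effort trend that simultaneously drives the self-reports,
#' a downward drift of the dominant movement frequencies (pace slows with
#' fatigue) and a growth of wide-band noise (degraded movement control,
#' i.e. rising jerk variability).
#'
#' @param roster Session roster, see [default_roster()].
#' @param sampling_rate_mean Mean sampling rate in Hz.
#' @param sampling_jitter_sd Standard deviation of inter-sample intervals,
#'   in seconds.
#' @param nan_timestamp_rate Probability that a sample's timestamp is
#'   recorded as missing.
#' @param sensor_sites Site labels to synthesize.
#' @param base_peak_freqs Named list of per-site dominant frequencies (Hz);
#'   all must lie strictly below the Nyquist rate.
#' @param effort_start,effort_end Latent effort endpoints on the 1-5 scale.
#' @param freq_drift_per_effort Frequency shift in Hz per unit of effort
#'   increase; non-positive (movement slows as fatigue builds).
#' @param jerk_gain_per_effort Relative growth of the noise amplitude per
#'   unit of effort increase; non-negative.
#' @param noise_sd Baseline white-noise standard deviation, acceleration
#'   units.
#' @param seed Integer master seed for [generate_study()].
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(roster = default_roster(),
                             sampling_rate_mean = 45,
                             sampling_jitter_sd = 0.004,
                             nan_timestamp_rate = 0.01,
                             sensor_sites = fatigue_sites(),
                             base_peak_freqs = default_peak_freqs(),
                             effort_start = 1,
                             effort_end = 3,
                             freq_drift_per_effort = -0.25,
                             jerk_gain_per_effort = 0.4,
                             noise_sd = 0.2,
                             seed = 1L) {
  validate_roster(roster)
  if (!is.numeric(sampling_rate_mean) || sampling_rate_mean <= 0) {
    stop("invalid config field 'sampling_rate_mean': must be > 0")
  }
  if (!is.numeric(sampling_jitter_sd) || sampling_jitter_sd < 0) {
    stop("invalid config field 'sampling_jitter_sd': must be >= 0")
  }
  if (!is.numeric(nan_timestamp_rate) || nan_timestamp_rate < 0 ||
      nan_timestamp_rate > 1) {
    stop("invalid config field 'nan_timestamp_rate': must be in [0, 1]")
  }
  if (length(sensor_sites) < 1 || anyDuplicated(sensor_sites)) {
    stop("invalid config field 'sensor_sites': need distinct site labels")
  }
  if (!all(sensor_sites %in% names(base_peak_freqs))) {
    stop("invalid config field 'base_peak_freqs': missing sites ",
         paste(setdiff(sensor_sites, names(base_peak_freqs)), collapse = ", "))
  }
  nyq <- sampling_rate_mean / 2
  if (any(unlist(base_peak_freqs[sensor_sites]) >= nyq)) {
    stop("invalid config field 'base_peak_freqs': all frequencies must be ",
         "strictly below Nyquist (", nyq, " Hz)")
  }
  for (fld in c("effort_start", "effort_end")) {
    v <- get(fld)
    if (!is.numeric(v) || v < 1 || v > 5) {
      stop("invalid config field '", fld, "': must be within [1, 5]")
    }
  }
  if (!is.numeric(freq_drift_per_effort) || freq_drift_per_effort > 0) {
    stop("invalid config field 'freq_drift_per_effort': must be <= 0")
  }
  if (!is.numeric(jerk_gain_per_effort) || jerk_gain_per_effort < 0) {
    stop("invalid config field 'jerk_gain_per_effort': must be >= 0")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("invalid config field 'noise_sd': must be >= 0")
  }
  structure(
    list(roster = roster,
         sampling_rate_mean = sampling_rate_mean,
         sampling_jitter_sd = sampling_jitter_sd,
         nan_timestamp_rate = nan_timestamp_rate,
         sensor_sites = sensor_sites,
         base_peak_freqs = base_peak_freqs,
         effort_start = effort_start,
         effort_end = effort_end,
         freq_drift_per_effort = freq_drift_per_effort,
         jerk_gain_per_effort = jerk_gain_per_effort,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# half-up rounding; self-report scales round .5 upward, unlike round()'s
# round-half-even convention
round_half_up <- function(x) floor(x + 0.5)

# deterministic per-session seed so adding a roster entry does not perturb
# the draws of the others; kept below 2^31 - 1
derive_session_seed <- function(master_seed, day, worker) {
  as.integer((abs(as.double(master_seed)) %% 1e6 * 2654435 +
                day * 9973 + worker * 7919) %% 2147483647)
}

#' Generate one synthetic hauling session
#'
#' The latent effort `e(t)` runs linearly from `effort_start` to
#' `effort_end` across the session. Each axis of each sensor is a sum of
#' sinusoids whose instantaneous frequencies are the site's base
#' frequencies shifted by `freq_drift_per_effort * (e(t) - e(0))`, plus
#' white noise whose amplitude grows by a factor
#' `1 + jerk_gain_per_effort * (e(t) - e(0))`. The vertical axis carries a
#' gravity offset so the acceleration magnitude preserves the movement
#' spectrum. Timestamps are drawn at the mean rate with Gaussian jitter and
#' a fraction is replaced by missing markers. Self-reports are the latent
#' effort rounded half-up, taken at the start, middle and end.
#'
#' @param config A [generator_config()].
#' @param entry One roster row (`day`, `worker`, `duration_min`).
#' @param seed Integer seed; identical `(config, entry, seed)` reproduce
#'   the session exactly.
#' @return A list of class `fatigue_session` with elements `day`, `worker`,
#'   `duration_min`, `streams` (named list of per-site data.frames with
#'   columns `timestamp`, `ax`, `ay`, `az`), `reports` (data.frame
#'   `time_s`, `effort`), `effort_start`, `effort_end`, `seed`.
#' @export
generate_session <- function(config, entry, seed) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  dur <- entry$duration_min * 60
  if (dur < 13 * 60) stop("session duration must be >= 13 min")
  set.seed(as.integer(seed))

  mu_dt <- 1 / config$sampling_rate_mean
  slope <- (config$effort_end - config$effort_start) / dur
  drift <- config$freq_drift_per_effort

  streams <- stats::setNames(vector("list", length(config$sensor_sites)),
                             config$sensor_sites)
  for (site in config$sensor_sites) {
    n_draw <- ceiling(dur * config$sampling_rate_mean * 1.05) + 8
    dts <- stats::rnorm(n_draw, mu_dt, config$sampling_jitter_sd)
    dts <- pmax(dts, 0.2 * mu_dt)
    tt <- cumsum(dts)
    tt <- tt[tt <= dur]
    n <- length(tt)

    de <- slope * tt                       # e(t) - e(0)
    freqs <- config$base_peak_freqs[[site]]
    amps <- 1 / seq_along(freqs)
    ax <- numeric(n); ay <- numeric(n); az <- numeric(n)
    for (j in seq_along(freqs)) {
      # instantaneous frequency f_j + drift * (e(t) - e(0)); with linear
      # effort the phase integral is analytic
      phase <- 2 * pi * (freqs[j] * tt + drift * slope * tt^2 / 2)
      phi <- stats::runif(3, 0, 2 * pi)
      ax <- ax + 0.6 * amps[j] * sin(phase + phi[1])
      ay <- ay + 0.6 * amps[j] * sin(phase + phi[2])
      az <- az + amps[j] * sin(phase + phi[3])
    }
    amp_noise <- config$noise_sd * (1 + config$jerk_gain_per_effort * de)
    if (config$noise_sd > 0) {
      ax <- ax + stats::rnorm(n) * amp_noise
      ay <- ay + stats::rnorm(n) * amp_noise
      az <- az + stats::rnorm(n) * amp_noise
    }
    az <- az + 9.81

    if (config$nan_timestamp_rate > 0) {
      miss <- stats::runif(n) < config$nan_timestamp_rate
      tt[miss] <- NA_real_
    }
    streams[[site]] <- data.frame(timestamp = tt, ax = ax, ay = ay, az = az)
  }

  report_times <- c(0, dur / 2, dur)
  e_at <- config$effort_start + slope * report_times
  reports <- data.frame(
    time_s = report_times,
    effort = pmin(pmax(round_half_up(e_at), 1), 5)
  )

  structure(
    list(day = entry$day, worker = entry$worker,
         duration_min = entry$duration_min,
         streams = streams, reports = reports,
         effort_start = config$effort_start,
         effort_end = config$effort_end,
         seed = as.integer(seed)),
    class = "fatigue_session"
  )
}

#' Latent effort trace of a synthetic session
#'
#' Ground truth retained for testing: the linear latent effort at time `t`
#' seconds into the session.
#'
#' @param session A `fatigue_session`.
#' @param t Time(s) in seconds.
#' @return Latent effort value(s) on the 1-5 scale.
#' @export
latent_effort <- function(session, t) {
  dur <- session$duration_min * 60
  session$effort_start +
    (session$effort_end - session$effort_start) * pmin(pmax(t, 0), dur) / dur
}

#' Generate a full synthetic study
#'
#' One session per roster entry, each seeded deterministically from the
#' master seed and the entry's day/worker so regenerating the study -- or
#' any single session -- is reproducible.
#'
#' @param config A [generator_config()].
#' @return A list of class `fatigue_study`: `sessions` (named list, names
#'   `d<day>_w<worker>`) and the `config` used.
#' @export
generate_study <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  validate_roster(config$roster)
  sessions <- vector("list", nrow(config$roster))
  ids <- character(nrow(config$roster))
  for (i in seq_len(nrow(config$roster))) {
    entry <- config$roster[i, ]
    sd_i <- derive_session_seed(config$seed, entry$day, entry$worker)
    sessions[[i]] <- generate_session(config, entry, sd_i)
    ids[i] <- session_id(sessions[[i]])
  }
  names(sessions) <- ids
  structure(list(sessions = sessions, config = config),
            class = "fatigue_study")
}

#' Session identifier
#'
#' @param session A `fatigue_session`.
#' @return Character id of the form `d<day>_w<worker>`.
#' @export
session_id <- function(session) {
  sprintf("d%d_w%d", session$day, session$worker)
}
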