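# Shared fixtures, built once per test run and cached in-process. The
# default study is the full 8-session roster at the generator defaults;
# the "small" study is a 3-session roster of short sessions for cheap
# pipeline-level checks.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

default_study <- function(seed = 1) {
  cached(paste0("study_", seed), function() {
    generate_study(generator_config(seed = seed))
  })
}

default_mats <- function(seed = 1) {
  cached(paste0("mats_", seed), function() {
    study_feature_matrices(default_study(seed))
  })
}

small_roster <- function() {
  data.frame(day = c(1L, 1L, 2L), worker = c(1L, 2L, 1L),
             duration_min = c(13.5, 14.2, 16.0))
}

small_config <- function(seed = 11) {
  generator_config(roster = small_roster(), seed = seed)
}

small_study <- function(seed = 11) {
  cached(paste0("small_study_", seed), function() {
    generate_study(small_config(seed))
  })
}

# a single short session used by per-stage tests
short_session <- function(seed = 5, duration_min = 13.5, ...) {
  cached(paste0("short_", seed, "_", duration_min), function() {
    cfg <- generator_config(...)
    generate_session(cfg, list(day = 1L, worker = 1L,
                               duration_min = duration_min), seed)
  })
}

# uniformly sampled total-acceleration series with a given signal
uniform_series <- function(signal_fun, duration_s, rate = 45) {
  tt <- (0:round(duration_s * rate)) / rate
  structure(list(site = "test", timestamps = tt,
                 magnitude = signal_fun(tt),
                 est_rate = (length(tt) - 1) / (tt[length(tt)] - tt[1])),
            class = "total_accel")
}
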