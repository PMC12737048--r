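test_that("Welch PSD locates pure-tone peaks to within one bin", {
  x <- sin(2 * pi * 2.0 * (0:4095) / 45)
  psd <- welch_psd(x, 45)
  expect_equal(psd$freqs[1], 0)
  expect_equal(psd$freqs[length(psd$freqs)], 22.5)
  binw <- psd$freqs[2] - psd$freqs[1]
  expect_lt(abs(psd$freqs[which.max(psd$power)] - 2.0), binw)
  expect_true(all(psd$power >= 0))
})

test_that("Welch PSD of white noise is flat", {
  for (seed in 1:20) {
    set.seed(seed)
    psd <- welch_psd(rnorm(4096), 45)
    expect_lt(max(psd$power), 5 * median(psd$power))
  }
})

test_that("two-tone PSD shows power proportional to amplitude squared", {
  tt <- (0:8191) / 45
  x <- 2 * sin(2 * pi * 1 * tt) + sin(2 * pi * 3 * tt)
  psd <- welch_psd(x, 45)
  band_power <- function(f0) {
    i <- which.min(abs(psd$freqs - f0))
    sum(psd$power[max(1, i - 2):min(length(psd$power), i + 2)])
  }
  ratio <- band_power(1) / band_power(3)
  expect_gt(ratio, 3.2)
  expect_lt(ratio, 4.8)
  # both tones are local maxima of the spectrum
  pk <- find_psd_peaks(psd, 8)
  expect_lt(min(abs(pk$freq[1:2] - 1), abs(pk$freq[1:2] - 3)), 0.2)
})

test_that("too-short windows are rejected for PSD estimation", {
  expect_error(welch_psd(rnorm(300), 45), "window too short for PSD")
})

test_that("peak extraction matches hand-enumerable cases", {
  psd <- structure(list(freqs = 0:6, power = c(0, 1, 0, 3, 0, 2, 0)),
                   class = "psd_estimate")
  pk <- find_psd_peaks(psd, 8)
  expect_equal(pk$freq, c(3, 5, 1, 0, 0, 0, 0, 0))
  expect_equal(pk$power, c(3, 2, 1, 0, 0, 0, 0, 0))
  expect_equal(pk$rank, 1:8)
  mono <- structure(list(freqs = 0:5, power = 1:6 / 6),
                    class = "psd_estimate")
  pk2 <- find_psd_peaks(mono, 8)
  expect_true(all(pk2$freq == 0) && all(pk2$power == 0))
})

test_that("peak extraction equals exhaustive enumeration on random arrays", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(3:32, 1)
    power <- round(runif(n), 2)  # rounding forces occasional exact ties
    psd <- structure(list(freqs = seq(0, 10, length.out = n), power = power),
                     class = "psd_estimate")
    k <- sample(1:8, 1)
    got <- find_psd_peaks(psd, k)
    want <- oracle_peaks(psd$freqs, power, k)
    expect_equal(got$freq, want$freq)
    expect_equal(got$power, want$power)
  }
})

test_that("power-weighted sum is the plain sum of freq x power", {
  single <- data.frame(rank = 1:8, freq = c(2, rep(0, 7)),
                       power = c(1, rep(0, 7)))
  expect_equal(power_weighted_sum(single), 2)
  two <- data.frame(rank = 1:8, freq = c(1, 3, rep(0, 6)),
                    power = c(0.5, 0.5, rep(0, 6)))
  expect_equal(power_weighted_sum(two), 2)
  set.seed(8)
  for (i in 1:100) {
    pk <- data.frame(rank = 1:8, freq = runif(8, 0, 22.5),
                     power = runif(8))
    naive <- 0
    for (k in 1:8) naive <- naive + pk$freq[k] * pk$power[k]
    expect_equal(power_weighted_sum(pk), naive)
  }
})

test_that("standard statistics use population sd and interpolated quantiles", {
  expect_equal(unname(standard_stats(rep(3, 10))), c(3, 0, 3, 3, 3))
  expect_equal(standard_stats(c(1, 2, 3, 4))[["median"]], 2.5)
  expect_error(standard_stats(numeric(0)), "empty")
  set.seed(9)
  for (i in 1:100) {
    x <- rnorm(sample(2:50, 1))
    expect_equal(standard_stats(x), oracle_standard_stats(x),
                 tolerance = 1e-12)
  }
})

test_that("jerk is the time gradient over actual timestamps", {
  # linear ramp -> constant derivative, zero spread
  w <- list(times = seq(0, 1, by = 0.1), samples = 3 * seq(0, 1, by = 0.1))
  js <- jerk_stats(w)
  expect_equal(unname(js), c(3, 0, 3, 3, 3))
  wc <- list(times = seq(0, 1, by = 0.1), samples = rep(1, 11))
  expect_equal(unname(jerk_stats(wc)), c(0, 0, 0, 0, 0))
  # central differences are exact for quadratics on a uniform grid
  tq <- seq(0, 2, by = 0.05)
  wq <- list(times = tq, samples = tq^2)
  g <- (wq$samples[3:length(tq)] - wq$samples[1:(length(tq) - 2)]) /
    (tq[3:length(tq)] - tq[1:(length(tq) - 2)])
  expect_equal(g, 2 * tq[2:(length(tq) - 1)], tolerance = 1e-12)
  expect_error(jerk_stats(list(times = c(0, 1), samples = c(0, 1))),
               ">= 3 samples")
})

test_that("jerk statistics match a brute-force gradient on irregular grids", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    tt <- cumsum(runif(n, 0.01, 0.1))
    y <- rnorm(n)
    got <- jerk_stats(list(times = tt, samples = y))
    expect_equal(got, oracle_standard_stats(oracle_gradient(y, tt)),
                 tolerance = 1e-12)
  }
})

test_that("feature assembly yields 19 columns per site in canonical order", {
  set.seed(11)
  mk_win <- function() {
    tt <- (0:599) / 45
    list(times = tt, samples = sin(2 * pi * tt) + rnorm(600, sd = 0.1))
  }
  wins <- list(mk_win(), mk_win())
  sites6 <- fatigue_sites()
  sw <- setNames(lapply(sites6, function(s) wins), sites6)
  rates <- setNames(rep(45, 6), sites6)
  f6 <- assemble_features(sw, rates)
  expect_equal(ncol(f6), 114)
  expect_equal(names(f6), feature_names(sites6))
  expect_false(anyDuplicated(names(f6)) > 0)
  f2 <- assemble_features(sw[c("pelvis", "sternum")], rates)
  expect_equal(ncol(f2), 38)
  f1 <- assemble_features(sw["pelvis"], rates)
  expect_equal(ncol(f1), 19)
  sw_bad <- sw
  sw_bad$pelvis <- wins[1]
  expect_error(assemble_features(sw_bad, rates), "unsynchronized sensors")
})

test_that("PSD peak-frequency features stay within [0, Nyquist]", {
  s <- default_study()$sessions[[2]]
  raw <- session_feature_matrix(s, normalization = "none")
  peak_cols <- grep("_psd_peak_", names(raw$features), value = TRUE)
  for (cl in peak_cols) {
    expect_gte(min(raw$features[[cl]]), 0)
    expect_lte(max(raw$features[[cl]]), 45 / 2 * 1.05)
  }
})

test_that("baseline normalization follows the first-two-windows rule", {
  f <- data.frame(a = c(2, 2, 4), b = c(1, 3, 8))
  nf <- normalize_features(f)
  expect_equal(nf$a, c(0.5, 0.5, 1.0))
  expect_equal(nf$a[1] + nf$a[2], 1)
  expect_equal(nf$b[1] + nf$b[2], 1)
  # the mean variant differs by exactly a global factor 2
  expect_equal(normalize_features(f, "mean")$b, 2 * nf$b)
  f0 <- data.frame(a = c(0, 0, 1), b = c(1, 1, 1))
  expect_error(normalize_features(f0), "'a'")
  expect_error(normalize_features(f[1, , drop = FALSE]), ">= 2 windows")
})

test_that("scaling raw accelerations cancels out of normalized features", {
  s <- short_session(seed = 5)
  s10 <- s
  for (site in names(s10$streams)) {
    s10$streams[[site]][, c("ax", "ay", "az")] <-
      s10$streams[[site]][, c("ax", "ay", "az")] * 10
  }
  raw <- session_feature_matrix(s, normalization = "none")
  raw10 <- session_feature_matrix(s10, normalization = "none")
  peak_cols <- grep("_psd_peak_", names(raw$features), value = TRUE)
  # peak frequencies are amplitude-invariant even before normalization
  expect_equal(raw10$features[peak_cols], raw$features[peak_cols],
               tolerance = 1e-9)
  nrm <- normalize_features(raw$features)
  nrm10 <- normalize_features(raw10$features)
  sj_cols <- grep("_std_|_jerk_", names(nrm), value = TRUE)
  expect_equal(nrm10[sj_cols], nrm[sj_cols], tolerance = 1e-9)
})
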