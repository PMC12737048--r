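#' Total acceleration from a raw three-axis stream
#'
#' Drops every sample whose timestamp or any axis value is missing, then
#' computes the Euclidean magnitude sqrt(ax^2 + ay^2 + az^2) of the
#' surviving rows. The average sampling rate is re-estimated after the
#' drop as (n - 1) / (t_last - t_first).
#'
#' @param stream A data.frame with columns `timestamp`, `ax`, `ay`, `az`.
#' @param site Optional site label carried through to the result.
#' @return A list of class `total_accel`: `site`, `timestamps`,
#'   `magnitude`, `est_rate` (Hz).
#' @export
compute_total_acceleration <- function(stream, site = NULL) {
  stopifnot(all(c("timestamp", "ax", "ay", "az") %in% names(stream)))
  keep <- !(is.na(stream$timestamp) | is.na(stream$ax) |
              is.na(stream$ay) | is.na(stream$az))
  if (sum(keep) < 2) stop("empty stream: fewer than 2 valid samples")
  tt <- stream$timestamp[keep]
  if (is.unsorted(tt, strictly = TRUE)) {
    stop("timestamps not strictly increasing after dropping missing values")
  }
  mag <- sqrt(stream$ax[keep]^2 + stream$ay[keep]^2 + stream$az[keep]^2)
  n <- length(tt)
  structure(
    list(site = site, timestamps = tt, magnitude = mag,
         est_rate = (n - 1) / (tt[n] - tt[1])),
    class = "total_accel"
  )
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass forward and backward
#' (zero phase), so the filtered series stays time-aligned with the effort
#' reports. The series' estimated average rate is used as the nominal
#' sampling rate; the irregular timestamps are left untouched.
#'
#' @param series A `total_accel` series.
#' @param cutoff Cutoff frequency in Hz (default 18).
#' @param order Filter order (default 4).
#' @return The series with filtered `magnitude`.
#' @export
lowpass_filter <- function(series, cutoff = 18, order = 4) {
  nyq <- series$est_rate / 2
  if (cutoff >= nyq) {
    stop(sprintf(
      "cutoff above Nyquist: cutoff %.3f Hz, Nyquist %.3f Hz (rate %.3f Hz)",
      cutoff, nyq, series$est_rate))
  }
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  x <- series$magnitude
  n <- length(x)
  # remove the DC level and pad with odd-reflected ends before the
  # forward-backward pass, so filter start-up transients do not leak into
  # the first windows (which anchor the baseline normalization)
  mu <- mean(x)
  x <- x - mu
  p <- min(n - 1, 3 * (2 * order + 1))
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  yp <- as.numeric(signal::filtfilt(bf, xp))
  series$magnitude <- yp[(p + 1):(p + n)] + mu
  series
}

#' Sliding-window specification
#'
#' Defaults to the 12-minute windows slid 1 minute at a time used for the
#' hauling analysis.
#'
#' @param length_s Window length in seconds.
#' @param step_s Slide step in seconds.
#' @return List of class `window_spec`.
#' @export
window_spec <- function(length_s = 720, step_s = 60) {
  if (!(step_s > 0 && step_s <= length_s)) {
    stop("window_spec requires 0 < step_s <= length_s")
  }
  structure(list(length_s = length_s, step_s = step_s), class = "window_spec")
}

# first index with t >= x and last index with t < x, exact at boundaries
.idx_geq <- function(t, x) {
  i <- findInterval(x, t)  # last index with t <= x
  if (i >= 1 && t[i] == x) i else i + 1
}
.idx_lt <- function(t, x) {
  i <- findInterval(x, t)
  if (i >= 1 && t[i] == x) i - 1 else i
}

#' Cut a series into sliding windows
#'
#' Windows are half-open `[start, start + length)`, start at the series'
#' first timestamp and advance by `step_s`; the last window must fit fully
#' inside the recorded span, so the count is
#' `floor((span - length) / step) + 1`.
#'
#' @param series A `total_accel` series.
#' @param spec A [window_spec()].
#' @return List of windows; each has `index` (0-based), `start_time`,
#'   `end_time`, `center_time`, `times`, `samples`.
#' @export
make_windows <- function(series, spec = window_spec()) {
  tt <- series$timestamps
  span <- tt[length(tt)] - tt[1]
  if (span < spec$length_s) {
    stop(sprintf("session too short: duration %.2f s < window length %.2f s",
                 span, spec$length_s))
  }
  n_win <- floor((span - spec$length_s) / spec$step_s) + 1
  out <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    start <- tt[1] + (k - 1) * spec$step_s
    end <- start + spec$length_s
    lo <- .idx_geq(tt, start)
    hi <- .idx_lt(tt, end)
    if (hi < lo) stop("empty window at index ", k - 1)
    out[[k]] <- list(index = k - 1L, start_time = start, end_time = end,
                     center_time = (start + end) / 2,
                     times = tt[lo:hi], samples = series$magnitude[lo:hi])
  }
  out
}

#' Interpolate effort self-reports to window centers
#'
#' Piecewise-linear interpolation through the report knots, evaluated at
#' the window centers; centers outside the report span are clamped to the
#' nearest knot value, so targets never leave the reported range.
#'
#' @param reports A data.frame with columns `time_s` and `effort`.
#' @param window_centers Numeric vector of window-center times (s).
#' @return List of class `effort_trend`: `window_centers`, `targets`.
#' @export
interpolate_effort <- function(reports, window_centers) {
  if (nrow(reports) < 2 || length(unique(reports$time_s)) < 2) {
    stop("insufficient reports: need >= 2 reports with distinct times")
  }
  o <- order(reports$time_s)
  y <- stats::approx(reports$time_s[o], reports$effort[o],
                     xout = window_centers, rule = 2, ties = "ordered")$y
  structure(list(window_centers = window_centers, targets = y),
            class = "effort_trend")
}
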