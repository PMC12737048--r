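#' Extract the highest peaks of a PSD
#'
#' A peak is a strict local maximum of the power array (greater than both
#' neighbours; endpoints excluded). Peaks are ranked by descending power,
#' ties broken toward the lower frequency, and the top `k` returned. When
#' fewer than `k` exist the remaining ranks are padded with
#' (freq 0, power 0) so the feature vector stays fixed-width.
#'
#' @param psd A `psd_estimate`.
#' @param k Number of peaks (default 8).
#' @return data.frame with columns `rank`, `freq`, `power`.
#' @export
find_psd_peaks <- function(psd, k = 8) {
  stopifnot(k >= 1)
  p <- psd$power
  n <- length(p)
  fr <- numeric(0); pw <- numeric(0)
  if (n >= 3) {
    i <- 2:(n - 1)
    is_peak <- p[i] > p[i - 1] & p[i] > p[i + 1]
    idx <- i[is_peak]
    fr <- psd$freqs[idx]; pw <- p[idx]
  }
  o <- order(-pw, fr)
  fr <- fr[o]; pw <- pw[o]
  if (length(fr) >= k) {
    fr <- fr[seq_len(k)]; pw <- pw[seq_len(k)]
  } else {
    pad <- k - length(fr)
    fr <- c(fr, rep(0, pad)); pw <- c(pw, rep(0, pad))
  }
  data.frame(rank = seq_len(k), freq = fr, power = pw)
}

#' Power-weighted sum of peak frequencies
#'
#' x = sum_k f_k * p_k over the ranked peaks, with raw (unnormalized) PSD
#' power as the weight; padded peaks contribute zero.
#'
#' @param peaks data.frame from [find_psd_peaks()].
#' @return Scalar power-weighted sum.
#' @export
power_weighted_sum <- function(peaks) {
  sum(peaks$freq * peaks$power)
}

#' Standard descriptive statistics of a window
#'
#' Mean, standard deviation, median, 75th and 25th percentile. The
#' standard deviation uses the population convention (divide by n);
#' percentiles interpolate linearly between order statistics.
#'
#' @param samples Numeric vector, non-empty.
#' @return Named numeric vector `(mean, sd, median, p75, p25)`.
#' @export
standard_stats <- function(samples) {
  if (length(samples) == 0) stop("standard_stats: empty input")
  n <- length(samples)
  m <- mean(samples)
  q <- unname(stats::quantile(samples, c(0.5, 0.75, 0.25), type = 7))
  c(mean = m,
    sd = sqrt(sum((samples - m)^2) / n),
    median = q[1], p75 = q[2], p25 = q[3])
}

# numerical gradient on (possibly irregular) timestamps: central
# differences in the interior, one-sided at the ends
time_gradient <- function(samples, times) {
  n <- length(samples)
  if (n < 3) stop("jerk_stats: need >= 3 samples")
  g <- numeric(n)
  g[1] <- (samples[2] - samples[1]) / (times[2] - times[1])
  g[n] <- (samples[n] - samples[n - 1]) / (times[n] - times[n - 1])
  i <- 2:(n - 1)
  g[i] <- (samples[i + 1] - samples[i - 1]) / (times[i + 1] - times[i - 1])
  g
}

#' Jerk statistics of a window
#'
#' The jerk series is the numerical time derivative of the total
#' acceleration over the window's actual timestamps; the same five
#' statistics as [standard_stats()] are then taken of the jerk series.
#'
#' @param window A window (list with `samples` and `times`).
#' @return Named numeric vector `(mean, sd, median, p75, p25)`.
#' @export
jerk_stats <- function(window) {
  standard_stats(time_gradient(window$samples, window$times))
}

# the 19 per-site feature names, in canonical family order
site_feature_names <- function(site) {
  c(paste0(site, "_psd_peak_", 1:8),
    paste0(site, "_psd_wsum"),
    paste0(site, "_std_", c("mean", "sd", "median", "p75", "p25")),
    paste0(site, "_jerk_", c("mean", "sd", "median", "p75", "p25")))
}

#' Canonical feature column names for a set of sites
#'
#' @param sites Site labels (default all six).
#' @return Character vector of `19 * length(sites)` unique names.
#' @export
feature_names <- function(sites = fatigue_sites()) {
  unlist(lapply(sites, site_feature_names), use.names = FALSE)
}

# 19 raw features for one window of one site
window_features <- function(window, rate, n_peaks = 8,
                            segment_length = 256, overlap = 0.5) {
  psd <- welch_psd(window, rate, segment_length, overlap)
  peaks <- find_psd_peaks(psd, n_peaks)
  c(peaks$freq, power_weighted_sum(peaks),
    standard_stats(window$samples), jerk_stats(window))
}

#' Assemble the raw per-window feature table
#'
#' For every window of every site: the 8 ranked PSD-peak frequencies, the
#' power-weighted peak sum, 5 standard statistics and 5 jerk statistics --
#' 19 features per site, 114 for the full six-sensor set. Column order is
#' the canonical site order, then family, then statistic.
#'
#' @param site_windows Named list: site label -> list of windows (as from
#'   [make_windows()]); all sites must have the same window count.
#' @param rates Named numeric vector of per-site average rates (Hz).
#' @param n_peaks Peaks per site (default 8).
#' @param segment_length,overlap Welch settings, see [welch_psd()].
#' @return data.frame with one row per window and `19 * n_sites` columns.
#' @export
assemble_features <- function(site_windows, rates, n_peaks = 8,
                              segment_length = 256, overlap = 0.5) {
  sites <- names(site_windows)
  counts <- vapply(site_windows, length, integer(1))
  if (length(unique(counts)) != 1) {
    stop("unsynchronized sensors: window counts ",
         paste(sprintf("%s=%d", sites, counts), collapse = ", "))
  }
  n_win <- counts[[1]]
  mats <- lapply(sites, function(site) {
    t(vapply(site_windows[[site]], window_features,
             numeric(19), rate = rates[[site]], n_peaks = n_peaks,
             segment_length = segment_length, overlap = overlap))
  })
  out <- as.data.frame(do.call(cbind, mats))
  names(out) <- feature_names(sites)
  rownames(out) <- NULL
  stopifnot(nrow(out) == n_win)
  out
}

#' Session-baseline feature normalization
#'
#' Divides each feature column by the sum of its own first two values
#' (first two windows of the session), so every feature is expressed
#' relative to the worker's non-fatigued start and the first two entries
#' of each normalized column sum to 1. The `"mean"` variant divides by the
#' average of the first two values instead (a global factor 2).
#'
#' @param features data.frame of raw features (rows = windows).
#' @param variant `"sum"` (default) or `"mean"`.
#' @return data.frame of normalized features.
#' @export
normalize_features <- function(features, variant = c("sum", "mean")) {
  variant <- match.arg(variant)
  if (nrow(features) < 2) stop("normalize_features: need >= 2 windows")
  for (j in seq_along(features)) {
    denom <- features[1, j] + features[2, j]
    if (variant == "mean") denom <- denom / 2
    if (!is.finite(denom) || denom == 0) {
      stop("normalization denominator zero or non-finite for column '",
           names(features)[j], "'")
    }
    features[[j]] <- features[[j]] / denom
  }
  features
}
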