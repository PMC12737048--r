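# Independent brute-force oracles. Deliberately naive (loops, direct
# formulas) and kept free of any package internals.

oracle_peaks <- function(freqs, power, k) {
  fr <- numeric(0); pw <- numeric(0)
  n <- length(power)
  for (i in seq_len(n)) {
    if (i == 1 || i == n) next
    if (power[i] > power[i - 1] && power[i] > power[i + 1]) {
      fr <- c(fr, freqs[i]); pw <- c(pw, power[i])
    }
  }
  o <- order(-pw, fr)
  fr <- fr[o]; pw <- pw[o]
  while (length(fr) < k) { fr <- c(fr, 0); pw <- c(pw, 0) }
  list(freq = fr[1:k], power = pw[1:k])
}

# linear interpolation between order statistics (h = (n-1)p convention)
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  s[lo] + (h - floor(h)) * (s[hi] - s[lo])
}

oracle_standard_stats <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  c(mean = m,
    sd = sqrt(sum((x - m)^2) / n),
    median = oracle_quantile(x, 0.5),
    p75 = oracle_quantile(x, 0.75),
    p25 = oracle_quantile(x, 0.25))
}

oracle_gradient <- function(y, t) {
  n <- length(y)
  g <- numeric(n)
  for (i in seq_len(n)) {
    g[i] <- if (i == 1) {
      (y[2] - y[1]) / (t[2] - t[1])
    } else if (i == n) {
      (y[n] - y[n - 1]) / (t[n] - t[n - 1])
    } else {
      (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
    }
  }
  g
}

oracle_f_values <- function(X, y) {
  n <- length(y)
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[[j]]
    sx <- sqrt(sum((x - mean(x))^2))
    sy <- sqrt(sum((y - mean(y))^2))
    if (sx == 0 || sy == 0) return(0)
    r <- sum((x - mean(x)) * (y - mean(y))) / (sx * sy)
    r2 <- r^2
    if (r2 >= 1 - 1e-12) return(1e15)
    r2 / (1 - r2) * (n - 2)
  }, numeric(1))
}

oracle_mae <- function(p, t) {
  s <- 0
  for (i in seq_along(p)) s <- s + abs(p[i] - t[i])
  s / length(p)
}

oracle_mse <- function(p, t) {
  s <- 0
  for (i in seq_along(p)) s <- s + (p[i] - t[i])^2
  s / length(p)
}

oracle_corr <- function(p, t) {
  mp <- mean(p); mt <- mean(t)
  sum((p - mp) * (t - mt)) /
    sqrt(sum((p - mp)^2) * sum((t - mt)^2))
}
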