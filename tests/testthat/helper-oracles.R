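# Shared fixtures and independent oracles, all built in code.

# Build a WindowSet directly from one 12-channel sample block, so feature
# statistics can be tested against hand-computed values.
make_ws <- function(block, window_len_s = nrow(block) / 50, fs = 50) {
  block <- as.matrix(block)
  colnames(block) <- default_feature_channels()[seq_len(ncol(block))]
  w <- array(block, c(nrow(block), ncol(block), 1L),
             dimnames = list(NULL, colnames(block), NULL))
  structure(list(windows = w, starts_s = 0, window_len_s = window_len_s,
                 overlap_fraction = 0.5, sample_rate_hz = fs, labels = NULL),
            class = "WindowSet")
}

# Brute-force enumeration of valid window start positions.
bf_window_count <- function(duration_s, window_len_s, overlap_fraction, fs = 50) {
  n <- round(duration_s * fs)
  spw <- round(window_len_s * fs)
  step <- round(window_len_s * (1 - overlap_fraction) * fs)
  count <- 0L
  i <- 1L
  while (i + spw - 1L <= n) {
    count <- count + 1L
    i <- i + step
  }
  count
}

# Two-parameter OLS by direct summation of the normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x * x)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- slope * x + intercept
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept,
       r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
       f_stat = (ss_tot - ss_res) / (ss_res / (n - 2)))
}

# Adjusted Fisher-Pearson skewness and sample excess kurtosis by direct
# moment summation.
skew_oracle <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}

kurt_oracle <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- sum((x - m)^2) / n
  m4 <- sum((x - m)^4) / n
  g2 <- m4 / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

autocov_oracle <- function(x) {
  n <- length(x)
  m <- mean(x)
  sum((x[-n] - m) * (x[-1] - m)) / (n - 1)
}

# A small labelled feature table from a simulated session.
session_features <- function(seed = 1, n_sets = 4, noise_sd = 0.05, ...) {
  s <- simulate_session(session_spec(seed = seed, n_sets = n_sets,
                                     noise_sd = noise_sd, ...))
  ws <- segment(s$left, s$right, s$labels)
  extract_features(ws)
}
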