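test_that("denoise is the identity, idempotent, and rejects unknown strategies", {
  s <- simulate_session(session_spec(seed = 1, n_sets = 1))
  expect_identical(denoise(s$left), s$left)
  expect_identical(denoise(denoise(s$left)), denoise(s$left))
  expect_error(denoise(s$left, "wavelet"), "unsupported")
})

test_that("window counts match brute-force start enumeration", {
  mk <- function(duration_s, seed = 1) {
    m <- matrix(rnorm(duration_s * 50 * 9), ncol = 9,
                dimnames = list(NULL, trainload:::SENSOR_CHANNELS))
    sensor_stream(m, 50, "left_wrist")
  }
  set.seed(99)
  # the canonical geometry: 60 s, 5 s windows, 50% overlap -> 23 windows
  l <- mk(60)
  r <- sensor_stream(l$samples, 50, "right_wrist")
  ws <- segment(l, r, window_len_s = 5, overlap_fraction = 0.5)
  expect_equal(dim(ws$windows)[3], 23L)
  expect_equal(ws$starts_s, seq(0, 55, by = 2.5))

  # exact tiling without overlap, and a single-window stream
  expect_equal(dim(segment(l, r, window_len_s = 5,
                           overlap_fraction = 0)$windows)[3], 12L)
  l5 <- mk(5)
  r5 <- sensor_stream(l5$samples, 50, "right_wrist")
  expect_equal(dim(segment(l5, r5)$windows)[3], 1L)

  # grid of (duration, window, overlap) against the enumeration oracle
  for (dur in c(7, 20, 33, 61)) {
    li <- mk(dur)
    ri <- sensor_stream(li$samples, 50, "right_wrist")
    for (len in c(2, 5)) {
      for (ov in c(0, 0.25, 0.5, 0.75)) {
        got <- dim(segment(li, ri, window_len_s = len,
                           overlap_fraction = ov)$windows)[3]
        expect_equal(got, bf_window_count(dur, len, ov),
                     info = sprintf("dur=%g len=%g ov=%g", dur, len, ov))
      }
    }
  }

  # common span shorter than one window -> empty set with warning
  l2 <- mk(2)
  r2 <- sensor_stream(l2$samples, 50, "right_wrist")
  expect_warning(ws0 <- segment(l2, r2), "shorter than one window")
  expect_equal(dim(ws0$windows)[3], 0L)
})

test_that("window labels use majority occupancy with ties to the earlier interval", {
  m <- matrix(0, 500, 9, dimnames = list(NULL, trainload:::SENSOR_CHANNELS))
  l <- sensor_stream(m, 50, "left_wrist")
  r <- sensor_stream(m, 50, "right_wrist")
  # exact 2.5/2.5 tie inside the first window -> earlier interval's code
  lt <- label_track(data.frame(start_s = c(0, 2.5), end_s = c(2.5, 10),
                               code = c(4, 2)))
  ws <- segment(l, r, lt)
  expect_equal(ws$labels[1], 4L)
  # clear majority elsewhere
  expect_equal(ws$labels[2], 2L)  # window [2.5, 7.5) fully code 2
})

test_that("feature vectors are 72-dimensional with hand-computed statistics", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  block <- matrix(rnorm(8 * 12), 8, 12)
  block[, 1] <- x
  block[, 2] <- 3  # constant channel
  ft <- extract_features(make_ws(block))
  expect_equal(ncol(ft), 72L)
  expect_false("label" %in% names(ft))

  ch <- default_feature_channels()[1]
  expect_equal(ft[[paste0(ch, ".mean")]], 4.5)
  expect_equal(ft[[paste0(ch, ".sd")]], sqrt(6))
  expect_equal(ft[[paste0(ch, ".iqr")]], 3.5)
  expect_equal(ft[[paste0(ch, ".kurtosis")]], kurt_oracle(x))
  expect_equal(ft[[paste0(ch, ".skewness")]], skew_oracle(x))
  expect_equal(ft[[paste0(ch, ".autocov")]], autocov_oracle(x))

  ch2 <- default_feature_channels()[2]
  expect_equal(unlist(ft[paste0(ch2, ".", trainload:::FEATURE_STATS)],
                      use.names = FALSE),
               c(3, 0, 0, 0, 0, 0))  # constant channel: finite, not NaN
})

test_that("random windows agree with direct-summation oracles per statistic", {
  set.seed(7)
  for (rep in 1:5) {
    block <- matrix(rnorm(250 * 12), 250, 12)
    ft <- extract_features(make_ws(block))
    j <- sample(12, 1)
    ch <- default_feature_channels()[j]
    x <- block[, j]
    expect_equal(ft[[paste0(ch, ".mean")]], mean(x))
    expect_equal(ft[[paste0(ch, ".sd")]], sqrt(sum((x - mean(x))^2) / 249))
    expect_equal(ft[[paste0(ch, ".kurtosis")]], kurt_oracle(x))
    expect_equal(ft[[paste0(ch, ".skewness")]], skew_oracle(x))
    expect_equal(ft[[paste0(ch, ".autocov")]], autocov_oracle(x))
  }
})

test_that("features respond to translation and scaling as the statistics dictate", {
  set.seed(21)
  block <- matrix(rnorm(100 * 12), 100, 12)
  base <- extract_features(make_ws(block))
  shifted <- block; shifted[, 3] <- shifted[, 3] + 2.5
  scaled <- block; scaled[, 3] <- scaled[, 3] * 1.7
  ft_sh <- extract_features(make_ws(shifted))
  ft_sc <- extract_features(make_ws(scaled))
  ch <- default_feature_channels()[3]
  others <- setdiff(names(base), paste0(ch, ".mean"))

  expect_equal(ft_sh[[paste0(ch, ".mean")]], base[[paste0(ch, ".mean")]] + 2.5)
  expect_equal(unlist(ft_sh[others]), unlist(base[others]))

  expect_equal(ft_sc[[paste0(ch, ".sd")]], base[[paste0(ch, ".sd")]] * 1.7)
  expect_equal(ft_sc[[paste0(ch, ".iqr")]], base[[paste0(ch, ".iqr")]] * 1.7)
  expect_equal(ft_sc[[paste0(ch, ".autocov")]],
               base[[paste0(ch, ".autocov")]] * 1.7^2)
  expect_equal(ft_sc[[paste0(ch, ".skewness")]], base[[paste0(ch, ".skewness")]])
  expect_equal(ft_sc[[paste0(ch, ".kurtosis")]], base[[paste0(ch, ".kurtosis")]])
})

test_that("the covariance feature supports the with-time interpretation", {
  set.seed(8)
  block <- matrix(rnorm(50 * 12), 50, 12)
  ft <- extract_features(make_ws(block), covariance = "cov_with_time")
  ch <- default_feature_channels()[5]
  expect_equal(ft[[paste0(ch, ".autocov")]], cov(block[, 5], 1:50))
})

test_that("channel subset is validated", {
  block <- matrix(rnorm(50 * 12), 50, 12)
  ws <- make_ws(block)
  expect_error(extract_features(ws, channels = c("nope", default_feature_channels()[1:11])),
               "not present")
  expect_error(extract_features(ws, channels = default_feature_channels()[1:6]),
               "12 channels")
})
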