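test_that("moving average matches its definition on hand cases", {
  expect_equal(moving_average(accel_stream(rep(3.5, 10)), 5)$values,
               rep(3.5, 10))
  # full centered window of 5 first fits at the third sample of 1..7
  expect_equal(moving_average(accel_stream(1:7), 5)$values[3], 3)
  # unit impulse spreads over exactly the window support
  x <- rep(0, 21); x[11] <- 1
  out <- moving_average(accel_stream(x), 5)$values
  expect_equal(which(out > 0), 9:13)
  expect_equal(out[9:13], rep(0.2, 5))
  expect_error(moving_average(accel_stream(1:5), 0), ">= 1")
})

test_that("moving average equals the brute-force oracle on random streams", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(5:80, 1)
    w <- sample(c(1, 3, 5, 7, 9), 1)
    x <- rnorm(n)
    expect_equal(moving_average(accel_stream(x), w)$values,
                 oracle_moving_average(x, w))
  }
})

test_that("peak segmentation finds bumps between sub-threshold minima", {
  # strictly monotone stream: no delimiting pair
  expect_length(detect_peak_segments(accel_stream(seq(0, 5, by = 0.1)), 10), 0)

  # two separated smooth bumps of heights 1 and 2
  t <- seq(0, 1, length.out = 31)
  bump <- function(a) a * 0.5 * (1 - cos(2 * pi * t))
  x <- c(rep(0, 10), bump(1), rep(0, 10), bump(2), rep(0, 10))
  segs <- detect_peak_segments(accel_stream(x), 0.2)
  expect_length(segs, 2)
  expect_equal(vapply(segs, function(s) s$raw_max, numeric(1)), c(1, 2))

  # a bump that never returns below threshold before the stream ends
  x2 <- c(rep(0, 10), seq(0, 3, length.out = 20))
  expect_length(detect_peak_segments(accel_stream(x2), 0.2), 0)
})

test_that("peak segmentation matches the exhaustive-scan oracle", {
  set.seed(202)
  for (rep in 1:100) {
    n <- sample(20:200, 1)
    x <- cumsum(rnorm(n))          # wandering continuous stream, no ties
    thr <- stats::quantile(x, runif(1, 0.2, 0.8))
    segs <- detect_peak_segments(accel_stream(x), thr)
    orc <- oracle_peak_segments(x, thr)
    expect_length(segs, length(orc))
    if (length(orc)) {
      expect_equal(vapply(segs, function(s) s$start_index, integer(1)),
                   vapply(orc, function(s) s$start, integer(1)))
      expect_equal(vapply(segs, function(s) s$raw_max, numeric(1)),
                   vapply(orc, function(s) s$raw_max, numeric(1)))
    }
  }
})

test_that("emitted segments satisfy their structural invariants", {
  set.seed(7)
  x <- cumsum(rnorm(300))
  thr <- stats::median(x)
  for (s in detect_peak_segments(accel_stream(x), thr)) {
    expect_gte(length(s$raw_values), 3)
    expect_equal(s$raw_max, max(s$raw_values))
    expect_lt(s$raw_values[1], thr)
    expect_lt(s$raw_values[length(s$raw_values)], thr)
    expect_gt(s$raw_max, max(s$raw_values[1], s$raw_values[length(s$raw_values)]))
  }
})

test_that("peak normalization maps segments onto [10, 20]", {
  expect_equal(normalize_peak(c(2, 4, 6)), c(10, 15, 20))
  expect_equal(normalize_peak(c(5, 5, 5)), c(10, 10, 10))
  set.seed(9)
  for (rep in 1:50) {
    x <- rnorm(sample(3:50, 1))
    nx <- normalize_peak(x)
    expect_equal(min(nx), 10)
    expect_equal(max(nx), 20)
    # invariance under positive affine transforms of the raw segment
    a <- runif(1, 0.1, 10); b <- rnorm(1, sd = 5)
    expect_equal(normalize_peak(a * x + b), nx)
  }
})

test_that("fit_window pads short and truncates long inputs", {
  cfg <- pipeline_config()
  e <- fit_window(rep(15, 80), cfg)
  expect_length(e$norm_values, 120)
  expect_equal(e$norm_values[81:120], rep(10, 40))
  expect_equal(e$original_len, 80L)

  e2 <- fit_window(rep(12, 120), cfg)
  expect_equal(e2$norm_values, rep(12, 120))

  e3 <- fit_window(seq_len(150), cfg)
  expect_equal(e3$norm_values, as.numeric(1:120))
  expect_equal(e3$original_len, 120L)

  expect_error(fit_window(numeric(0), cfg), "empty")
})

test_that("preprocess_stream composes the stages and keeps episode invariants", {
  cfg <- pipeline_config()
  expect_length(preprocess_stream(accel_stream(rep(1, 200)), cfg), 0)

  sim <- simulate_session(sim_config(noise_sd = 0, n_nonsip_events = 0,
                                     n_cycles = 2, sips_per_cycle = 5))
  eps <- preprocess_stream(sim$stream, cfg)
  expect_length(eps, 10)
  for (e in eps) {
    expect_length(e$norm_values, cfg$episode_len)
    expect_true(all(e$norm_values >= cfg$norm_low - 1e-12))
    expect_true(all(e$norm_values <= cfg$norm_high + 1e-12))
    if (e$original_len < cfg$episode_len)
      expect_equal(e$norm_values[(e$original_len + 1):cfg$episode_len],
                   rep(cfg$pad_value, cfg$episode_len - e$original_len))
  }
  # raw_max carries the source segment's raw height
  expect_equal(vapply(eps, function(e) e$raw_max, numeric(1)),
               vapply(detect_peak_segments(moving_average(sim$stream, 5)),
                      function(s) s$raw_max, numeric(1)))
})
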