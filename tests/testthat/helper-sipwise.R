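# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, .fixtures)) assign(key, build(), .fixtures)
  get(key, .fixtures)
}

# Balanced labeled episode set from the simulator (the sip-classifier world).
fixture_episode_dataset <- function() memo("episodes", function() {
  ds <- simulate_episode_dataset(100, 100, sim_config(seed = 7))
  list(episodes = ds, labels = attr(ds, "labels"),
       features = extract_sip_feature_table(ds))
})

# A trained 1-hidden-layer, 3-neuron sip classifier.
fixture_sip_model <- function() memo("sip_model", function() {
  d <- fixture_episode_dataset()
  train_sip_classifier(d$features, d$labels, hidden_sizes = 3L,
                       config = sip_train_config(seed = 0))
})

# A first-sip detector trained on noise-free cycles in the raw-signal
# height world (baseline 1 + amplitudes ~0.5, increments 0.05).
fixture_firstsip_model <- function() memo("firstsip_model", function() {
  tr <- simulate_sip_height_sequence(30, c(4, 10), base = 1.5,
                                     increment = 0.05, seed = 3)
  train_firstsip_detector(firstsip_feature_table(tr$heights), tr$is_first_sip,
                          config = firstsip_train_config(seed = 0))
})

# Brute-force centered moving average (independent of the implementation).
oracle_moving_average <- function(x, window) {
  n <- length(x)
  h <- window %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(h, i - 1, n - i)
    out[i] <- mean(x[(i - k):(i + k)])
  }
  out
}

# Exhaustive-scan peak segmentation oracle: naive per-sample extremum loops
# and pairwise minima scanning. Assumes no tied neighbouring values (use
# continuous random streams).
oracle_peak_segments <- function(x, thr) {
  n <- length(x)
  is_min <- is_max <- logical(n)
  for (i in 2:(n - 1)) {
    is_min[i] <- x[i] < x[i - 1] && x[i] < x[i + 1]
    is_max[i] <- x[i] > x[i - 1] && x[i] > x[i + 1]
  }
  is_min[1] <- x[1] < x[2]
  is_min[n] <- x[n] < x[n - 1]
  mins <- which(is_min & x < thr)
  segs <- list()
  if (length(mins) >= 2) {
    for (i in seq_len(length(mins) - 1)) {
      a <- mins[i]; b <- mins[i + 1]
      inner <- which(is_max)
      inner <- inner[inner > a & inner < b]
      if (length(inner) &&
          any(x[inner] > x[a] & x[inner] > x[b] & x[inner] > thr))
        segs[[length(segs) + 1]] <- list(start = a, end = b, raw_max = max(x[a:b]))
    }
  }
  segs
}

# Independent forward pass: explicit per-observation loops.
oracle_forward <- function(model, X) {
  Xs <- sweep(sweep(X, 2, model$scaler_mean, `-`), 2, model$scaler_scale, `/`)
  out <- numeric(nrow(Xs))
  for (r in seq_len(nrow(Xs))) {
    a <- Xs[r, ]
    for (l in seq_along(model$weights)) {
      z <- numeric(ncol(model$weights[[l]]))
      for (j in seq_along(z))
        z[j] <- sum(a * model$weights[[l]][, j]) + model$biases[[l]][j]
      a <- if (l < length(model$weights)) pmax(z, 0) else 1 / (1 + exp(-z))
    }
    out[r] <- a
  }
  out
}

# A clean single-bump stream: quiet margins around a raised-cosine tilt.
bump_stream <- function(amp = 1, n_bump = 40, margin = 30, baseline = 0,
                        fs = 20) {
  t <- seq(0, 1, length.out = n_bump)
  accel_stream(baseline + c(rep(0, margin), amp * 0.5 * (1 - cos(2 * pi * t)),
                            rep(0, margin)), fs)
}
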