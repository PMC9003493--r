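test_that("simulated sessions are reproducible from the seed", {
  cfg <- sim_config(seed = 5)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$stream$values, s2$stream$values)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_session(sim_config(seed = 6))
  expect_false(identical(s1$stream$values, s3$stream$values))
})

test_that("zero-noise sessions are recovered exactly by preprocessing", {
  sim <- simulate_session(sim_config(noise_sd = 0, n_nonsip_events = 0,
                                     n_cycles = 2, sips_per_cycle = 5))
  eps <- preprocess_stream(sim$stream)
  expect_length(eps, 10)

  raw_max <- vapply(eps, function(e) e$raw_max, numeric(1))
  truth <- sim$truth
  # amplitudes rise strictly within each cycle and drop at the refill
  for (cy in 1:2) {
    h <- raw_max[truth$cycle == cy]
    expect_true(all(diff(h) > 0))
  }
  expect_lt(raw_max[6], raw_max[5])  # refill drop
  # the generated amplitudes sit on baseline + amp (within filter smoothing)
  expect_equal(raw_max, sim$config$baseline + truth$amplitude, tolerance = 0.02)
  expect_equal(label_episodes(eps, truth), rep(1L, 10))
})

test_that("a stationary-only session produces no episodes", {
  mix <- stats::setNames(c(0, 0, 0, 1, 0, 0),
                         c("walk_flat", "walk_stairs", "bag_walk",
                           "stationary", "car", "fidget"))
  sim <- simulate_session(sim_config(noise_sd = 0, n_cycles = 1,
                                     sips_per_cycle = 0, n_nonsip_events = 3,
                                     nonsip_mix = mix))
  expect_length(preprocess_stream(sim$stream), 0)
})

test_that("session packing respects a fixed session length", {
  expect_error(simulate_session(sim_config(session_length_s = 5)),
               "infeasible packing")
  sim <- simulate_session(sim_config(session_length_s = 600, n_nonsip_events = 0))
  expect_length(sim$stream$values, 600 * 20)
})

test_that("episode datasets have exact class counts and labels", {
  ds <- simulate_episode_dataset(30, 20, sim_config(seed = 1))
  expect_length(ds, 50)
  expect_equal(sum(attr(ds, "labels") == 1), 30)
  expect_equal(sum(attr(ds, "labels") == 0), 20)

  ds0 <- simulate_episode_dataset(0, 10, sim_config(seed = 2))
  expect_equal(attr(ds0, "labels"), rep(0L, 10))

  ds1 <- simulate_episode_dataset(5, 5, sim_config(seed = 3))
  ds2 <- simulate_episode_dataset(5, 5, sim_config(seed = 3))
  expect_identical(lapply(ds1, `[[`, "norm_values"),
                   lapply(ds2, `[[`, "norm_values"))
})

test_that("sip-height sequences encode the refill structure", {
  s <- simulate_sip_height_sequence(2, 3, base = 30, increment = 5, seed = 1)
  expect_equal(s$heights, c(30, 35, 40, 30, 35, 40))
  expect_equal(s$is_first_sip, c(1L, 0L, 0L, 1L, 0L, 0L))

  one <- simulate_sip_height_sequence(1, 6, seed = 2)
  expect_equal(sum(one$is_first_sip), 1L)

  flat <- simulate_sip_height_sequence(3, 4, increment = 0, seed = 3)
  ft <- firstsip_feature_table(flat$heights)
  expect_true(all(ft$f1[flat$is_first_sip == 0] == 0))
})

test_that("generated sip amplitudes separate refills by at least 3 increments", {
  cfg <- sim_config(n_cycles = 3, sips_per_cycle = c(4, 8), noise_sd = 0, seed = 9)
  sim <- simulate_session(cfg)
  sips <- sim$truth[sim$truth$kind == "sip", ]
  inc <- cfg$within_cycle_amplitude_increment
  for (cy in 2:3) {
    last_prev <- utils::tail(sips$amplitude[sips$cycle == cy - 1], 1)
    first_cur <- sips$amplitude[sips$cycle == cy][1]
    expect_gte(last_prev - first_cur, 3 * inc)
  }
})
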