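test_that("init_state divides the bottle into the expected sips", {
  s <- init_state(500, 10)
  expect_equal(s$v_sip, 50)
  expect_equal(s$v_intake, 0)
  expect_equal(s$s_count, 0L)
  expect_equal(init_state(500, 1)$v_sip, 500)
  expect_error(init_state(500, 0), ">= 1")
  expect_error(init_state(-1, 10), "> 0")
})

test_that("a perfect cycle closes with zero correction", {
  # 10 non-first sips then a first sip: consumed exactly one bottle
  flags <- c(TRUE, rep(FALSE, 9), TRUE)
  r <- run_volume_estimator(rep(NA, 11), flags, 500, 10)
  tr <- r$trajectory
  expect_equal(tr$v_intake[10], 500)         # cycle ends on the bottle volume
  expect_equal(tr$v_intake[11], 550)         # snap (no-op) + new first sip
  expect_equal(r$state$v_sip, 50)            # re-estimate confirms 50 mL
})

test_that("missed sips are repaired at the next first sip", {
  # 8 of 10 sips detected: cycle total 400 snaps up to 500, v_sip -> 62.5
  flags <- c(TRUE, rep(FALSE, 7), TRUE)
  r <- run_volume_estimator(rep(NA, 9), flags, 500, 10)
  tr <- r$trajectory
  expect_equal(tr$v_intake[8], 400)
  expect_equal(tr$v_intake[9] - r$state$v_sip, 500)  # boundary snapped to 500
  expect_equal(r$state$v_sip, 62.5)
})

test_that("a missed first sip caps the cycle then snaps to two bottles", {
  # two true 10-sip cycles, the intervening first sip undetected
  flags <- rep(FALSE, 21); flags[c(1, 21)] <- TRUE
  r <- run_volume_estimator(rep(NA, 21), flags, 500, 10)
  tr <- r$trajectory
  # cap: estimate freezes at one bottle while undetected sips accrue
  expect_equal(tr$v_intake[10], 500)
  expect_equal(tr$v_intake[20], 500)
  # the next detected first sip recognizes k* = 2 bottles
  expect_equal(tr$v_intake[21] - r$state$v_sip, 1000)
  expect_equal(r$state$v_sip, 1000 / 20)
})

test_that("a first sip closing a one-sip cycle snaps to a single bottle", {
  flags <- c(TRUE, TRUE, rep(FALSE, 3))
  r <- run_volume_estimator(rep(NA, 5), flags, 500, 10)
  # k is never allowed below 1: the 1-sip cycle maps to one full bottle
  expect_equal(r$trajectory$v_intake[2], 500 + r$trajectory$v_sip[2])
  # and the follow-up sips are capped at the new cycle's bottle
  expect_equal(r$state$v_intake, 1000)
})

test_that("intake is non-decreasing and cycles never exceed the bottle", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    flags <- runif(n) < 0.15
    r <- run_volume_estimator(rep(NA, n), flags, 500,
                              sample(5:15, 1))
    v <- r$trajectory$v_intake
    expect_true(all(diff(v) >= 0))
  }
})

test_that("zero detected sips produce a flat zero trajectory", {
  r <- run_volume_estimator(numeric(0), logical(0), 500, 10)
  expect_equal(nrow(r$trajectory), 0L)
  expect_equal(r$state$v_intake, 0)
})

test_that("boundary error vanishes under perfect detection, any true sip size", {
  # true world: 3 cycles x 8 sips of 62.5 mL; detector output perfect
  spc <- 8; v_bottle <- 500
  flags <- rep(c(TRUE, rep(FALSE, spc - 1)), 3)
  true_intake <- cumsum(rep(v_bottle / spc, 3 * spc))
  r <- run_volume_estimator(rep(NA, length(flags)), flags, v_bottle,
                            expected_sips_per_bottle = 12,  # wrong cold start
                            true_intake = true_intake)
  tr <- r$trajectory
  # at every detected first sip the snap makes the estimate exact, and the
  # re-estimated per-sip volume equals the true one
  firsts <- which(tr$is_first_sip)[-1]
  expect_equal(tr$v_intake[firsts], true_intake[firsts])
  expect_equal(unique(tr$v_sip[firsts]), v_bottle / spc)
})

test_that("randomly dropped sips give bounded, non-accumulating error", {
  set.seed(23)
  v_bottle <- 500; spc <- 10; n_cycles <- 6
  q <- 0.2
  for (mc in 1:10) {
    # exactly a fraction q of each cycle's sips dropped, positions random;
    # first sips always detected
    keep <- lapply(seq_len(n_cycles), function(cy) {
      k <- rep(TRUE, spc)
      k[sample(2:spc, round(q * spc))] <- FALSE
      k
    })
    flags <- unlist(lapply(keep, function(k) c(TRUE, rep(FALSE, sum(k) - 1L))))
    true_after <- unlist(lapply(seq_len(n_cycles), function(cy) {
      per_sip <- v_bottle / spc
      base <- (cy - 1) * v_bottle
      sips <- which(keep[[cy]])
      base + sips * per_sip
    }))
    r <- run_volume_estimator(rep(NA, length(flags)), flags, v_bottle, spc,
                              true_intake = true_after)
    tr <- r$trajectory
    # after each correction (first sip, before its own volume is added) the
    # cycle total sits exactly on whole bottles: errors do not accumulate
    firsts <- which(tr$is_first_sip)[-1]
    closed <- tr$v_intake[firsts] - tr$v_sip[firsts]
    expect_equal(closed, (seq_along(firsts)) * v_bottle)
    # intra-cycle error bounded by the dropped volume plus one sip estimate
    expect_true(all(abs(tr$v_intake - tr$true_v_ml) <=
                      q * v_bottle + max(tr$v_sip) + 1e-9))
  }
})

test_that("trajectories are deterministic for identical inputs", {
  flags <- c(TRUE, rep(FALSE, 5), TRUE, rep(FALSE, 5))
  r1 <- run_volume_estimator(rep(NA, 12), flags, 750, 6)
  r2 <- run_volume_estimator(rep(NA, 12), flags, 750, 6)
  expect_identical(r1$trajectory, r2$trajectory)
})

test_that("the literal add-then-correct order is available", {
  flags <- c(TRUE, rep(FALSE, 9), TRUE)
  r <- run_volume_estimator(rep(NA, 11), flags, 500, 10, literal_order = TRUE)
  # the closing snap lands on the bottle volume either way
  expect_equal(r$trajectory$v_intake[11], 500)
})
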