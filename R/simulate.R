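NONSIP_ACTIVITIES <- c("walk_flat", "walk_stairs", "bag_walk", "stationary",
                       "car", "fidget")

#' Simulation configuration
#'
#' Describes the synthetic drinking world the generator emulates. A session
#' is a quiet upright-bottle baseline (x-axis reading 1.0 raw unit, i.e.
#' gravity) interrupted by drinking cycles and non-drinking activities:
#'
#' * each sip is a smooth raised-cosine tilt bump of 1-6 s; within a cycle
#'   the bump amplitude grows sip over sip (`sip_base_amplitude` plus
#'   `(rank - 1) * within_cycle_amplitude_increment`) because an emptier
#'   bottle needs a steeper tilt, and drops back to the base at a refill —
#'   the first-sip signature;
#' * non-sip activities are oscillatory (walking ~2 Hz, stairs, bottle in a
#'   swinging bag), noisy (stationary, moving car) or spiky (sub-second
#'   in-hand fidgeting);
#' * white Gaussian sensor noise at `noise_sd` is added throughout.
#'
#' Only relative amplitudes matter downstream (peak normalization removes
#' scale), so units are arbitrary raw accelerometer units with baseline 1.
#'
#' @param sample_rate_hz sampling rate, Hz.
#' @param n_cycles number of drinking cycles (refill-to-refill periods).
#' @param sips_per_cycle sips per cycle: a single integer or a
#'   `c(min, max)` range sampled per cycle.
#' @param sip_duration_s `c(min, max)` sip duration range, within `[1, 6]` s
#'   (6 s is one full episode window).
#' @param sip_base_amplitude tilt-bump amplitude of a cycle's first sip.
#' @param within_cycle_amplitude_increment amplitude growth per sip (> 0).
#' @param baseline upright-bottle raw reading.
#' @param gap_s `c(min, max)` quiet-gap range between events, seconds.
#' @param n_nonsip_events non-sip activity bouts inserted per session.
#' @param nonsip_mix named non-negative weights over the six activities.
#' @param noise_sd sensor noise standard deviation, raw units.
#' @param bottle_volume_ml bottle volume; each cycle's sip volumes are equal
#'   and sum to it.
#' @param session_length_s optional fixed session length; an error is
#'   raised if the generated activities do not fit.
#' @param seed integer seed; every generator output is a deterministic
#'   function of (config, seed).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sample_rate_hz = 20,
                       n_cycles = 2L,
                       sips_per_cycle = 5L,
                       sip_duration_s = c(1.5, 4),
                       sip_base_amplitude = 0.5,
                       within_cycle_amplitude_increment = 0.05,
                       baseline = 1.0,
                       gap_s = c(2, 5),
                       n_nonsip_events = 3L,
                       nonsip_mix = stats::setNames(rep(1, 6), NONSIP_ACTIVITIES),
                       noise_sd = 0.01,
                       bottle_volume_ml = 500,
                       session_length_s = NULL,
                       seed = 1L) {
  stopifnot(sample_rate_hz > 0, n_cycles >= 1,
            all(sips_per_cycle >= 0), length(sips_per_cycle) %in% c(1L, 2L),
            length(sip_duration_s) == 2L,
            sip_duration_s[1] >= 1, sip_duration_s[2] <= 6,
            sip_duration_s[1] <= sip_duration_s[2],
            sip_base_amplitude > 0, within_cycle_amplitude_increment > 0,
            length(gap_s) == 2L, gap_s[1] > 0, gap_s[1] <= gap_s[2],
            n_nonsip_events >= 0, noise_sd >= 0, bottle_volume_ml > 0)
  stopifnot(all(NONSIP_ACTIVITIES %in% names(nonsip_mix)),
            all(nonsip_mix >= 0), sum(nonsip_mix) > 0)
  structure(list(sample_rate_hz = as.numeric(sample_rate_hz),
                 n_cycles = as.integer(n_cycles),
                 sips_per_cycle = as.integer(sips_per_cycle),
                 sip_duration_s = as.numeric(sip_duration_s),
                 sip_base_amplitude = as.numeric(sip_base_amplitude),
                 within_cycle_amplitude_increment =
                   as.numeric(within_cycle_amplitude_increment),
                 baseline = as.numeric(baseline),
                 gap_s = as.numeric(gap_s),
                 n_nonsip_events = as.integer(n_nonsip_events),
                 nonsip_mix = nonsip_mix[NONSIP_ACTIVITIES],
                 noise_sd = as.numeric(noise_sd),
                 bottle_volume_ml = as.numeric(bottle_volume_ml),
                 session_length_s = session_length_s,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Raised-cosine bump: 0 -> amp -> 0 over n samples, single interior maximum.
raised_cosine <- function(n, amp) {
  t <- seq(0, 1, length.out = n)
  amp * 0.5 * (1 - cos(2 * pi * t))
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

# One non-sip activity bout (values relative to 0 baseline).
nonsip_kernel <- function(activity, fs) {
  dur <- switch(activity,
    walk_flat = runif1(c(3, 8)), walk_stairs = runif1(c(3, 8)),
    bag_walk = runif1(c(3, 8)), stationary = runif1(c(3, 8)),
    car = runif1(c(3, 8)), fidget = runif1(c(1, 3)))
  n <- max(3L, round(dur * fs))
  t <- (seq_len(n) - 1) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  v <- switch(activity,
    # arm-swing oscillation while walking, ~2 Hz step cadence
    walk_flat = 0.30 * sin(2 * pi * 2.0 * t + phase),
    # slower, larger excursions on stairs
    walk_stairs = 0.45 * sin(2 * pi * 1.5 * t + phase),
    # bag sway: slow oscillation plus jostle noise
    bag_walk = 0.25 * sin(2 * pi * 1.0 * t + phase) +
               stats::rnorm(n, 0, 0.05),
    # bottle parked on a table: sensor noise only
    stationary = stats::rnorm(n, 0, 0.005),
    # cup holder in a moving car: road vibration
    car = stats::rnorm(n, 0, 0.03),
    # in-hand fidgeting: a few sub-second spikes
    fidget = {
      v <- numeric(n)
      for (s in seq_len(sample(1:3, 1))) {
        len <- max(3L, round(runif1(c(0.3, 0.8)) * fs))
        start <- sample(max(1L, n - len + 1L), 1)
        idx <- start:min(n, start + len - 1L)
        v[idx] <- v[idx] + raised_cosine(length(idx), runif1(c(0.4, 0.7)))
      }
      v
    })
  v
}

#' Simulate a full drinking session
#'
#' Generates one session stream plus its ground truth: sips laid out in
#' `n_cycles` drinking cycles with rising within-cycle amplitudes, non-sip
#' activity bouts interleaved at random positions, quiet gaps in between,
#' and additive sensor noise. The first sip of every cycle carries the
#' cycle-minimum amplitude; a refill event sits just before it (from cycle
#' 2 on). True per-sip volumes are equal within a cycle and sum to the
#' bottle volume.
#'
#' @param config a [sim_config()].
#' @return A list:
#' \describe{
#'   \item{`stream`}{the raw `accel_stream`.}
#'   \item{`truth`}{data.frame of events: `kind` ("sip"/activity name),
#'     `start_sample`, `end_sample`, `amplitude`, `is_first_sip`,
#'     `cycle`, `true_volume_ml`.}
#'   \item{`refill_samples`}{sample indices of refill events.}
#'   \item{`config`}{the input config.}
#' }
#' @export
simulate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sample_rate_hz
  with_seed(config$seed, {
    spc <- if (length(config$sips_per_cycle) == 2L)
      sample(config$sips_per_cycle[1]:config$sips_per_cycle[2], config$n_cycles,
             replace = TRUE)
    else rep(config$sips_per_cycle, config$n_cycles)

    # event plan: sips in cycle order, non-sip bouts at random slots
    events <- list()
    for (cy in seq_len(config$n_cycles)) {
      for (r in seq_len(spc[cy])) {
        events[[length(events) + 1L]] <- list(
          kind = "sip", cycle = cy, rank = r,
          amplitude = config$sip_base_amplitude +
            (r - 1) * config$within_cycle_amplitude_increment,
          is_first_sip = (r == 1L),
          true_volume_ml = config$bottle_volume_ml / spc[cy])
      }
    }
    if (config$n_nonsip_events > 0L) {
      acts <- sample(NONSIP_ACTIVITIES, config$n_nonsip_events, replace = TRUE,
                     prob = config$nonsip_mix / sum(config$nonsip_mix))
      slots <- sample(length(events) + 1L, config$n_nonsip_events, replace = TRUE)
      ord <- order(slots, decreasing = TRUE)  # insert back-to-front, no shifts
      for (j in ord) {
        ev <- list(kind = acts[j], cycle = NA_integer_, rank = NA_integer_,
                   amplitude = NA_real_, is_first_sip = FALSE,
                   true_volume_ml = 0)
        events <- append(events, list(ev), after = slots[j] - 1L)
      }
    }

    # lay events on the timeline with quiet gaps
    pieces <- list(rep(0, round(runif1(config$gap_s) * fs)))
    truth <- list()
    refills <- integer(0)
    pos <- length(pieces[[1]])
    for (ev in events) {
      v <- if (ev$kind == "sip") {
        n <- max(3L, round(runif1(config$sip_duration_s) * fs))
        raised_cosine(n, ev$amplitude)
      } else nonsip_kernel(ev$kind, fs)
      if (ev$kind == "sip" && ev$is_first_sip && ev$cycle > 1L)
        refills <- c(refills, pos)      # refill just before this sip starts
      truth[[length(truth) + 1L]] <- data.frame(
        kind = ev$kind, start_sample = pos + 1L,
        end_sample = pos + length(v),
        amplitude = ev$amplitude, is_first_sip = ev$is_first_sip,
        cycle = ev$cycle, true_volume_ml = ev$true_volume_ml)
      gap <- rep(0, round(runif1(config$gap_s) * fs))
      pieces[[length(pieces) + 1L]] <- v
      pieces[[length(pieces) + 1L]] <- gap
      pos <- pos + length(v) + length(gap)
    }

    values <- config$baseline + unlist(pieces)
    if (!is.null(config$session_length_s)) {
      need <- round(config$session_length_s * fs)
      if (length(values) > need)
        stop("infeasible packing: activities need ",
             round(length(values) / fs), " s but session_length_s is ",
             config$session_length_s)
      values <- c(values, rep(config$baseline, need - length(values)))
    }
    if (config$noise_sd > 0)
      values <- values + stats::rnorm(length(values), 0, config$noise_sd)

    empty_truth <- data.frame(kind = character(0), start_sample = integer(0),
                              end_sample = integer(0), amplitude = numeric(0),
                              is_first_sip = logical(0), cycle = integer(0),
                              true_volume_ml = numeric(0))
    list(stream = accel_stream(values, fs),
         truth = if (length(truth)) do.call(rbind, truth) else empty_truth,
         refill_samples = refills,
         config = config)
  })
}

#' Label preprocessed episodes against simulator ground truth
#'
#' An episode is labeled a sip iff its source segment overlaps a true sip
#' interval. Used to build training sets from simulated sessions and to
#' score end-to-end detection.
#'
#' @param episodes output of [preprocess_stream()] (carries `start_index`).
#' @param truth the `truth` data.frame from [simulate_session()].
#' @return Integer 0/1 vector, one label per episode.
#' @export
label_episodes <- function(episodes, truth) {
  start_idx <- attr(episodes, "start_index")
  stopifnot(length(start_idx) == length(episodes))
  sips <- truth[truth$kind == "sip", , drop = FALSE]
  vapply(seq_along(episodes), function(i) {
    a <- start_idx[i]
    b <- a + episodes[[i]]$original_len - 1L
    as.integer(any(pmax(a, sips$start_sample) <= pmin(b, sips$end_sample)))
  }, integer(1))
}

#' Simulate a labeled episode dataset
#'
#' Builds a balanced (or user-set) labeled set of classification episodes by
#' generating isolated activity snippets — raised-cosine sips and the
#' peak-producing non-sip kernels (walking, stairs, bag, fidgeting) — and
#' passing each through the real preprocessing path
#' ([preprocess_stream()]). Sub-threshold activities (stationary, car)
#' never produce peaks, hence never reach the classifier, and are excluded.
#'
#' @param n_sips,n_nonsips requested class counts (>= 0).
#' @param config a [sim_config()]; supplies amplitudes, durations, noise
#'   and the seed.
#' @param pipeline a [pipeline_config()] used for preprocessing.
#' @return A list of `episode`s with attribute `labels` (1 = sip).
#' @export
simulate_episode_dataset <- function(n_sips, n_nonsips,
                                     config = sim_config(),
                                     pipeline = pipeline_config()) {
  stopifnot(n_sips >= 0, n_nonsips >= 0)
  fs <- config$sample_rate_hz
  margin <- rep(0, round(2 * fs))
  peaky <- c("walk_flat", "walk_stairs", "bag_walk", "fidget")
  mix <- config$nonsip_mix[peaky]
  if (sum(mix) == 0) mix <- stats::setNames(rep(1, length(peaky)), peaky)

  with_seed(config$seed, {
    gen_one <- function(is_sip) {
      for (attempt in 1:20) {
        v <- if (is_sip) {
          n <- max(3L, round(runif1(config$sip_duration_s) * fs))
          amp <- runif1(c(config$sip_base_amplitude,
                          config$sip_base_amplitude +
                            4 * config$within_cycle_amplitude_increment))
          raised_cosine(n, amp)
        } else {
          nonsip_kernel(sample(peaky, 1, prob = mix / sum(mix)), fs)
        }
        values <- config$baseline + c(margin, v, margin)
        if (config$noise_sd > 0)
          values <- values + stats::rnorm(length(values), 0, config$noise_sd)
        eps <- preprocess_stream(accel_stream(values, fs), pipeline)
        if (length(eps)) {
          pick <- if (is_sip) which.max(vapply(eps, function(e) e$raw_max,
                                               numeric(1)))
                  else sample(length(eps), 1)
          return(eps[[pick]])
        }
      }
      stop("failed to generate a ", if (is_sip) "sip" else "non-sip",
           " episode in 20 attempts; check amplitudes vs threshold")
    }
    episodes <- c(lapply(seq_len(n_sips), function(i) gen_one(TRUE)),
                  lapply(seq_len(n_nonsips), function(i) gen_one(FALSE)))
    attr(episodes, "labels") <- rep(c(1L, 0L), c(n_sips, n_nonsips))
    episodes
  })
}

#' Simulate a sip-height sequence with refill structure
#'
#' Fast path for first-sip detector work: bypasses the signal layer and
#' directly generates the per-sip height sequence p(i) — strictly
#' increasing within each cycle (`base + (rank - 1) * increment`), dropping
#' back to the base at every refill — plus the first-sip labels.
#'
#' @param n_cycles number of drinking cycles (>= 1).
#' @param sips_per_cycle sips per cycle: integer or `c(min, max)` range.
#' @param base height of each cycle's first sip.
#' @param increment within-cycle height increase per sip (>= 0).
#' @param jitter_sd Gaussian height jitter (0 = noise-free sequences).
#' @param seed integer seed.
#' @return A list with `heights` (numeric) and `is_first_sip` (0/1 integer).
#' @examples
#' simulate_sip_height_sequence(2, 3, base = 30, increment = 5, seed = 1)
#' @export
simulate_sip_height_sequence <- function(n_cycles, sips_per_cycle,
                                         base = 30, increment = 5,
                                         jitter_sd = 0, seed = 1L) {
  stopifnot(n_cycles >= 1, all(sips_per_cycle >= 1),
            length(sips_per_cycle) %in% c(1L, 2L), increment >= 0,
            jitter_sd >= 0)
  with_seed(seed, {
    spc <- if (length(sips_per_cycle) == 2L)
      sample(sips_per_cycle[1]:sips_per_cycle[2], n_cycles, replace = TRUE)
    else rep(as.integer(sips_per_cycle), n_cycles)
    heights <- unlist(lapply(spc, function(k) base + (seq_len(k) - 1) * increment))
    labels <- unlist(lapply(spc, function(k) c(1L, rep(0L, k - 1L))))
    if (jitter_sd > 0)
      heights <- heights + stats::rnorm(length(heights), 0, jitter_sd)
    list(heights = heights, is_first_sip = labels)
  })
}
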