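#' Initialize the cumulative volume estimator
#'
#' Sets up the running state of the self-correcting intake estimator:
#' cumulative intake starts at zero and the per-sip volume estimate at
#' `v_bottle / expected_sips_per_bottle` — a cold-start guess that the
#' algorithm re-estimates from data at the end of every completed drinking
#' cycle.
#'
#' @param v_bottle known bottle volume in mL (> 0).
#' @param expected_sips_per_bottle cold-start guess for sips per full bottle
#'   (>= 1).
#' @return An object of class `volume_state` with fields `v_intake`,
#'   `v_sip`, `s_count`, `v_bottle`, `cycle_start_intake` and a `history`
#'   data.frame.
#' @export
init_state <- function(v_bottle, expected_sips_per_bottle = 10L) {
  if (!is.numeric(v_bottle) || v_bottle <= 0) stop("v_bottle must be > 0")
  expected_sips_per_bottle <- as.integer(expected_sips_per_bottle)
  if (is.na(expected_sips_per_bottle) || expected_sips_per_bottle < 1L)
    stop("expected_sips_per_bottle must be >= 1")
  structure(list(
    v_intake = 0,
    v_sip = v_bottle / expected_sips_per_bottle,
    s_count = 0L,
    v_bottle = as.numeric(v_bottle),
    cycle_start_intake = 0,
    history = data.frame(sip_index = integer(0), v_intake = numeric(0),
                         is_first_sip = logical(0), v_sip = numeric(0),
                         height = numeric(0))
  ), class = "volume_state")
}

#' @export
print.volume_state <- function(x, ...) {
  cat(sprintf("<volume_state> intake %.1f mL over %d sip(s); v_sip %.1f mL, bottle %.0f mL\n",
              x$v_intake, nrow(x$history), x$v_sip, x$v_bottle))
  invisible(x)
}

# Integer number of bottles (>= 1) closest to `consumed`; ties break to the
# smaller k.
best_bottle_multiple <- function(consumed, v_bottle) {
  k <- max(1, floor(consumed / v_bottle + 0.5))
  # floor(x + 0.5) rounds half up, i.e. a residual of exactly v_bottle/2
  # would go to the larger k; pull it back to the smaller one.
  if (k > 1 && abs(consumed - (k - 1) * v_bottle) <= abs(consumed - k * v_bottle))
    k <- k - 1
  as.integer(k)
}

#' Advance the volume estimator by one detected sip
#'
#' For a non-first sip, the per-sip estimate is added to the cumulative
#' intake, capped so that the running cycle never exceeds one bottle volume
#' (once a cycle's estimate reaches the full bottle it stays constant until
#' the next first sip). For a first sip, the previous cycle is closed with
#' the self-correction step: the cycle's uncapped consumption estimate
#' (`s_count * v_sip`) is snapped onto the nearest integer multiple
#' `k >= 1` of the bottle volume, the signed correction is applied to the
#' cumulative intake, and the per-sip volume is re-estimated as
#' `k * v_bottle / s_count`. A first sip arriving with no sips in the
#' current cycle (`s_count == 0`) starts the cycle without a correction —
#' this covers both the session's first sip and duplicate first-sip
#' detections.
#'
#' With `literal_order = TRUE` the first-sip update instead adds the sip
#' volume before computing the correction, reproducing the unguarded
#' textbook line order; the default closes the cycle first, so the snap
#' covers exactly the sips that emptied the bottle.
#'
#' @param state a `volume_state`.
#' @param is_first_sip logical: did the first-sip detector fire?
#' @param height optional sip height, stored in the history.
#' @param literal_order use the add-then-correct line order.
#' @return The updated `volume_state`.
#' @export
update_volume <- function(state, is_first_sip, height = NA_real_,
                          literal_order = FALSE) {
  stopifnot(inherits(state, "volume_state"))
  is_first_sip <- isTRUE(is_first_sip)

  add_capped_sip <- function(st) {
    room <- st$v_bottle - (st$v_intake - st$cycle_start_intake)
    st$v_intake <- st$v_intake + min(st$v_sip, max(room, 0))
    st
  }

  if (!is_first_sip || state$s_count == 0L) {
    # regular sip, or a first sip opening a fresh cycle (session start /
    # duplicate detection): no correction possible yet
    if (is_first_sip) state$cycle_start_intake <- state$v_intake
    state$s_count <- state$s_count + 1L
    state <- add_capped_sip(state)
  } else {
    if (literal_order) {
      state$s_count <- state$s_count + 1L
      state <- add_capped_sip(state)
    }
    # close the previous cycle: snap onto k full bottles
    uncapped <- state$s_count * state$v_sip
    k <- best_bottle_multiple(uncapped, state$v_bottle)
    state$v_intake <- state$cycle_start_intake + k * state$v_bottle
    state$v_sip <- (k * state$v_bottle) / state$s_count
    # open the new cycle with this first sip
    state$cycle_start_intake <- state$v_intake
    if (literal_order) {
      state$s_count <- 0L
    } else {
      state$s_count <- 1L
      state <- add_capped_sip(state)
    }
  }

  state$history <- rbind(state$history,
                         data.frame(sip_index = nrow(state$history) + 1L,
                                    v_intake = state$v_intake,
                                    is_first_sip = is_first_sip,
                                    v_sip = state$v_sip,
                                    height = as.numeric(height)))
  state
}

#' Run the volume estimator over a detected sip sequence
#'
#' Feeds a sequence of detected sips (heights plus first-sip flags) through
#' [update_volume()] and returns the stepped intake trajectory. When the
#' true cumulative intake at each detected sip is supplied, a per-step
#' percentage error column is added.
#'
#' @param heights numeric vector of detected sip heights (may be `NA`).
#' @param is_first_sip logical vector, one flag per detected sip.
#' @param v_bottle known bottle volume (mL).
#' @param expected_sips_per_bottle cold-start sips-per-bottle guess.
#' @param true_intake optional numeric vector of true cumulative intake
#'   (mL) after each detected sip.
#' @param literal_order see [update_volume()].
#' @return A list with `state` (final `volume_state`) and `trajectory`
#'   (data.frame: `sip_index`, `v_intake`, `is_first_sip`, `v_sip`, plus
#'   `true_v_ml` and `pct_error` when truth is given).
#' @export
run_volume_estimator <- function(heights, is_first_sip, v_bottle,
                                 expected_sips_per_bottle = 10L,
                                 true_intake = NULL,
                                 literal_order = FALSE) {
  n <- length(is_first_sip)
  if (length(heights) == 0L) heights <- rep(NA_real_, n)
  stopifnot(length(heights) == n)
  state <- init_state(v_bottle, expected_sips_per_bottle)
  for (i in seq_len(n))
    state <- update_volume(state, is_first_sip[i], height = heights[i],
                           literal_order = literal_order)
  traj <- state$history
  if (!is.null(true_intake)) {
    stopifnot(length(true_intake) == n)
    traj$true_v_ml <- true_intake
    traj$pct_error <- ifelse(true_intake > 0,
                             100 * (traj$v_intake - true_intake) / true_intake,
                             NA_real_)
  }
  list(state = state, trajectory = traj)
}

#' End-to-end intake estimation on a raw accelerometer session
#'
#' Chains the whole pipeline: preprocessing into episodes, sip
#' classification, sequential first-sip detection on the detected sip
#' heights, and the self-correcting volume estimator. First-sip features
#' are computed online: each detected sip extends the height sequence
#' before its gradient features are evaluated.
#'
#' @param stream raw `accel_stream` for one session.
#' @param sip_model trained sip classifier (5 features).
#' @param firstsip_model trained first-sip detector (3 features).
#' @param config a [pipeline_config()]; supplies `bottle_volume_ml`.
#' @param expected_sips_per_bottle cold-start sips-per-bottle guess.
#' @param verbose log per-stage counts.
#' @return A list: `trajectory` (stepped intake estimate with a `time_s`
#'   column), `detections` (per-episode classifier output), `episodes`, and
#'   the final `state`.
#' @export
estimate_session <- function(stream, sip_model, firstsip_model,
                             config = pipeline_config(),
                             expected_sips_per_bottle = 10L,
                             verbose = FALSE) {
  episodes <- preprocess_stream(stream, config, verbose = verbose)
  detections <- classify_episodes(sip_model, episodes, config, verbose = verbose)
  start_idx <- attr(episodes, "start_index")
  detections$time_s <- if (length(start_idx)) (start_idx - 1) / stream$sample_rate_hz
                       else numeric(0)

  sip_rows <- which(detections$label == 1L)
  heights <- numeric(0)
  first_flags <- logical(0)
  for (r in sip_rows) {
    heights <- c(heights, detections$raw_max[r])
    i <- length(heights)
    flag <- if (i == 1L) TRUE   # session's first detected sip opens a cycle
            else detect_first_sip(firstsip_model, compute_gradient_features(heights, i))
    first_flags <- c(first_flags, flag)
  }
  res <- run_volume_estimator(heights, first_flags,
                              v_bottle = config$bottle_volume_ml,
                              expected_sips_per_bottle = expected_sips_per_bottle)
  traj <- res$trajectory
  traj$time_s <- detections$time_s[sip_rows]
  if (verbose)
    message(sprintf("estimate: %d sips detected, %d first sips, intake %.1f mL",
                    length(sip_rows), sum(first_flags), res$state$v_intake))
  list(trajectory = traj, detections = detections, episodes = episodes,
       state = res$state)
}

#' Write an intake trajectory to CSV
#' @param trajectory data.frame from [run_volume_estimator()] or
#'   [estimate_session()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}
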