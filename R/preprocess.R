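#' Moving-average filter
#'
#' Smooths a stream with a centered sliding mean of `window` samples. Near
#' the edges the window shrinks symmetrically (half-width
#' `min(floor(window/2), distance to nearest edge)`), so output length
#' equals input length and a constant stream passes through unchanged. An
#' even `window` behaves as the next odd size, since a centered window needs
#' an odd support.
#'
#' @param stream an [accel_stream()].
#' @param window window length in samples (>= 1).
#' @return A filtered `accel_stream` of the same length and rate.
#' @export
moving_average <- function(stream, window = 5L) {
  stopifnot(inherits(stream, "accel_stream"))
  window <- as.integer(window)
  if (window < 1L) stop("moving-average window must be >= 1")
  x <- stream$values
  n <- length(x)
  if (n == 0L) stop("cannot filter an empty stream")
  h <- window %/% 2L
  if (h == 0L) return(stream)
  # Each interior output is summed independently (stats::filter), not via
  # prefix-sum differences: runs of equal inputs then stay exactly equal,
  # which the plateau-based peak segmentation relies on.
  out <- if (n > 2L * h) {
    as.numeric(stats::filter(x, rep(1, 2L * h + 1L), sides = 2)) / (2L * h + 1L)
  } else rep(NA_real_, n)
  edge <- which(is.na(out))
  for (i in edge) {
    k <- min(h, i - 1L, n - i)
    out[i] <- mean(x[(i - k):(i + k)])
  }
  accel_stream(out, stream$sample_rate_hz)
}

# Strict local extrema with plateaus collapsed to their first sample.
# Returns indices into `x`; endpoints are never extrema.
local_extrema <- function(x, kind = c("min", "max")) {
  kind <- match.arg(kind)
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  m <- length(r$values)
  if (m < 3L) return(integer(0))
  run_start <- cumsum(c(1L, r$lengths[-m]))
  j <- 2:(m - 1)
  hit <- if (kind == "min") {
    r$values[j] < r$values[j - 1] & r$values[j] < r$values[j + 1]
  } else {
    r$values[j] > r$values[j - 1] & r$values[j] > r$values[j + 1]
  }
  run_start[j][hit]
}

# Default raw-domain segmentation threshold: baseline (median) plus a
# quarter of the span up to the stream maximum. A stream whose whole span
# stays under `min_prominence` (raw units; gravity is ~1, and any drinking
# tilt moves the vertical-axis projection far more than 0.1) contains no
# candidate gestures: the threshold is +Inf and nothing is emitted.
auto_segmentation_threshold <- function(values, min_prominence = 0.1) {
  base <- stats::median(values)
  span <- max(values) - base
  if (span < min_prominence) return(Inf)
  base + 0.25 * span
}

#' Detect peak segments in a filtered stream
#'
#' Scans for pairs of consecutive local minima that both lie below the
#' segmentation threshold. If at least one local maximum lying strictly
#' above both delimiting minima and above the threshold sits between them,
#' everything between the two minima (inclusive) becomes a `peak_segment`:
#' the raw material for one candidate drinking episode. Requiring the
#' maximum to clear the threshold keeps sub-threshold sensor noise (a
#' stationary bottle, a moving car) from emitting spurious segments.
#' Consecutive segments share at most their boundary minimum. A gesture
#' that never returns below the threshold before the stream ends is not
#' emitted.
#'
#' A sample is a local minimum (maximum) iff it is strictly below (above)
#' both neighbours; plateaus collapse to their first sample.
#'
#' @param stream a filtered `accel_stream`.
#' @param segmentation_threshold raw-domain threshold below which delimiting
#'   minima must lie; `NULL` estimates `median + 0.25 * (max - median)`.
#' @return A list of `peak_segment` objects, each with `raw_values`,
#'   `start_index` (into the stream) and `raw_max`.
#' @export
detect_peak_segments <- function(stream, segmentation_threshold = NULL) {
  stopifnot(inherits(stream, "accel_stream"))
  x <- stream$values
  if (length(x) < 3L) return(list())
  if (is.null(segmentation_threshold))
    segmentation_threshold <- auto_segmentation_threshold(x)

  r <- rle(x)
  m <- length(r$values)
  if (m < 2L) return(list())
  run_start <- cumsum(c(1L, r$lengths[-m]))
  run_end <- run_start + r$lengths - 1L

  is_min <- logical(m)
  is_max <- logical(m)
  if (m >= 3L) {
    j <- 2:(m - 1)
    is_min[j] <- r$values[j] < r$values[j - 1] & r$values[j] < r$values[j + 1]
    is_max[j] <- r$values[j] > r$values[j - 1] & r$values[j] > r$values[j + 1]
  }
  # terminal runs delimit too: a stream that settles back to (or starts at)
  # a sub-threshold level closes/opens a peak at its edge
  is_min[1] <- r$values[1] < r$values[2]
  is_min[m] <- r$values[m] < r$values[m - 1]

  min_runs <- which(is_min & r$values < segmentation_threshold)
  if (length(min_runs) < 2L) return(list())
  max_runs <- which(is_max)

  segments <- list()
  for (i in seq_len(length(min_runs) - 1L)) {
    a <- min_runs[i]; b <- min_runs[i + 1L]
    inner <- max_runs[max_runs > a & max_runs < b]
    if (length(inner) &&
        any(r$values[inner] > r$values[a] & r$values[inner] > r$values[b] &
              r$values[inner] > segmentation_threshold)) {
      # tight bounds: step over a delimiting plateau to its inner edge
      from <- run_end[a]; to <- run_start[b]
      seg_vals <- x[from:to]
      segments[[length(segments) + 1L]] <- structure(
        list(raw_values = seg_vals, start_index = from, raw_max = max(seg_vals)),
        class = "peak_segment")
    }
  }
  segments
}

#' Normalize an extracted peak into the episode value range
#'
#' Affine min-max rescaling of the raw segment `x` into
#' `[norm_low, norm_high]` (defaults `[10, 20]`):
#' `norm = ((x - min(x)) / (max(x) - min(x)) + 1) * 10`.
#' The output of any non-constant segment therefore attains exactly 10 at
#' its minimum and 20 at its maximum, and is invariant under positive affine
#' transforms of the raw values. A degenerate constant segment maps to all
#' `norm_low`.
#'
#' @param segment a `peak_segment`, or a bare numeric vector.
#' @param config a [pipeline_config()].
#' @return Numeric vector of normalized values.
#' @export
normalize_peak <- function(segment, config = pipeline_config()) {
  x <- if (inherits(segment, "peak_segment")) segment$raw_values else as.numeric(segment)
  if (!length(x)) stop("cannot normalize an empty segment")
  span <- max(x) - min(x)
  lo <- config$norm_low
  hi <- config$norm_high
  if (span == 0) return(rep(lo, length(x)))
  lo + (x - min(x)) / span * (hi - lo)
}

new_episode <- function(norm_values, raw_max, original_len) {
  structure(list(norm_values = as.numeric(norm_values),
                 raw_max = as.numeric(raw_max),
                 original_len = as.integer(original_len)),
            class = "episode")
}

#' @export
print.episode <- function(x, ...) {
  cat(sprintf("<episode> %d samples (original %d), raw_max %.4g\n",
              length(x$norm_values), x$original_len, x$raw_max))
  invisible(x)
}

#' Fit normalized values into a fixed-length episode window
#'
#' Episodes have a constant length of `episode_len` samples (default 120,
#' i.e. 6 s at 20 Hz, the maximum duration of a normalized sip). Shorter
#' inputs are right-padded with `pad_value` (default 10, the minimum
#' normalized value); longer inputs are truncated to the first
#' `episode_len` samples.
#'
#' @param norm_values numeric vector of normalized values.
#' @param config a [pipeline_config()].
#' @param raw_max raw-domain maximum carried alongside the window.
#' @return An `episode` with fields `norm_values` (length `episode_len`),
#'   `raw_max` and `original_len` (pre-padding length, capped at
#'   `episode_len`).
#' @export
fit_window <- function(norm_values, config = pipeline_config(), raw_max = NA_real_) {
  if (!length(norm_values)) stop("cannot window an empty episode")
  len <- config$episode_len
  n <- length(norm_values)
  out <- if (n >= len) norm_values[seq_len(len)]
         else c(norm_values, rep(config$pad_value, len - n))
  new_episode(out, raw_max = raw_max, original_len = min(n, len))
}

#' Preprocess a raw stream into classification episodes
#'
#' The full front end: moving-average filter, peak segmentation,
#' normalization into `[norm_low, norm_high]`, and fixed-length windowing.
#' Each episode keeps the raw-domain maximum of its source segment
#' (`raw_max`), which downstream serves as the sip height p(i).
#'
#' @param stream an `accel_stream` of raw values.
#' @param config a [pipeline_config()].
#' @param verbose log per-stage counts with [message()].
#' @return A list of `episode` objects in temporal order, with attribute
#'   `start_index` giving each source segment's position in the stream.
#' @export
preprocess_stream <- function(stream, config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(stream, "accel_stream"))
  if (!length(stream$values)) stop("cannot preprocess an empty stream")
  filtered <- moving_average(stream, config$ma_window)
  segments <- detect_peak_segments(filtered, config$segmentation_threshold)
  episodes <- lapply(segments, function(seg) {
    fit_window(normalize_peak(seg, config), config, raw_max = seg$raw_max)
  })
  attr(episodes, "start_index") <- vapply(segments, function(s) s$start_index,
                                          integer(1))
  if (verbose)
    message(sprintf("preprocess: %d samples in, %d peak segments, %d episodes",
                    length(stream$values), length(segments), length(episodes)))
  episodes
}
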