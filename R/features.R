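SIP_FEATURE_NAMES <- c("n_peaks", "max_peak_height", "peak_duration",
                       "n_stable", "last_height")

#' Extract the five sip-classification features from an episode
#'
#' The feature vector that feeds the sip/non-sip classifier:
#' \describe{
#'   \item{`n_peaks`}{number of strict local maxima of the normalized episode
#'     with value above `th_norm` — how many times the bottle was tilted.}
#'   \item{`max_peak_height`}{the raw-domain maximum of the source segment
#'     (`episode$raw_max`), the maximum tilt the bottle experienced. Taken
#'     pre-normalization because every normalized episode maxes out at the
#'     top of the range by construction.}
#'   \item{`peak_duration`}{number of samples with normalized value above
#'     `th_norm`; sips hold the tilt longer than most other gestures.}
#'   \item{`n_stable`}{number of samples within `stable_fraction` (default
#'     20\%) of the episode maximum, i.e. `>= (1 - stable_fraction) * max`;
#'     counts the dwell at the top of the tilt.}
#'   \item{`last_height`}{normalized value of the final sample; above the
#'     floor only when a gesture ran past the end of the window.}
#' }
#'
#' @param episode an `episode` (see [fit_window()]).
#' @param config a [pipeline_config()].
#' @return A one-row data.frame with the five named feature columns.
#' @export
extract_sip_features <- function(episode, config = pipeline_config()) {
  stopifnot(inherits(episode, "episode"))
  v <- episode$norm_values
  maxima <- local_extrema(v, "max")
  peak_max <- max(v)
  data.frame(
    n_peaks = length(maxima[v[maxima] > config$th_norm]),
    max_peak_height = episode$raw_max,
    peak_duration = sum(v > config$th_norm),
    n_stable = sum(v >= (1 - config$stable_fraction) * peak_max),
    last_height = v[length(v)]
  )
}

#' Feature matrix for a list of episodes
#'
#' @param episodes list of `episode` objects.
#' @param config a [pipeline_config()].
#' @param labels optional 0/1 labels appended as a `label` column.
#' @return A data.frame with one row per episode.
#' @export
extract_sip_feature_table <- function(episodes, config = pipeline_config(),
                                      labels = NULL) {
  if (!length(episodes)) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), 5), SIP_FEATURE_NAMES))
    if (!is.null(labels)) out$label <- integer(0)
    return(out)
  }
  out <- do.call(rbind, lapply(episodes, extract_sip_features, config = config))
  rownames(out) <- NULL
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(episodes))
    out$label <- as.integer(labels)
  }
  out
}
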