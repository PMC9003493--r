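FIRSTSIP_FEATURE_NAMES <- c("f1", "f2", "f3")

#' Sip-height gradient features for first-sip detection
#'
#' While a bottle empties, the tilt needed for each successive sip grows, so
#' sip heights rise within a drinking cycle and drop sharply at a refill.
#' The detector therefore looks at backward differences of the sip-height
#' sequence `p` at lags 1-3:
#' `f_j(i) = p(i) - p(i - j)`, `j = 1, 2, 3`.
#' For the first sips of a session (`i <= 3`) the missing lag references
#' clamp to `p(1)`, giving near-zero, neutral features instead of an error.
#' All three features are strongly negative right after a refill.
#'
#' @param heights numeric vector of sip heights `p(1..i..)` (raw-domain
#'   episode maxima from the sip classifier).
#' @param i 1-based sip index at which to evaluate (defaults to the last).
#' @return A one-row data.frame with columns `f1`, `f2`, `f3`.
#' @examples
#' compute_gradient_features(c(30, 32, 35, 40), 4)  # 5, 8, 10
#' @export
compute_gradient_features <- function(heights, i = length(heights)) {
  heights <- as.numeric(heights)
  if (!length(heights)) stop("empty sip-height sequence")
  i <- as.integer(i)
  stopifnot(i >= 1L, i <= length(heights))
  lagged <- function(j) heights[max(1L, i - j)]
  data.frame(f1 = heights[i] - lagged(1L),
             f2 = heights[i] - lagged(2L),
             f3 = heights[i] - lagged(3L))
}

#' Gradient-feature table for a whole sip-height sequence
#'
#' @param heights numeric vector of sip heights.
#' @param labels optional 0/1 first-sip labels appended as `label`.
#' @return A data.frame with one row per sip: `f1`, `f2`, `f3` (and `label`).
#' @export
firstsip_feature_table <- function(heights, labels = NULL) {
  heights <- as.numeric(heights)
  out <- do.call(rbind, lapply(seq_along(heights), function(i)
    compute_gradient_features(heights, i)))
  rownames(out) <- NULL
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(heights))
    out$label <- as.integer(labels)
  }
  out
}

#' Detect a first sip from its gradient features
#'
#' @param model a trained `dense_net_model` over `(f1, f2, f3)`.
#' @param features a one-row data.frame or length-3 numeric vector.
#' @return `TRUE` iff the predicted probability reaches the model's decision
#'   threshold.
#' @export
detect_first_sip <- function(model, features) {
  stopifnot(inherits(model, "dense_net_model"))
  predict_proba(model, features) >= model$decision_threshold
}

#' Train the first-sip detector
#'
#' Convenience wrapper around [train_dense_net()] for the 3-input gradient
#' features. First sips are rare (one per drinking cycle), so rows are
#' weighted by inverse class frequency by default.
#'
#' @param features data.frame with columns `f1`, `f2`, `f3` (a `label`
#'   column is ignored as a predictor).
#' @param labels 0/1 first-sip labels.
#' @param hidden_sizes hidden-layer widths; default a single hidden layer of
#'   3 neurons, the smallest width that reaches perfect recovery on clean
#'   height sequences.
#' @param config a [train_config()]; default [firstsip_train_config()]
#'   (Adam, 150 epochs, batch 10).
#' @param balance_classes weight rows by inverse class frequency.
#' @return A trained `dense_net_model`.
#' @export
train_firstsip_detector <- function(features, labels, hidden_sizes = 3L,
                                    config = firstsip_train_config(),
                                    balance_classes = TRUE) {
  labels <- as.integer(labels)
  w <- NULL
  if (balance_classes) {
    freq <- table(factor(labels, levels = c(0L, 1L)))
    if (all(freq > 0)) w <- as.numeric(length(labels) / (2 * freq[as.character(labels)]))
  }
  train_dense_net(features[, FIRSTSIP_FEATURE_NAMES, drop = FALSE], labels,
                  net_architecture(3L, hidden_sizes, 1L),
                  config = config, sample_weights = w)
}

#' Train the sip classifier
#'
#' Convenience wrapper around [train_dense_net()] for the five episode
#' features, with the sip-classifier regime (SGD, 300 epochs, batch 100).
#'
#' @param features data.frame with the five sip feature columns (a `label`
#'   column is ignored as a predictor).
#' @param labels 0/1 sip labels.
#' @param hidden_sizes hidden-layer widths; default one hidden layer of 3
#'   neurons, the best accuracy-per-energy compromise among the candidate
#'   on-device architectures.
#' @param config a [train_config()]; default [sip_train_config()].
#' @return A trained `dense_net_model`.
#' @export
train_sip_classifier <- function(features, labels, hidden_sizes = 3L,
                                 config = sip_train_config()) {
  train_dense_net(features[, SIP_FEATURE_NAMES, drop = FALSE],
                  as.integer(labels),
                  net_architecture(5L, hidden_sizes, 1L),
                  config = config)
}
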