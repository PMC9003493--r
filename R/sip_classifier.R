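#' Classify a list of episodes as sip / non-sip
#'
#' Extracts the five episode features and runs the trained sip classifier.
#' Order is preserved: one prediction per episode.
#'
#' @param model a trained `dense_net_model` over the five sip features.
#' @param episodes list of `episode` objects.
#' @param config a [pipeline_config()].
#' @param verbose log the detected-sip count.
#' @return A data.frame with columns `label` (0/1), `proba` and `raw_max`
#'   (the sip height carried from preprocessing).
#' @export
classify_episodes <- function(model, episodes, config = pipeline_config(),
                              verbose = FALSE) {
  stopifnot(inherits(model, "dense_net_model"))
  if (!length(episodes))
    return(data.frame(label = integer(0), proba = numeric(0),
                      raw_max = numeric(0)))
  feats <- extract_sip_feature_table(episodes, config)
  proba <- predict_proba(model, feats)
  out <- data.frame(label = as.integer(proba >= model$decision_threshold),
                    proba = proba,
                    raw_max = vapply(episodes, function(e) e$raw_max, numeric(1)))
  if (verbose)
    message(sprintf("classify: %d episodes in, %d sips detected",
                    length(episodes), sum(out$label)))
  out
}

#' Sip-detection performance metrics
#'
#' Confusion-table rates in the convention used for on-device sip
#' detection, with sip = positive class:
#' * `tp = Nsd / Ns` — fraction of true sips detected;
#' * `fp = (Nns - Nnsd) / Nns` — fraction of non-sips misclassified as sips;
#' * `accuracy = (Nsd + Nnsd) / (Ns + Nns)` — overall fraction correct.
#'
#' Integer-percent fields (`tp_pct` etc.) use floor, so e.g. an overall
#' accuracy of 26.82\% reports as 26\%. A class absent from `truth` leaves
#' its rate `NA`.
#'
#' @param predictions 0/1 predicted labels.
#' @param truth 0/1 true labels, same length.
#' @return An object of class `classification_metrics`: counts `Ns`, `Nns`,
#'   `Nsd`, `Nnsd`, fractional rates `tp`, `fp`, `accuracy`, and their
#'   floored percent versions.
#' @examples
#' # a degenerate model that calls everything a sip
#' truth <- rep(c(1, 0), c(424, 1157))
#' evaluate_detection(rep(1, length(truth)), truth)
#' @export
evaluate_detection <- function(predictions, truth) {
  predictions <- as.integer(predictions)
  truth <- as.integer(truth)
  if (length(predictions) != length(truth))
    stop("predictions and truth differ in length")
  stopifnot(all(predictions %in% c(0L, 1L)), all(truth %in% c(0L, 1L)))

  Ns <- sum(truth == 1L)
  Nns <- sum(truth == 0L)
  Nsd <- sum(predictions == 1L & truth == 1L)
  Nnsd <- sum(predictions == 0L & truth == 0L)
  tp <- if (Ns > 0) Nsd / Ns else NA_real_
  fp <- if (Nns > 0) (Nns - Nnsd) / Nns else NA_real_
  accuracy <- if (Ns + Nns > 0) (Nsd + Nnsd) / (Ns + Nns) else NA_real_

  pct <- function(x) if (is.na(x)) NA_integer_ else as.integer(floor(100 * x))
  structure(list(Ns = Ns, Nns = Nns, Nsd = Nsd, Nnsd = Nnsd,
                 tp = tp, fp = fp, accuracy = accuracy,
                 tp_pct = pct(tp), fp_pct = pct(fp),
                 accuracy_pct = pct(accuracy)),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat("<classification_metrics>\n")
  cat(sprintf("  sips     : %d true, %d detected (tp %s%%)\n",
              x$Ns, x$Nsd, format(x$tp_pct)))
  cat(sprintf("  non-sips : %d true, %d correct (fp %s%%)\n",
              x$Nns, x$Nnsd, format(x$fp_pct)))
  cat(sprintf("  accuracy : %s%% (%.4f)\n", format(x$accuracy_pct), x$accuracy))
  invisible(x)
}

#' Write detection metrics to JSON
#' @param metrics a `classification_metrics`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  stopifnot(inherits(metrics, "classification_metrics"))
  jsonlite::write_json(
    list(Ns = metrics$Ns, Nns = metrics$Nns, Nsd = metrics$Nsd,
         Nnsd = metrics$Nnsd, tp_pct = metrics$tp_pct, fp_pct = metrics$fp_pct,
         accuracy_pct = metrics$accuracy_pct),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Accuracy-per-energy ratio for ranking architectures
#'
#' Divides detection accuracy (as a percentage) by the measured
#' per-classification energy in millijoules. Energy figures come from
#' external hardware measurements — they are user-supplied inputs here.
#'
#' @param accuracy detection accuracy as a fraction in `[0, 1]`.
#' @param energy_mj measured energy per classification, mJ (> 0).
#' @return The ratio in \%/mJ.
#' @examples
#' accuracy_per_energy(0.94, 10)  # 9.4 %/mJ
#' @export
accuracy_per_energy <- function(accuracy, energy_mj) {
  stopifnot(accuracy >= 0, accuracy <= 1)
  if (any(energy_mj <= 0)) stop("energy must be positive")
  100 * accuracy / energy_mj
}
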