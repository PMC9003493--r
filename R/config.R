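#' Pipeline configuration
#'
#' Bundles every tunable constant of the sip-detection pipeline. Defaults
#' reproduce the canonical on-device setup: a 20 Hz single-axis (bottle
#' vertical) accelerometer stream, a 5-sample moving-average filter,
#' 120-sample episodes (6 s at 20 Hz), and peak normalization into
#' \[10, 20\] with pad value 10.
#'
#' Two distinct thresholds share the name "Th" in the field's usage and are
#' deliberately split here:
#' \describe{
#'   \item{`segmentation_threshold`}{raw-signal units; local minima below it
#'     delimit candidate peaks. `NULL` (default) means estimate per stream as
#'     `median + 0.25 * (max - median)`.}
#'   \item{`th_norm`}{normalized-domain threshold (default 10) used by the
#'     episode features (peak counting, peak duration).}
#' }
#'
#' @param sample_rate_hz sampling rate in Hz. Default 20.
#' @param ma_window moving-average window length in samples. Default 5.
#' @param episode_len episode window length in samples. Default 120.
#' @param pad_value padding value for short episodes. Default 10.
#' @param norm_low,norm_high target range of peak normalization. Defaults 10, 20.
#' @param th_norm normalized-domain feature threshold. Default 10.
#' @param segmentation_threshold raw-domain peak segmentation threshold, or
#'   `NULL` to estimate it from each stream.
#' @param stable_fraction fraction defining the "stable portion" of a peak:
#'   samples within `stable_fraction` of the episode maximum
#'   (multiplicatively, i.e. `>= (1 - stable_fraction) * max`). Default 0.20.
#' @param decision_threshold probability cutoff for both classifiers. Default 0.5.
#' @param bottle_volume_ml known bottle volume in mL. Default 500.
#' @param rng_seed integer seed used by operations with randomness. Default 1.
#'
#' @return An object of class `pipeline_config` (a validated list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$episode_len
#' @export
pipeline_config <- function(sample_rate_hz = 20,
                            ma_window = 5L,
                            episode_len = 120L,
                            pad_value = 10,
                            norm_low = 10,
                            norm_high = 20,
                            th_norm = 10,
                            segmentation_threshold = NULL,
                            stable_fraction = 0.20,
                            decision_threshold = 0.5,
                            bottle_volume_ml = 500,
                            rng_seed = 1L) {
  cfg <- list(
    sample_rate_hz = as.numeric(sample_rate_hz),
    ma_window = as.integer(ma_window),
    episode_len = as.integer(episode_len),
    pad_value = as.numeric(pad_value),
    norm_low = as.numeric(norm_low),
    norm_high = as.numeric(norm_high),
    th_norm = as.numeric(th_norm),
    segmentation_threshold = if (is.null(segmentation_threshold)) NULL
                             else as.numeric(segmentation_threshold),
    stable_fraction = as.numeric(stable_fraction),
    decision_threshold = as.numeric(decision_threshold),
    bottle_volume_ml = as.numeric(bottle_volume_ml),
    rng_seed = as.integer(rng_seed)
  )
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  stopifnot(
    cfg$sample_rate_hz > 0,
    cfg$ma_window >= 1L,
    cfg$episode_len >= 1L,
    cfg$norm_low < cfg$norm_high,
    cfg$stable_fraction > 0, cfg$stable_fraction < 1,
    cfg$decision_threshold > 0, cfg$decision_threshold < 1,
    cfg$bottle_volume_ml > 0
  )
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  sample rate      : %g Hz\n", x$sample_rate_hz))
  cat(sprintf("  filter window    : %d samples\n", x$ma_window))
  cat(sprintf("  episode length   : %d samples (%.1f s)\n",
              x$episode_len, x$episode_len / x$sample_rate_hz))
  cat(sprintf("  norm range       : [%g, %g], pad %g\n",
              x$norm_low, x$norm_high, x$pad_value))
  cat(sprintf("  th_norm          : %g\n", x$th_norm))
  cat(sprintf("  segmentation thr : %s\n",
              if (is.null(x$segmentation_threshold)) "auto (median + 0.25 * span)"
              else format(x$segmentation_threshold)))
  cat(sprintf("  bottle volume    : %g mL\n", x$bottle_volume_ml))
  invisible(x)
}

#' Read or write a pipeline configuration file
#'
#' Configurations are stored as flat JSON or YAML (chosen by file
#' extension: `.yaml`/`.yml` vs anything else). Unknown keys are rejected so
#' typos fail loudly.
#'
#' @param path file path.
#' @param config a `pipeline_config`.
#' @return `read_config` returns a `pipeline_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::yaml.load_file(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to write YAML configs")
    writeLines(yaml::as.yaml(vals), path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
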