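#' Construct an accelerometer stream
#'
#' An `accel_stream` holds uniformly sampled single-axis accelerometer
#' values (the axis aligned with the bottle vertical) plus the sampling
#' rate. Timestamps are implicit: sample `i` sits at `(i - 1) / sample_rate_hz`
#' seconds.
#'
#' @param values numeric vector of raw accelerometer readings.
#' @param sample_rate_hz sampling rate in Hz.
#' @return An object of class `accel_stream`.
#' @export
accel_stream <- function(values, sample_rate_hz = 20) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("accelerometer values contain NA")
  stopifnot(sample_rate_hz > 0)
  structure(list(values = values, sample_rate_hz = as.numeric(sample_rate_hz)),
            class = "accel_stream")
}

#' @export
print.accel_stream <- function(x, ...) {
  cat(sprintf("<accel_stream> %d samples @ %g Hz (%.1f s)\n",
              length(x$values), x$sample_rate_hz,
              length(x$values) / x$sample_rate_hz))
  invisible(x)
}

#' @export
length.accel_stream <- function(x) length(x$values)

#' Times (seconds) of each sample in a stream
#' @param stream an `accel_stream`.
#' @return numeric vector of timestamps starting at 0.
#' @export
stream_times <- function(stream) {
  stopifnot(inherits(stream, "accel_stream"))
  (seq_along(stream$values) - 1) / stream$sample_rate_hz
}

#' Read an accelerometer stream from CSV
#'
#' Accepts headerless numeric CSV with either one column (value) or two
#' columns (time, value). Only the value column feeds the pipeline: the
#' processing chain is sample-indexed and `sample_rate_hz` alone converts to
#' seconds, so file timestamps are validated as numeric but otherwise
#' ignored. A header line is tolerated and skipped if its fields are
#' non-numeric.
#'
#' @param path CSV file path.
#' @param config a [pipeline_config()]; supplies `sample_rate_hz`.
#' @return An `accel_stream`.
#' @export
read_accel_csv <- function(path, config = pipeline_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty accelerometer CSV: ", path)

  parse_row <- function(line) suppressWarnings(as.numeric(strsplit(line, ",")[[1]]))
  first <- parse_row(lines[1])
  header_skipped <- FALSE
  if (anyNA(first)) {           # tolerate a single header row
    lines <- lines[-1]
    header_skipped <- TRUE
    if (!length(lines)) stop("empty accelerometer CSV (header only): ", path)
  }

  rows <- lapply(lines, parse_row)
  ncols <- lengths(rows)
  if (any(ncols < 1 | ncols > 2))
    stop("row ", which(ncols < 1 | ncols > 2)[1] + header_skipped,
         ": expected 1 (value) or 2 (time,value) columns")
  bad <- which(vapply(rows, anyNA, logical(1)))
  if (length(bad))
    stop("row ", bad[1] + header_skipped, ": non-numeric value in '",
         lines[bad[1]], "'")
  if (length(unique(ncols)) != 1)
    stop("inconsistent column count across rows")

  values <- vapply(rows, function(r) r[length(r)], numeric(1))
  accel_stream(values, config$sample_rate_hz)
}

#' Write an accelerometer stream to CSV
#'
#' Writes two headerless columns: time (s) and value. [read_accel_csv()] of
#' the result reproduces the values to stored precision.
#'
#' @param stream an `accel_stream`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(stream, path) {
  stopifnot(inherits(stream, "accel_stream"))
  df <- data.frame(time = stream_times(stream), value = stream$values)
  utils::write.table(df, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write episodes to CSV / read them back
#'
#' One row per episode: `episode_len` normalized-value columns
#' (`v1..v<episode_len>`), then `raw_max`, `original_len` and, when known,
#' `label` (1 = sip).
#'
#' @param episodes list of `episode` objects (see [preprocess_stream()]).
#' @param path CSV path.
#' @param labels optional integer vector of 0/1 labels.
#' @return `write_episode_csv` returns `path` invisibly;
#'   `read_episode_csv` a list of episodes with a `labels` attribute when the
#'   file carries labels.
#' @export
write_episode_csv <- function(episodes, path, labels = NULL) {
  stopifnot(is.list(episodes))
  if (!length(episodes)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  mat <- t(vapply(episodes, function(e) e$norm_values,
                  numeric(length(episodes[[1]]$norm_values))))
  df <- as.data.frame(mat)
  names(df) <- paste0("v", seq_len(ncol(mat)))
  df$raw_max <- vapply(episodes, function(e) e$raw_max, numeric(1))
  df$original_len <- vapply(episodes, function(e) e$original_len, numeric(1))
  start_idx <- attr(episodes, "start_index")
  df$start_index <- if (is.null(start_idx)) NA_integer_ else start_idx
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(episodes))
    df$label <- as.integer(labels)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_episode_csv
#' @export
read_episode_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  info <- file.info(path)
  if (info$size == 0) return(list())
  df <- utils::read.csv(path)
  vcols <- grep("^v[0-9]+$", names(df))
  eps <- lapply(seq_len(nrow(df)), function(i) {
    new_episode(as.numeric(df[i, vcols]),
                raw_max = df$raw_max[i],
                original_len = as.integer(df$original_len[i]))
  })
  if ("start_index" %in% names(df) && !anyNA(df$start_index))
    attr(eps, "start_index") <- as.integer(df$start_index)
  if ("label" %in% names(df)) attr(eps, "labels") <- as.integer(df$label)
  eps
}

# ---- model serialization ----------------------------------------------------

MODEL_FORMAT_VERSION <- 1L

#' Save or load a dense-network model
#'
#' Models are stored as a single self-describing JSON document: layer sizes,
#' activation names, flat weight/bias arrays, per-feature scaler constants
#' and the decision threshold. All floating-point parameters are written as
#' `%.17g` strings, which round-trip IEEE doubles bit-exactly, so
#' `load_model(save_model(m))` reproduces `m`'s predictions identically.
#'
#' @param model a `dense_net_model` from [train_dense_net()] or
#'   [new_dense_net()].
#' @param path file path for the JSON document.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   reconstructed `dense_net_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dense_net_model"))
  num <- function(x) I(sprintf("%.17g", as.numeric(x)))  # bit-exact doubles
  doc <- list(
    format = "sipwise-dense-net",
    version = MODEL_FORMAT_VERSION,
    n_inputs = model$architecture$n_inputs,
    hidden_sizes = I(model$architecture$hidden_sizes),
    n_outputs = model$architecture$n_outputs,
    hidden_activation = model$hidden_activation,
    output_activation = model$output_activation,
    weights = lapply(model$weights, num),
    biases = lapply(model$biases, num),
    scaler_mean = num(model$scaler_mean),
    scaler_scale = num(model$scaler_scale),
    decision_threshold = sprintf("%.17g", model$decision_threshold),
    feature_names = if (is.null(model$feature_names)) NULL
                    else I(model$feature_names)
  )
  doc <- doc[!vapply(doc, is.null, logical(1))]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed model file: ",
                                           conditionMessage(e)))
  if (!identical(doc$format, "sipwise-dense-net"))
    stop("not a sipwise model file: ", path)
  if (!identical(as.integer(doc$version), MODEL_FORMAT_VERSION))
    stop("unsupported model format version: ", doc$version)

  arch <- net_architecture(doc$n_inputs, as.integer(doc$hidden_sizes),
                           doc$n_outputs)
  sizes <- c(arch$n_inputs, arch$hidden_sizes, arch$n_outputs)
  weights <- vector("list", length(sizes) - 1)
  biases <- vector("list", length(sizes) - 1)
  for (l in seq_along(weights)) {
    w <- as.numeric(doc$weights[[l]])
    if (length(w) != sizes[l] * sizes[l + 1])
      stop("weight array ", l, " has wrong length (truncated file?)")
    weights[[l]] <- matrix(w, nrow = sizes[l], ncol = sizes[l + 1])
    b <- as.numeric(doc$biases[[l]])
    if (length(b) != sizes[l + 1])
      stop("bias array ", l, " has wrong length (truncated file?)")
    biases[[l]] <- b
  }
  new_dense_net(arch,
                weights = weights, biases = biases,
                hidden_activation = doc$hidden_activation,
                scaler_mean = as.numeric(doc$scaler_mean),
                scaler_scale = as.numeric(doc$scaler_scale),
                decision_threshold = as.numeric(doc$decision_threshold),
                feature_names = if (is.null(doc$feature_names)) NULL
                                else as.character(doc$feature_names))
}
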