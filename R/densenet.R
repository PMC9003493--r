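#' Dense network architecture
#'
#' Describes a fully connected feed-forward network by its layer widths.
#' The on-bottle classifiers are tiny: a single hidden layer of 1-20
#' neurons over 5 (sip) or 3 (first-sip) inputs, with 1 sigmoid output.
#'
#' @param n_inputs number of input features (>= 1).
#' @param hidden_sizes integer vector of hidden-layer widths; may be empty
#'   for a single-layer (logistic-regression-like) network.
#' @param n_outputs number of outputs (1 for binary classification).
#' @return An object of class `net_architecture`.
#' @examples
#' net_architecture(5, c(20, 15), 1)
#' @export
net_architecture <- function(n_inputs, hidden_sizes = integer(0), n_outputs = 1L) {
  n_inputs <- as.integer(n_inputs)
  hidden_sizes <- as.integer(hidden_sizes)
  n_outputs <- as.integer(n_outputs)
  if (n_inputs < 1L || n_outputs < 1L || any(hidden_sizes < 1L))
    stop("all layer sizes must be >= 1")
  structure(list(n_inputs = n_inputs, hidden_sizes = hidden_sizes,
                 n_outputs = n_outputs),
            class = "net_architecture")
}

#' Count trainable parameters of a dense architecture
#'
#' Sums `(fan_in + 1) * fan_out` over consecutive layer pairs — every weight
#' plus one bias per receiving neuron. This is the memory-footprint figure
#' used to rank candidate on-device architectures.
#'
#' @param arch a [net_architecture()].
#' @return Integer parameter count.
#' @examples
#' count_weights(net_architecture(5, 20, 1))   # 141
#' count_weights(net_architecture(5, c(20, 15), 1))  # 451
#' @export
count_weights <- function(arch) {
  stopifnot(inherits(arch, "net_architecture"))
  sizes <- c(arch$n_inputs, arch$hidden_sizes, arch$n_outputs)
  sum((sizes[-length(sizes)] + 1L) * sizes[-1L])
}

#' Construct a dense network model from explicit parameters
#'
#' Lower-level constructor used by [train_dense_net()], [load_model()] and
#' the tests. Weight matrices are `fan_in x fan_out`; biases are vectors of
#' length `fan_out`. When `weights` is `NULL` the network is initialized
#' with Glorot-uniform weights (`+/- sqrt(6 / (fan_in + fan_out))`) and zero
#' biases, using the current RNG state.
#'
#' @param arch a [net_architecture()].
#' @param weights,biases lists of per-layer arrays, or `NULL` to initialize.
#' @param hidden_activation `"relu"` (default) or `"identity"`.
#' @param scaler_mean,scaler_scale per-feature standardization constants
#'   applied before the forward pass.
#' @param decision_threshold probability cutoff for [classify()].
#' @param feature_names optional character vector documenting the inputs.
#' @return An object of class `dense_net_model`.
#' @export
new_dense_net <- function(arch, weights = NULL, biases = NULL,
                          hidden_activation = "relu",
                          scaler_mean = rep(0, arch$n_inputs),
                          scaler_scale = rep(1, arch$n_inputs),
                          decision_threshold = 0.5,
                          feature_names = NULL) {
  stopifnot(inherits(arch, "net_architecture"))
  hidden_activation <- match.arg(hidden_activation, c("relu", "identity"))
  sizes <- c(arch$n_inputs, arch$hidden_sizes, arch$n_outputs)
  n_layers <- length(sizes) - 1L
  if (is.null(weights)) {
    weights <- vector("list", n_layers)
    biases <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      weights[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                             nrow = sizes[l], ncol = sizes[l + 1])
      biases[[l]] <- rep(0, sizes[l + 1])
    }
  }
  stopifnot(length(weights) == n_layers, length(biases) == n_layers)
  for (l in seq_len(n_layers)) {
    stopifnot(nrow(weights[[l]]) == sizes[l], ncol(weights[[l]]) == sizes[l + 1],
              length(biases[[l]]) == sizes[l + 1])
    if (!all(is.finite(weights[[l]])) || !all(is.finite(biases[[l]])))
      stop("non-finite parameters in layer ", l)
  }
  stopifnot(length(scaler_mean) == arch$n_inputs,
            length(scaler_scale) == arch$n_inputs,
            all(scaler_scale > 0))
  structure(list(architecture = arch, weights = weights, biases = biases,
                 hidden_activation = hidden_activation,
                 output_activation = "sigmoid",
                 scaler_mean = as.numeric(scaler_mean),
                 scaler_scale = as.numeric(scaler_scale),
                 decision_threshold = as.numeric(decision_threshold),
                 feature_names = feature_names),
            class = "dense_net_model")
}

#' @export
print.dense_net_model <- function(x, ...) {
  a <- x$architecture
  cat(sprintf("<dense_net_model> %d-%s-%d (%s hidden, sigmoid out), %d parameters\n",
              a$n_inputs,
              if (length(a$hidden_sizes)) paste(a$hidden_sizes, collapse = "-") else "0",
              a$n_outputs, x$hidden_activation, count_weights(a)))
  if (!is.null(x$feature_names))
    cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Total parameters actually stored in a model
#' @param model a `dense_net_model`.
#' @return Integer count of stored weights plus biases; always equals
#'   [count_weights()] of the architecture.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "dense_net_model"))
  sum(vapply(model$weights, length, integer(1))) +
    sum(vapply(model$biases, length, integer(1)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass over a plain matrix of already-scaled inputs.
# Returns the activation list when cache = TRUE (for backprop).
forward_pass <- function(model, X, cache = FALSE) {
  A <- X
  acts <- list(A)
  n_layers <- length(model$weights)
  for (l in seq_len(n_layers)) {
    Z <- sweep(A %*% model$weights[[l]], 2, model$biases[[l]], `+`)
    A <- if (l < n_layers && model$hidden_activation == "relu") pmax(Z, 0)
         else if (l < n_layers) Z
         else sigmoid(Z)
    acts[[l + 1L]] <- A
  }
  if (cache) acts else A
}

as_feature_matrix <- function(model, features) {
  d <- model$architecture$n_inputs
  if (is.data.frame(features)) {
    if (!is.null(model$feature_names) &&
        all(model$feature_names %in% names(features)))
      features <- features[, model$feature_names, drop = FALSE]
    features <- as.matrix(features)
  }
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != d)
    stop("feature dimension mismatch: model expects ", d, " inputs, got ",
         ncol(features))
  storage.mode(features) <- "double"
  features
}

#' Predicted sip probability / hard classification
#'
#' `predict_proba` standardizes the features with the model's stored scaler
#' constants and runs the sigmoid-output forward pass; `classify` applies
#' the model's decision threshold (probability >= threshold maps to 1).
#'
#' @param model a `dense_net_model`.
#' @param features numeric vector (one observation), matrix, or data.frame
#'   whose columns cover the model's `feature_names`.
#' @return `predict_proba`: numeric vector of probabilities in `[0, 1]`;
#'   `classify`: integer vector of 0/1 labels.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "dense_net_model"))
  X <- as_feature_matrix(model, features)
  Xs <- sweep(sweep(X, 2, model$scaler_mean, `-`), 2, model$scaler_scale, `/`)
  as.numeric(forward_pass(model, Xs))
}

#' @rdname predict_proba
#' @export
classify <- function(model, features) {
  as.integer(predict_proba(model, features) >= model$decision_threshold)
}

#' Training configuration for the dense networks
#'
#' The two on-device classifiers use different regimes: the sip classifier
#' trains with SGD for 300 epochs at batch size 100, the first-sip detector
#' with Adam for 150 epochs at batch size 10; both use binary cross-entropy
#' and an 80:20 stratified train-validation split. Learning rates default to
#' 0.01 (SGD) and 0.001 (Adam).
#'
#' @param optimizer `"sgd"` or `"adam"`.
#' @param epochs number of passes over the training split.
#' @param batch_size minibatch size.
#' @param train_val_split fraction of rows used for training (default 0.8).
#' @param learning_rate step size; `NULL` picks the optimizer default.
#' @param seed integer seed fixing initialization and shuffling.
#' @param n_restarts independent seeded restarts; the fit with the lowest
#'   final training loss is kept. Tiny networks occasionally land in a poor
#'   local minimum from an unlucky initialization; a few restarts make the
#'   outcome robust while staying fully deterministic.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = c("sgd", "adam"), epochs = 300L,
                         batch_size = 100L, train_val_split = 0.8,
                         learning_rate = NULL, seed = 0L, n_restarts = 3L) {
  optimizer <- match.arg(optimizer)
  if (is.null(learning_rate))
    learning_rate <- if (optimizer == "sgd") 0.01 else 0.001
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            train_val_split > 0, train_val_split < 1, n_restarts >= 1)
  structure(list(optimizer = optimizer, loss = "binary_cross_entropy",
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 train_val_split = as.numeric(train_val_split),
                 learning_rate = as.numeric(learning_rate),
                 seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts)),
            class = "train_config")
}

#' @rdname train_config
#' @export
sip_train_config <- function(seed = 0L, epochs = 300L, batch_size = 100L, ...) {
  train_config(optimizer = "sgd", epochs = epochs, batch_size = batch_size,
               seed = seed, ...)
}

#' @rdname train_config
#' @export
firstsip_train_config <- function(seed = 0L, epochs = 150L, batch_size = 10L,
                                  learning_rate = 0.01, ...) {
  # 150 epochs is a short budget; 1e-3 Adam plateaus short of convergence
  # on separable gradient features, so this regime steps harder.
  train_config(optimizer = "adam", epochs = epochs, batch_size = batch_size,
               learning_rate = learning_rate, seed = seed, ...)
}

# Evaluate RNG-dependent code under a fixed seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

bce_loss <- function(p, y, w) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w)
}

#' Train a dense network classifier from scratch
#'
#' Explicit minibatch gradient descent over the dense layers: standardize
#' the features (constants estimated on the training split and stored in
#' the model), initialize Glorot-uniform, then minimize weighted binary
#' cross-entropy with SGD or Adam. Everything downstream of `config$seed`
#' (initialization, split, shuffle order) is deterministic, so two runs
#' with the same data and seed produce bit-identical weights.
#'
#' @param features data.frame or matrix of predictors (rows = observations).
#' @param labels 0/1 vector, one per row.
#' @param arch a [net_architecture()] whose `n_inputs` matches the features.
#' @param config a [train_config()].
#' @param sample_weights optional per-row weights (e.g. inverse class
#'   frequency for imbalanced first-sip data); `NULL` for uniform.
#' @param decision_threshold stored with the model for [classify()].
#' @return A `dense_net_model` with a `training` element: per-epoch training
#'   loss, the train/validation row indices, and final loss/accuracy on both
#'   splits.
#' @export
train_dense_net <- function(features, labels, arch,
                            config = train_config(),
                            sample_weights = NULL,
                            decision_threshold = 0.5) {
  stopifnot(inherits(arch, "net_architecture"), inherits(config, "train_config"))
  feature_names <- if (is.data.frame(features)) {
    nm <- setdiff(names(features), "label")
    features <- features[, nm, drop = FALSE]
    nm
  } else colnames(features)
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as.numeric(labels)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (!all(is.finite(X))) stop("features contain non-finite values")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  if (ncol(X) != arch$n_inputs)
    stop("architecture expects ", arch$n_inputs, " inputs, features have ",
         ncol(X), " columns")
  w <- if (is.null(sample_weights)) rep(1, n) else as.numeric(sample_weights)
  stopifnot(length(w) == n, all(w > 0))

  # stratified shuffle split, fixed by the base seed (shared by restarts)
  idx_tr <- with_seed(config$seed, {
    sort(unlist(lapply(c(0, 1), function(cl) {
      rows <- which(y == cl)
      rows <- sample(rows)
      rows[seq_len(max(1L, round(config$train_val_split * length(rows))))]
    })))
  })
  idx_va <- setdiff(seq_len(n), idx_tr)

  mu <- colMeans(X[idx_tr, , drop = FALSE])
  sdev <- apply(X[idx_tr, , drop = FALSE], 2, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, `-`), 2, sdev, `/`)

  fit_once <- function(restart_seed) with_seed(restart_seed, {
    model <- new_dense_net(arch, scaler_mean = mu, scaler_scale = sdev,
                           decision_threshold = decision_threshold,
                           feature_names = feature_names)
    n_layers <- length(model$weights)

    # Adam state
    mW <- lapply(model$weights, function(w) w * 0); vW <- mW
    mB <- lapply(model$biases, function(b) b * 0); vB <- mB
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; adam_t <- 0L

    epoch_loss <- numeric(config$epochs)
    Xtr <- Xs[idx_tr, , drop = FALSE]; ytr <- y[idx_tr]; wtr <- w[idx_tr]
    ntr <- length(ytr)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample(ntr)
      for (start in seq(1L, ntr, by = config$batch_size)) {
        rows <- ord[start:min(start + config$batch_size - 1L, ntr)]
        Xb <- Xtr[rows, , drop = FALSE]
        yb <- ytr[rows]; wb <- wtr[rows]

        acts <- forward_pass(model, Xb, cache = TRUE)
        p <- as.numeric(acts[[n_layers + 1L]])
        # d(BCE)/d(logit) for sigmoid output, weighted mean over the batch
        delta <- matrix((p - yb) * wb / sum(wb), ncol = 1)

        gW <- vector("list", n_layers); gB <- vector("list", n_layers)
        for (l in rev(seq_len(n_layers))) {
          gW[[l]] <- crossprod(acts[[l]], delta)
          gB[[l]] <- colSums(delta)
          if (l > 1L) {
            delta <- delta %*% t(model$weights[[l]])
            if (model$hidden_activation == "relu")
              delta <- delta * (acts[[l]] > 0)
          }
        }

        if (config$optimizer == "sgd") {
          for (l in seq_len(n_layers)) {
            model$weights[[l]] <- model$weights[[l]] - config$learning_rate * gW[[l]]
            model$biases[[l]] <- model$biases[[l]] - config$learning_rate * gB[[l]]
          }
        } else {
          adam_t <- adam_t + 1L
          c1 <- 1 - beta1^adam_t; c2 <- 1 - beta2^adam_t
          for (l in seq_len(n_layers)) {
            mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
            vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
            model$weights[[l]] <- model$weights[[l]] -
              config$learning_rate * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + adam_eps)
            mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB[[l]]
            vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB[[l]]^2
            model$biases[[l]] <- model$biases[[l]] -
              config$learning_rate * (mB[[l]] / c1) / (sqrt(vB[[l]] / c2) + adam_eps)
          }
        }
      }
      epoch_loss[epoch] <- bce_loss(as.numeric(forward_pass(model, Xtr)), ytr, wtr)
    }
    model$training <- list(epoch_loss = epoch_loss)
    model
  })

  fits <- lapply(seq_len(config$n_restarts) - 1L,
                 function(r) fit_once(config$seed + r * 10007L))
  final_loss <- vapply(fits, function(f) utils::tail(f$training$epoch_loss, 1),
                       numeric(1))
  model <- fits[[which.min(final_loss)]]

  split_metrics <- function(rows) {
    if (!length(rows)) return(list(loss = NA_real_, accuracy = NA_real_))
    p <- as.numeric(forward_pass(model, Xs[rows, , drop = FALSE]))
    list(loss = bce_loss(p, y[rows], w[rows]),
         accuracy = mean((p >= decision_threshold) == (y[rows] == 1)))
  }
  model$training <- list(
    config = config,
    epoch_loss = model$training$epoch_loss,
    restart_final_loss = final_loss,
    train_idx = idx_tr, val_idx = idx_va,
    train = split_metrics(idx_tr),
    validation = split_metrics(idx_va)
  )
  model
}
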