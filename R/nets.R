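# Network architectures for c-VEP decoding: the shared convolutional trunk,
# the K-bit reconstruction head, the 6-class head and the Siamese
# (twin-network) similarity models, with their training loops.

#' Convolutional trunk configuration
#'
#' The trunk front end bin-averages the temporal axis to `resample_to`
#' samples (4 per code bit under the defaults) so that the two /2 poolings
#' leave one temporal bin per code bit; the flattened feature length is then
#' `temporal_filters2 * resample_to / 4` (2016 = 32 x 63 under the defaults,
#' which fixes the dense-head parameter counts).
#'
#' @param spatial_filters Filters of the channel-collapsing spatial
#'   convolution (default 8).
#' @param temporal_kernel1,temporal_filters1 First temporal block: kernel
#'   length 11, 16 filters, followed by ReLU, 1x2 max pooling and 20%
#'   dropout.
#' @param temporal_kernel2,temporal_filters2 Second temporal block: kernel
#'   length 14, 32 filters, ReLU, 1x2 max pooling, 30% dropout.
#' @param dropout1,dropout2 Dropout rates of the two blocks.
#' @param resample_to Temporal length after the bin-average front end
#'   (default 252; must be divisible by 4).
#' @return A `cvep_trunkconfig` list.
#' @export
trunk_config <- function(spatial_filters = 8L,
                         temporal_kernel1 = 11L, temporal_filters1 = 16L,
                         temporal_kernel2 = 14L, temporal_filters2 = 32L,
                         dropout1 = 0.20, dropout2 = 0.30,
                         resample_to = 252L) {
  stopifnot(dropout1 >= 0, dropout1 < 1, dropout2 >= 0, dropout2 < 1,
            temporal_kernel1 > 0, temporal_kernel2 > 0,
            resample_to %% 4L == 0L)
  structure(list(spatial_filters = as.integer(spatial_filters),
                 temporal_kernel1 = as.integer(temporal_kernel1),
                 temporal_filters1 = as.integer(temporal_filters1),
                 temporal_kernel2 = as.integer(temporal_kernel2),
                 temporal_filters2 = as.integer(temporal_filters2),
                 dropout1 = dropout1, dropout2 = dropout2,
                 resample_to = as.integer(resample_to)),
            class = "cvep_trunkconfig")
}

#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-3).
#' @param l2 L2 regularization factor on weights (default 1e-4).
#' @param epochs Training epochs (40 for the CNN heads, 30 for Siamese).
#' @param batch Mini-batch size (64 for the CNN heads, 256 pairs for
#'   Siamese).
#' @param shuffle Reshuffle the data each epoch (default TRUE).
#' @param seed Seed governing all training randomness: weight init (when the
#'   net is built inside the training call), shuffling, dropout and pair
#'   sampling.
#' @return A `cvep_trainconfig` list.
#' @export
train_config <- function(lr = 1e-3, l2 = 1e-4, epochs = 40L, batch = 64L,
                         shuffle = TRUE, seed = 1L) {
  stopifnot(lr > 0, epochs >= 1)
  structure(list(lr = lr, l2 = l2, epochs = as.integer(epochs),
                 batch = as.integer(batch), shuffle = shuffle,
                 seed = as.integer(seed)),
            class = "cvep_trainconfig")
}

#' Build the shared convolutional trunk
#'
#' Layer order: temporal bin-average resampling, spatial convolution (Ns x 1,
#' collapses the channel axis), temporal convolution block 1 (ReLU, 1x2 max
#' pool, dropout), temporal convolution block 2 (ReLU, 1x2 max pool,
#' dropout), flatten. Under the default configuration the flattened feature
#' length is 2016 and the trunk carries 8,640 weight parameters (8,696 with
#' convolution biases).
#'
#' @param config A [trunk_config()].
#' @param n_channels Input channel count Ns.
#' @param n_time Input temporal length Nt (any length; the front end
#'   resamples it).
#' @param seed Optional seed for weight initialization; `NULL` uses the
#'   current RNG state.
#' @return A `cvep_trunk` object (list of layers plus geometry).
#' @export
build_trunk <- function(config = trunk_config(), n_channels = 8L,
                        n_time = 538L, seed = NULL) {
  stopifnot(inherits(config, "cvep_trunkconfig"))
  build <- function() {
    layers <- list(
      layer_resample(n_time, config$resample_to),
      layer_conv_spatial(n_channels, config$spatial_filters),
      layer_conv_temporal(config$spatial_filters, config$temporal_filters1,
                          config$temporal_kernel1),
      layer_relu(), layer_maxpool2(), layer_dropout(config$dropout1),
      layer_conv_temporal(config$temporal_filters1, config$temporal_filters2,
                          config$temporal_kernel2),
      layer_relu(), layer_maxpool2(), layer_dropout(config$dropout2),
      layer_flatten())
    structure(list(layers = layers, config = config,
                   n_channels = n_channels, n_time = n_time,
                   feature_len = config$temporal_filters2 *
                     config$resample_to %/% 4L),
              class = "cvep_trunk")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Parameter counts of a network or trunk
#'
#' @param net A `cvep_trunk` or `cvep_net`.
#' @return Named vector: `with_bias` and `weights_only` parameter counts.
#' @export
n_params <- function(net) {
  c(with_bias = count_params(net$layers, TRUE),
    weights_only = count_params(net$layers, FALSE))
}

# epochs (n, C, T) -> batch tensor (C, T, n)
epochs_to_batch <- function(epochs, idx = seq_len(n_trials(epochs))) {
  aperm(epochs$data[idx, , , drop = FALSE], c(2, 3, 1))
}

#' Attach the K-bit reconstruction head
#'
#' Dense layer from the flattened trunk features to K sigmoid outputs, one
#' per code bit (2016 x 63 + 63 = 127,071 added parameters under the default
#' trunk).
#'
#' @param trunk A [build_trunk()].
#' @param K Code length in bits (default 63).
#' @param seed Optional seed for head initialization.
#' @return A `cvep_net` with `kind = "kbit"`.
#' @export
build_kbit_head <- function(trunk, K = 63L, seed = NULL) {
  stopifnot(inherits(trunk, "cvep_trunk"))
  build <- function() {
    layers <- c(trunk$layers, list(layer_dense(trunk$feature_len, K),
                                   layer_sigmoid()))
    structure(list(layers = layers, kind = "kbit", K = K,
                   trunk_depth = length(trunk$layers),
                   n_channels = trunk$n_channels, n_time = trunk$n_time),
              class = "cvep_net")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Attach the direct-classification head
#'
#' Dense layer to `n_classes` softmax outputs (2016 x 6 + 6 = 12,102 added
#' parameters under the default trunk).
#'
#' @param trunk A [build_trunk()].
#' @param n_classes Number of stimulus classes (default 6).
#' @param seed Optional seed for head initialization.
#' @return A `cvep_net` with `kind = "class"`.
#' @export
build_class_head <- function(trunk, n_classes = 6L, seed = NULL) {
  stopifnot(inherits(trunk, "cvep_trunk"))
  build <- function() {
    layers <- c(trunk$layers, list(layer_dense(trunk$feature_len, n_classes),
                                   layer_softmax()))
    structure(list(layers = layers, kind = "class", n_classes = n_classes,
                   trunk_depth = length(trunk$layers),
                   n_channels = trunk$n_channels, n_time = trunk$n_time),
              class = "cvep_net")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Forward pass of a trained network
#'
#' Dropout disabled: deterministic, and equivariant to trial order.
#'
#' @param net A `cvep_net`.
#' @param epochs A `cvep_epochs` (or a `(C, T, n)` array).
#' @param batch Evaluation batch size (default 256).
#' @return Matrix `trials x outputs`: reconstructions in `[0, 1]` for
#'   `"kbit"` nets, class probabilities (rows sum 1) for `"class"` nets.
#' @export
predict_net <- function(net, epochs, batch = 256L) {
  x <- if (inherits(epochs, "cvep_epochs")) epochs_to_batch(epochs) else epochs
  n <- dim(x)[3]
  out <- NULL
  for (at in seq(1L, n, batch)) {
    idx <- at:min(at + batch - 1L, n)
    y <- forward_net(net$layers, x[, , idx, drop = FALSE], FALSE)$out
    out <- cbind(out, y)
  }
  t(out)
}

# Shared mini-batch trainer. loss: "mse" (targets matrix K x n in columns) or
# "ce" (targets = one-hot matrix n_classes x n). Returns net + history.
train_loop <- function(net, x, targets, cfg, loss,
                       x_val = NULL, t_val = NULL) {
  n <- dim(x)[3]
  state <- adam_init(net$layers)
  step <- 0L
  history <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- if (cfg$shuffle) sample.int(n) else seq_len(n)
      for (at in seq(1L, n, cfg$batch)) {
        idx <- ord[at:min(at + cfg$batch - 1L, n)]
        nb <- length(idx)
        fw <- forward_net(net$layers, x[, , idx, drop = FALSE], TRUE)
        if (loss == "mse") {
          dout <- 2 * (fw$out - targets[, idx, drop = FALSE]) /
            (nb * nrow(targets))
        } else {
          # cross-entropy through softmax: replace the softmax backward by
          # feeding (p - y)/n into the layer below
          dout <- (fw$out - targets[, idx, drop = FALSE]) / nb
        }
        if (loss == "ce") {
          # skip the softmax layer's own backward (its gradient is folded in)
          L <- length(net$layers)
          bw <- backward_net(net$layers[-L], fw$caches[-L], dout)
          bw$grads <- c(bw$grads, list(NULL))
        } else {
          bw <- backward_net(net$layers, fw$caches, dout)
        }
        step <- step + 1L
        upd <- adam_step(net$layers, bw$grads, state, step, cfg$lr, cfg$l2)
        net$layers <- upd$layers
        state <- upd$state
      }
      ev_x <- if (is.null(x_val)) x else x_val
      ev_t <- if (is.null(x_val)) targets else t_val
      pred <- t(predict_net(net, ev_x))
      history[ep] <- if (loss == "mse") sqrt(mean((pred - ev_t)^2))
                     else mean(apply(pred, 2, which.max) ==
                               apply(ev_t, 2, which.max))
    }
  })
  list(net = net, history = history)
}

#' Train the K-bit reconstruction network
#'
#' Mean-squared-error loss between the sigmoid outputs and the 0/1 code-bank
#' row of each trial's class; validation RMSE is recorded once per epoch
#' (training RMSE when no validation set is given). Data are reshuffled each
#' epoch; deterministic given `cfg$seed`.
#'
#' @param net A [build_kbit_head()] network.
#' @param train Training `cvep_epochs`.
#' @param bank The [build_code_bank()] defining the targets.
#' @param val Optional validation `cvep_epochs`.
#' @param cfg A [train_config()] (use `epochs = 40`, `batch = 64` for the
#'   reference regime).
#' @return List with `net` (trained) and `history` (per-epoch RMSE).
#' @export
train_reconstruction <- function(net, train, bank, val = NULL,
                                 cfg = train_config()) {
  stopifnot(inherits(net, "cvep_net"), net$kind == "kbit",
            inherits(bank, "cvep_codebank"))
  if (any(train$labels > bank$n_classes))
    stop("trial label outside the code bank")
  x <- epochs_to_batch(train)
  targets <- t(bank$codes[train$labels, , drop = FALSE])
  xv <- tv <- NULL
  if (!is.null(val)) {
    xv <- epochs_to_batch(val)
    tv <- t(bank$codes[val$labels, , drop = FALSE])
  }
  train_loop(net, x, targets, cfg, "mse", xv, tv)
}

#' Train the direct-classification network
#'
#' Categorical cross-entropy loss; per-epoch accuracy history (validation
#' accuracy when a validation set is given).
#'
#' @param net A [build_class_head()] network.
#' @param train,val Training / optional validation `cvep_epochs`.
#' @param cfg A [train_config()].
#' @return List with `net` and `history` (per-epoch accuracy).
#' @export
train_classifier <- function(net, train, val = NULL, cfg = train_config()) {
  stopifnot(inherits(net, "cvep_net"), net$kind == "class")
  onehot <- function(l) {
    m <- matrix(0, net$n_classes, length(l))
    m[cbind(l, seq_along(l))] <- 1
    m
  }
  x <- epochs_to_batch(train)
  xv <- if (!is.null(val)) epochs_to_batch(val)
  tv <- if (!is.null(val)) onehot(val$labels)
  train_loop(net, x, onehot(train$labels), cfg, "ce", xv, tv)
}
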