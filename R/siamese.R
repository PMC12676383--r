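# Siamese (twin) similarity networks: shared-weight trunks project trials
# into a K-dimensional embedding; the absolute embedding difference feeds a
# dense + sigmoid similarity head. Both the single multi-class model and the
# per-class binary ensemble are provided.

#' Build a Siamese pair-similarity network
#'
#' Twin copies of the trunk share one set of weights; trunk features are
#' projected by a dense layer into a K-dimensional embedding, and the
#' similarity of a pair is `sigmoid(dense(|e1 - e2|))`, a scalar in `[0, 1]`.
#' Identical inputs give `sigmoid(bias)` by construction, and the score is
#' symmetric in its arguments.
#'
#' @param trunk A [build_trunk()].
#' @param K Embedding dimension (default 63, one per code bit).
#' @param seed Optional seed for initialization.
#' @return A `cvep_siamese` object: `body` (trunk + embedding layers) and
#'   `head` (dense 1-unit similarity layer).
#' @export
build_siamese <- function(trunk, K = 63L, seed = NULL) {
  stopifnot(inherits(trunk, "cvep_trunk"))
  build <- function() {
    body <- c(trunk$layers, list(layer_dense(trunk$feature_len, K)))
    head <- layer_dense(K, 1L)
    structure(list(body = body, head = head, K = K,
                   n_channels = trunk$n_channels, n_time = trunk$n_time),
              class = "cvep_siamese")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Sample a balanced batch of trial pairs
#'
#' Exactly `floor(n_pairs/2)` same-class and `ceiling(n_pairs/2)`
#' different-class pairs (balanced within one pair), reproducible by seed.
#'
#' @param epochs A `cvep_epochs` with at least 2 classes present (and at
#'   least one class with 2 trials).
#' @param n_pairs Number of pairs.
#' @param seed RNG seed.
#' @return A `cvep_pairbatch`: `epochs`, index vectors `left` / `right`, and
#'   binary `same`.
#' @export
make_pairs <- function(epochs, n_pairs, seed = 1L) {
  cls <- sort(unique(epochs$labels))
  if (length(cls) < 2L) stop("need at least 2 classes to form negative pairs")
  by_class <- lapply(cls, function(c) which(epochs$labels == c))
  names(by_class) <- cls
  rich <- which(lengths(by_class) >= 2L)
  if (!length(rich)) stop("no class has 2 trials to form positive pairs")
  n_pos <- n_pairs %/% 2L
  n_neg <- n_pairs - n_pos
  with_seed(seed, {
    left <- integer(n_pairs); right <- integer(n_pairs)
    same <- c(rep(1L, n_pos), rep(0L, n_neg))
    for (i in seq_len(n_pos)) {
      c1 <- rich[sample.int(length(rich), 1L)]
      ij <- sample(by_class[[c1]], 2L)
      left[i] <- ij[1]; right[i] <- ij[2]
    }
    for (i in n_pos + seq_len(n_neg)) {
      cc <- sample.int(length(cls), 2L)
      left[i] <- by_class[[cc[1]]][sample.int(length(by_class[[cc[1]]]), 1L)]
      right[i] <- by_class[[cc[2]]][sample.int(length(by_class[[cc[2]]]), 1L)]
    }
    structure(list(epochs = epochs, left = left, right = right, same = same),
              class = "cvep_pairbatch")
  })
}

#' Sample a balanced pair batch for one target class
#'
#' Positives pair two trials of class `k`; negatives pair one class-`k` trial
#' with one trial from any other class — the regime used to train each model
#' of the per-class Siamese ensemble.
#'
#' @inheritParams make_pairs
#' @param k Target class.
#' @return A `cvep_pairbatch`.
#' @export
make_pairs_binary <- function(epochs, k, n_pairs, seed = 1L) {
  in_k <- which(epochs$labels == k)
  out_k <- which(epochs$labels != k)
  if (length(in_k) < 2L) stop("class ", k, " needs at least 2 trials")
  if (!length(out_k)) stop("no trials outside class ", k)
  n_pos <- n_pairs %/% 2L
  n_neg <- n_pairs - n_pos
  with_seed(seed, {
    left <- integer(n_pairs); right <- integer(n_pairs)
    same <- c(rep(1L, n_pos), rep(0L, n_neg))
    for (i in seq_len(n_pos)) {
      ij <- sample(in_k, 2L)
      left[i] <- ij[1]; right[i] <- ij[2]
    }
    for (i in n_pos + seq_len(n_neg)) {
      left[i] <- in_k[sample.int(length(in_k), 1L)]
      right[i] <- out_k[sample.int(length(out_k), 1L)]
    }
    structure(list(epochs = epochs, left = left, right = right, same = same),
              class = "cvep_pairbatch")
  })
}

# elementwise sum of two grads lists
add_grads <- function(g1, g2) {
  for (i in seq_along(g1)) {
    if (is.null(g1[[i]])) next
    g1[[i]]$W <- g1[[i]]$W + g2[[i]]$W
    g1[[i]]$b <- g1[[i]]$b + g2[[i]]$b
  }
  g1
}

# forward a pair batch; returns embeddings, similarity and caches
siamese_forward <- function(net, x1, x2, training = FALSE) {
  f1 <- forward_net(net$body, x1, training)
  f2 <- forward_net(net$body, x2, training)
  u <- abs(f1$out - f2$out)
  z <- net$head$W %*% u + net$head$b
  p <- 1 / (1 + exp(-z))
  list(p = as.numeric(p), u = u, f1 = f1, f2 = f2)
}

#' Train a Siamese network on labeled pairs
#'
#' Binary cross-entropy between predicted similarities and pair labels;
#' gradients flow through both twins into the shared weights. Pairs are
#' reshuffled into mini-batches each epoch; deterministic given `cfg$seed`.
#'
#' @param net A [build_siamese()].
#' @param pairs A [make_pairs()] / [make_pairs_binary()] batch.
#' @param cfg A [train_config()] (reference regime: `epochs = 30`,
#'   `batch = 256`).
#' @return List with `net` (trained) and `history` (per-epoch mean BCE over
#'   the pair set).
#' @export
train_siamese <- function(net, pairs, cfg = train_config(epochs = 30L,
                                                         batch = 256L)) {
  stopifnot(inherits(net, "cvep_siamese"), inherits(pairs, "cvep_pairbatch"))
  xall <- epochs_to_batch(pairs$epochs)
  n <- length(pairs$same)
  state_body <- adam_init(net$body)
  state_head <- adam_init(list(net$head))
  step <- 0L
  history <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- if (cfg$shuffle) sample.int(n) else seq_len(n)
      ep_loss <- 0
      for (at in seq(1L, n, cfg$batch)) {
        idx <- ord[at:min(at + cfg$batch - 1L, n)]
        nb <- length(idx)
        fw <- siamese_forward(net,
                              xall[, , pairs$left[idx], drop = FALSE],
                              xall[, , pairs$right[idx], drop = FALSE],
                              training = TRUE)
        y <- pairs$same[idx]
        eps <- 1e-12
        ep_loss <- ep_loss - sum(y * log(fw$p + eps) +
                                 (1 - y) * log(1 - fw$p + eps))
        dz <- matrix(fw$p - y, 1L, nb) / nb        # BCE through sigmoid
        g_head <- list(W = tcrossprod(dz, fw$u), b = rowSums(dz))
        du <- crossprod(net$head$W, dz)
        s <- sign(fw$f1$out - fw$f2$out)
        b1 <- backward_net(net$body, fw$f1$caches, du * s)
        b2 <- backward_net(net$body, fw$f2$caches, -du * s)
        g_body <- add_grads(b1$grads, b2$grads)
        step <- step + 1L
        upd <- adam_step(net$body, g_body, state_body, step, cfg$lr, cfg$l2)
        net$body <- upd$layers; state_body <- upd$state
        updh <- adam_step(list(net$head), list(g_head), state_head, step,
                          cfg$lr, cfg$l2)
        net$head <- updh$layers[[1]]; state_head <- updh$state
      }
      history[ep] <- ep_loss / n
    }
  })
  list(net = net, history = history)
}

#' Embed trials with a Siamese body
#' @param net A `cvep_siamese`.
#' @param epochs A `cvep_epochs`.
#' @param batch Evaluation batch size.
#' @return Matrix `trials x K` of embeddings.
#' @export
siamese_embed <- function(net, epochs, batch = 256L) {
  x <- epochs_to_batch(epochs)
  n <- dim(x)[3]
  out <- NULL
  for (at in seq(1L, n, batch)) {
    idx <- at:min(at + batch - 1L, n)
    out <- cbind(out, forward_net(net$body, x[, , idx, drop = FALSE],
                                  FALSE)$out)
  }
  t(out)
}

# similarity between two embedding matrices (n x K each), row-wise
sim_from_embed <- function(net, E1, E2) {
  z <- abs(E1 - E2) %*% as.numeric(net$head$W) + net$head$b
  as.numeric(1 / (1 + exp(-z)))
}

#' Pair similarity scores
#' @param net A trained `cvep_siamese`.
#' @param pairs A `cvep_pairbatch`.
#' @return Numeric similarity in `[0, 1]` per pair.
#' @export
siamese_similarity <- function(net, pairs) {
  E <- siamese_embed(net, pairs$epochs)
  sim_from_embed(net, E[pairs$left, , drop = FALSE],
                 E[pairs$right, , drop = FALSE])
}

#' Multi-class scoring with a single Siamese model
#'
#' The score of a trial for class `c` is its mean similarity to `n_ref`
#' support trials of class `c` (drawn deterministically by `seed`); the label
#' is the argmax, ties to the lowest class index.
#'
#' @param net A trained `cvep_siamese`.
#' @param test Trials to score.
#' @param support Labeled support trials containing every class.
#' @param n_ref Reference trials per class (default 10, capped at the class
#'   size).
#' @param n_classes Number of classes (default `max(support$labels)`).
#' @param seed Seed for the support draw.
#' @return List with `scores` (trials x classes) and `labels`.
#' @export
siamese_score_multiclass <- function(net, test, support, n_ref = 10L,
                                     n_classes = max(support$labels),
                                     seed = 1L) {
  refs <- with_seed(seed, lapply(seq_len(n_classes), function(c) {
    idx <- which(support$labels == c)
    if (!length(idx)) stop("class ", c, " absent from support set")
    if (length(idx) > n_ref) sample(idx, n_ref) else idx
  }))
  Et <- siamese_embed(net, test)
  Es <- siamese_embed(net, support)
  S <- vapply(seq_len(n_classes), function(c) {
    R <- Es[refs[[c]], , drop = FALSE]
    rowMeans(vapply(seq_len(nrow(R)), function(r)
      sim_from_embed(net, Et, matrix(R[r, ], nrow(Et), ncol(Et),
                                     byrow = TRUE)),
      numeric(nrow(Et))))
  }, numeric(nrow(Et)))
  S <- matrix(S, nrow = nrow(Et))
  list(scores = S, labels = argmax_rows(S))
}

#' Train the per-class binary Siamese ensemble
#'
#' One Siamese model per class; model `k` is trained on pairs whose positives
#' are both in class `k` and whose negatives pair class `k` with the rest.
#'
#' @param trunk_factory Zero-argument function returning a freshly
#'   initialized [build_trunk()] (called once per class).
#' @param train Training `cvep_epochs`.
#' @param cfg A [train_config()]; model `k` trains under seed
#'   `cfg$seed + k`.
#' @param n_pairs Pairs sampled per model (default 1024).
#' @param n_classes Number of classes (default `max(train$labels)`).
#' @param K Embedding dimension.
#' @return A `cvep_siamese_ensemble` (list of models + the support set).
#' @export
train_siamese_ensemble <- function(trunk_factory, train,
                                   cfg = train_config(epochs = 30L,
                                                      batch = 256L),
                                   n_pairs = 1024L,
                                   n_classes = max(train$labels), K = 63L) {
  models <- lapply(seq_len(n_classes), function(k) {
    seed_k <- cfg$seed + k
    net <- build_siamese(trunk_factory(), K = K, seed = seed_k)
    pk <- make_pairs_binary(train, k, n_pairs, seed = seed_k)
    cfg_k <- cfg; cfg_k$seed <- seed_k
    train_siamese(net, pk, cfg_k)$net
  })
  structure(list(models = models, n_classes = n_classes, support = train),
            class = "cvep_siamese_ensemble")
}

#' Score trials with the Siamese ensemble
#'
#' `score[i, k]` is the mean similarity of trial `i` under model `k` to
#' `n_ref` class-`k` support trials; the multi-class label is the argmax
#' (ties to the lowest index) and `binary` holds each model's own 0.5
#' thresholded decision.
#'
#' @param ensemble A [train_siamese_ensemble()].
#' @param test Trials to score.
#' @param n_ref Reference trials per class.
#' @param seed Seed for the support draw.
#' @return List with `scores`, `labels` and `binary` (trials x classes 0/1).
#' @export
siamese_ensemble_score <- function(ensemble, test, n_ref = 10L, seed = 1L) {
  stopifnot(inherits(ensemble, "cvep_siamese_ensemble"))
  support <- ensemble$support
  S <- vapply(seq_len(ensemble$n_classes), function(k) {
    net <- ensemble$models[[k]]
    idx <- which(support$labels == k)
    refs <- with_seed(seed + k,
                      if (length(idx) > n_ref) sample(idx, n_ref) else idx)
    Et <- siamese_embed(net, test)
    Es <- siamese_embed(net, subset_epochs(support, refs))
    rowMeans(vapply(seq_len(nrow(Es)), function(r)
      sim_from_embed(net, Et, matrix(Es[r, ], nrow(Et), ncol(Et),
                                     byrow = TRUE)),
      numeric(nrow(Et))))
  }, numeric(n_trials(test)))
  S <- matrix(S, nrow = n_trials(test))
  list(scores = S, labels = argmax_rows(S), binary = (S >= 0.5) * 1L)
}
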