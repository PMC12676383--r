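# Trunk geometry, parameter-count identities, gradient correctness,
# training smoke tests and determinism.

test_that("the default trunk reaches the printed feature and parameter counts", {
  trunk <- build_trunk(trunk_config(), 8L, 538L, seed = 1)
  expect_equal(trunk$feature_len, 2016L)        # 32 filters x 63 bins
  np <- n_params(trunk)
  expect_equal(unname(np["weights_only"]), 8640L)
  expect_equal(unname(np["with_bias"]), 8696L)

  kb <- build_kbit_head(trunk, 63L, seed = 2)
  expect_equal(unname(n_params(kb)["with_bias"] - np["with_bias"]),
               2016L * 63L + 63L)               # 127,071
  cl <- build_class_head(trunk, 6L, seed = 2)
  expect_equal(unname(n_params(cl)["with_bias"] - np["with_bias"]),
               2016L * 6L + 6L)                 # 12,102

  x <- array(rnorm(8 * 538 * 3), c(8, 538, 3))
  feats <- forward_net(trunk$layers, x, FALSE)$out
  expect_equal(dim(feats), c(2016L, 3L))
  # spatial convolution collapses the channel axis 8 -> spatial_filters
  sp <- forward_net(trunk$layers[1:2], x, FALSE)$out
  expect_equal(dim(sp), c(8L, 252L, 3L))
})

test_that("incompatible input lengths are rejected with the required length", {
  tc <- trunk_config(resample_to = 252L)
  expect_error(
    forward_net(build_trunk(tc, 4L, 40L)$layers,
                array(0, c(4, 40, 1)), FALSE),
    "252")
})

test_that("forward passes are deterministic and order-equivariant at inference", {
  tc <- trunk_config(spatial_filters = 3L, temporal_kernel1 = 3L,
                     temporal_filters1 = 4L, temporal_kernel2 = 5L,
                     temporal_filters2 = 6L, dropout1 = 0.2, dropout2 = 0.2,
                     resample_to = 20L)
  trunk <- build_trunk(tc, 4L, 40L, seed = 3)
  net <- build_class_head(trunk, 3L, seed = 4)
  ep <- new_epochs(array(rnorm(6 * 4 * 40), c(6, 4, 40)),
                   rep(1:3, 2), rep(1L, 6), 512)
  p1 <- predict_net(net, ep)
  p2 <- predict_net(net, ep)
  expect_identical(p1, p2)
  perm <- c(4, 2, 6, 1, 3, 5)
  p3 <- predict_net(net, subset_epochs(ep, perm))
  expect_equal(p3, p1[perm, ], tolerance = 1e-12)
  expect_equal(rowSums(p1), rep(1, 6), tolerance = 1e-9)
})

test_that("sigmoid outputs are bounded and zero input yields sigmoid(bias)", {
  tc <- trunk_config(spatial_filters = 3L, temporal_kernel1 = 3L,
                     temporal_filters1 = 4L, temporal_kernel2 = 5L,
                     temporal_filters2 = 6L, dropout1 = 0, dropout2 = 0,
                     resample_to = 20L)
  trunk <- build_trunk(tc, 4L, 40L, seed = 5)
  net <- build_kbit_head(trunk, 7L, seed = 6)
  x0 <- array(0, c(4, 40, 2))
  y <- forward_net(net$layers, x0, FALSE)$out
  b <- net$layers[[length(net$layers) - 1L]]$b
  expect_equal(y[, 1], 1 / (1 + exp(-b)), tolerance = 1e-12)
  expect_identical(y[, 1], y[, 2])
  x <- array(rnorm(4 * 40 * 5), c(4, 40, 5))
  yr <- forward_net(net$layers, x, FALSE)$out
  expect_true(all(yr >= 0 & yr <= 1))
})

test_that("analytic gradients match numerical differentiation", {
  tc <- trunk_config(spatial_filters = 3L, temporal_kernel1 = 3L,
                     temporal_filters1 = 4L, temporal_kernel2 = 5L,
                     temporal_filters2 = 6L, dropout1 = 0, dropout2 = 0,
                     resample_to = 16L)
  trunk <- build_trunk(tc, 2L, 20L, seed = 7)
  net <- build_kbit_head(trunk, 5L, seed = 8)
  set.seed(9)
  x <- array(rnorm(2 * 20 * 4), c(2, 20, 4))
  y <- matrix(runif(5 * 4) > 0.5, 5, 4) * 1
  loss <- function(layers) mean((forward_net(layers, x, FALSE)$out - y)^2)
  fw <- forward_net(net$layers, x, FALSE)
  bw <- backward_net(net$layers, fw$caches, 2 * (fw$out - y) / length(y))
  for (li in seq_along(net$layers)) {
    g <- bw$grads[[li]]
    if (is.null(g)) next
    for (pn in c("W", "b")) {
      P <- net$layers[[li]][[pn]]
      for (ii in sample(length(P), min(4L, length(P)))) {
        eps <- 1e-6
        lp <- net$layers; lp[[li]][[pn]][ii] <- P[ii] + eps
        lm <- net$layers; lm[[li]][[pn]][ii] <- P[ii] - eps
        num <- (loss(lp) - loss(lm)) / (2 * eps)
        expect_equal(g[[pn]][ii], num, tolerance = 1e-5)
      }
    }
  }
})

test_that("reconstruction training reduces RMSE and is seed-deterministic", {
  ep <- sim_small(n_sessions = 1L, n_trials = 60L, snr_db = 20, seed = 61L)
  trunk <- build_trunk(tiny_trunk_config(), 8L, 538L, seed = 10)
  net <- build_kbit_head(trunk, 63L, seed = 11)
  cfg <- train_config(epochs = 4L, batch = 16L, seed = 12L)
  tr1 <- train_reconstruction(net, ep, the_bank, cfg = cfg)
  expect_length(tr1$history, 4L)
  expect_lt(tr1$history[4], tr1$history[1])
  tr2 <- train_reconstruction(net, ep, the_bank, cfg = cfg)
  expect_identical(tr1$net$layers, tr2$net$layers)

  # validation RMSE reported once per epoch on the held-out set
  val <- subset_epochs(ep, 1:12)
  trv <- train_reconstruction(net, subset_epochs(ep, 13:60), the_bank,
                              val = val, cfg = cfg)
  expect_length(trv$history, 4L)

  bad <- ep; bad$labels[1] <- 9L
  expect_error(train_reconstruction(net, bad, the_bank, cfg = cfg),
               "outside the code bank")
})

test_that("classification training overfits a tiny separable set", {
  ep <- sim_small(n_sessions = 1L, n_trials = 36L, snr_db = 30, seed = 62L)
  trunk <- build_trunk(tiny_trunk_config(), 8L, 538L, seed = 13)
  net <- build_class_head(trunk, 6L, seed = 14)
  tr <- train_classifier(net, ep, cfg = train_config(epochs = 8L,
                                                     batch = 12L, seed = 15L))
  expect_gte(tail(tr$history, 1), 0.95)
  proba <- predict_net(tr$net, ep)
  expect_equal(dim(proba), c(36L, 6L))
  expect_equal(argmax_rows(proba),
               apply(proba, 1, which.max), ignore_attr = TRUE)
})

test_that("pair sampling is balanced, reproducible and label-consistent", {
  ep <- sim_small(seed = 63L)
  pb <- make_pairs(ep, 256L, seed = 20L)
  expect_equal(sum(pb$same == 1), 128L)
  expect_equal(sum(pb$same == 0), 128L)
  pb2 <- make_pairs(ep, 256L, seed = 20L)
  expect_identical(pb$left, pb2$left)
  expect_identical(pb$right, pb2$right)
  pos <- pb$same == 1
  expect_true(all(ep$labels[pb$left[pos]] == ep$labels[pb$right[pos]]))
  expect_true(all(ep$labels[pb$left[!pos]] != ep$labels[pb$right[!pos]]))

  one <- subset_epochs(ep, ep$labels == 1)
  expect_error(make_pairs(one, 10L), "2 classes")

  pk <- make_pairs_binary(ep, 3L, 100L, seed = 21L)
  expect_true(all(ep$labels[pk$left] == 3L |
                  ep$labels[pk$right] == 3L))
  expect_true(all(ep$labels[pk$left[pk$same == 1]] == 3L &
                  ep$labels[pk$right[pk$same == 1]] == 3L))
})

test_that("siamese similarity is symmetric with a 63-d embedding", {
  trunk <- build_trunk(tiny_trunk_config(), 8L, 538L, seed = 22)
  net <- build_siamese(trunk, K = 63L, seed = 23)
  ep <- sim_small(seed = 64L)
  E <- siamese_embed(net, subset_epochs(ep, 1:6))
  expect_equal(dim(E), c(6L, 63L))
  x <- epochs_to_batch(subset_epochs(ep, 1:4))
  fw_ab <- siamese_forward(net, x[, , 1:2, drop = FALSE],
                           x[, , 3:4, drop = FALSE])
  fw_ba <- siamese_forward(net, x[, , 3:4, drop = FALSE],
                           x[, , 1:2, drop = FALSE])
  expect_equal(fw_ab$p, fw_ba$p, tolerance = 1e-12)
  # identical inputs: similarity = sigmoid(head bias), same for any pair
  fw_aa <- siamese_forward(net, x[, , 1:2, drop = FALSE],
                           x[, , 1:2, drop = FALSE])
  expect_equal(fw_aa$p, rep(1 / (1 + exp(-net$head$b)), 2),
               tolerance = 1e-12)
})

test_that("siamese training learns pair similarity on easy data", {
  ep <- sim_small(n_sessions = 1L, n_trials = 48L, snr_db = 30, seed = 65L)
  trunk <- build_trunk(tiny_trunk_config(), 8L, 538L, seed = 24)
  net <- build_siamese(trunk, K = 63L, seed = 25)
  pairs <- make_pairs(ep, 384L, seed = 26L)
  cfg <- train_config(epochs = 8L, batch = 64L, seed = 27L)
  tr <- train_siamese(net, pairs, cfg)
  expect_lt(tail(tr$history, 1), tr$history[1])
  # held-out pairs from the same generator settings
  ep2 <- sim_small(n_sessions = 1L, n_trials = 48L, snr_db = 30, seed = 66L)
  held <- make_pairs(ep2, 128L, seed = 28L)
  sim <- siamese_similarity(tr$net, held)
  expect_gte(mean((sim >= 0.5) == (held$same == 1)), 0.9)
  # determinism
  tr2 <- train_siamese(net, pairs, cfg)
  expect_identical(tr$net$body, tr2$net$body)

  sc <- siamese_score_multiclass(tr$net, ep2, ep, n_ref = 5L, seed = 29L)
  expect_equal(dim(sc$scores), c(48L, 6L))
  expect_gte(mean(sc$labels == ep2$labels), 0.9)
  expect_error(siamese_score_multiclass(tr$net, ep2,
                                        subset_epochs(ep, ep$labels < 6),
                                        n_classes = 6L, seed = 29L),
               "absent")
})

test_that("the per-class ensemble yields six models and sane accuracy", {
  ep <- sim_small(n_sessions = 1L, n_trials = 48L, snr_db = 30, seed = 67L)
  cfg <- train_config(epochs = 3L, batch = 64L, seed = 30L)
  factory <- function() build_trunk(tiny_trunk_config(), 8L, 538L)
  ens <- with_seed(31L, train_siamese_ensemble(factory, ep, cfg,
                                               n_pairs = 192L, K = 63L))
  expect_length(ens$models, 6L)
  ep2 <- sim_small(n_sessions = 1L, n_trials = 48L, snr_db = 30, seed = 68L)
  sc <- siamese_ensemble_score(ens, ep2, n_ref = 5L, seed = 32L)
  expect_equal(dim(sc$scores), c(48L, 6L))
  expect_true(all(sc$binary %in% c(0L, 1L)))
  expect_gte(mean(sc$labels == ep2$labels), 0.8)
})
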