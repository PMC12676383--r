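# End-to-end decoding pipelines: each constructor returns a
# `(train, test) -> labels` function suitable for session_cv(), with
# temporal augmentation applied according to an augment_config().

#' Method vocabulary
#'
#' The nine-method battery: `corr_blda`, `cca_blda`,
#' `cnn_kbit_euclid`, `cnn_kbit_mahal`, `cnn_kbit_emd`, `cnn_kbit_cemd`,
#' `cnn_class`, `siamese_single`, `siamese_ensemble` (plus the simple
#' `template_corr` baseline).
#'
#' @return Character vector of method names.
#' @export
method_names <- function() {
  c("corr_blda", "cca_blda", "cnn_kbit_euclid", "cnn_kbit_mahal",
    "cnn_kbit_emd", "cnn_kbit_cemd", "cnn_class", "siamese_single",
    "siamese_ensemble", "template_corr")
}

# apply TA-side augmentation
aug_train <- function(train, aug) {
  if (aug$mode %in% c("TA", "TA_TC") && aug$alpha_shift > 0L)
    expand_train(train, aug) else train
}

#' Build a decoding pipeline
#'
#' @param method One of [method_names()].
#' @param bank Code bank (needed by the K-bit and template methods).
#' @param aug An [augment_config()] (default: no augmentation).
#' @param trunk_cfg,train_cfg Network configurations for the CNN / Siamese
#'   methods.
#' @param R Movement radius for `cnn_kbit_cemd` (default 8 bits).
#' @param lambda_shrink Shrinkage for `cnn_kbit_mahal` (default 0.1).
#' @param n_pairs Training pairs for the Siamese methods (default 1024).
#' @param n_ref Support trials per class for Siamese scoring (default 10).
#' @param transductive_cov Estimate the Mahalanobis covariance from the test
#'   reconstructions instead of the training ones (default FALSE).
#' @return Function `(train, test) -> integer labels`.
#' @export
make_pipeline <- function(method, bank = build_code_bank(paper_code()),
                          aug = augment_config(),
                          trunk_cfg = trunk_config(),
                          train_cfg = train_config(),
                          R = 8, lambda_shrink = 0.1,
                          n_pairs = 1024L, n_ref = 10L,
                          transductive_cov = FALSE) {
  method <- match.arg(method, method_names())
  force(bank); force(aug); force(trunk_cfg); force(train_cfg)

  blda_pipe <- function(kind) {
    function(train, test) {
      train <- aug_train(train, aug)
      tpl <- build_templates(train)
      fm <- feature_matrix(train, tpl, kind)
      ovr <- fit_blda_ovr(fm$X, fm$labels)
      score_fn <- function(te)
        predict_ovr(ovr, feature_matrix(te, tpl, kind)$X)$scores
      combine_test(score_fn, test, aug, "max")$labels
    }
  }

  kbit_pipe <- function(distance) {
    function(train, test) {
      train <- aug_train(train, aug)
      d <- dim(train$data)
      trunk <- build_trunk(trunk_cfg, d[2], d[3], seed = train_cfg$seed)
      net <- build_kbit_head(trunk, K = ncol(bank$codes),
                             seed = train_cfg$seed + 1L)
      net <- train_reconstruction(net, train, bank, cfg = train_cfg)$net
      recon_train <- if (distance == "mahal" && !transductive_cov)
        predict_net(net, train)
      score_fn <- function(te) {
        recon <- predict_net(net, te)
        switch(distance,
          euclid = euclidean_decode(recon, bank)$D,
          mahal = if (transductive_cov)
            mahalanobis_decode(recon, bank, shrinkage_config(lambda_shrink),
                               cov_source = recon)$D
          else
            mahalanobis_decode(recon, bank, shrinkage_config(lambda_shrink),
                               cov_source = recon_train,
                               cov_labels = train$labels)$D,
          emd = emd_decode(recon, bank)$D,
          cemd = cemd_decode(recon, bank, R)$D)
      }
      labels <- combine_test(score_fn, test, aug, "min")$labels
      if (anyNA(labels)) {   # all-infeasible constrained rows: EMD fallback
        fb <- combine_test(function(te) emd_decode(predict_net(net, te),
                                                   bank)$D,
                           test, aug, "min")$labels
        labels[is.na(labels)] <- fb[is.na(labels)]
      }
      labels
    }
  }

  switch(method,
    corr_blda = blda_pipe("corr"),
    cca_blda = blda_pipe("cca"),
    template_corr = function(train, test) {
      train <- aug_train(train, aug)
      tpl <- build_templates(train)
      score_fn <- function(te) template_correlate_decode(te, tpl)$scores
      combine_test(score_fn, test, aug, "max")$labels
    },
    cnn_kbit_euclid = kbit_pipe("euclid"),
    cnn_kbit_mahal = kbit_pipe("mahal"),
    cnn_kbit_emd = kbit_pipe("emd"),
    cnn_kbit_cemd = kbit_pipe("cemd"),
    cnn_class = function(train, test) {
      train <- aug_train(train, aug)
      d <- dim(train$data)
      trunk <- build_trunk(trunk_cfg, d[2], d[3], seed = train_cfg$seed)
      net <- build_class_head(trunk, n_classes = max(train$labels),
                              seed = train_cfg$seed + 1L)
      net <- train_classifier(net, train, cfg = train_cfg)$net
      score_fn <- function(te) predict_net(net, te)
      combine_test(score_fn, test, aug, "max")$labels
    },
    siamese_single = function(train, test) {
      train <- aug_train(train, aug)
      d <- dim(train$data)
      trunk <- build_trunk(trunk_cfg, d[2], d[3], seed = train_cfg$seed)
      net <- build_siamese(trunk, K = ncol(bank$codes),
                           seed = train_cfg$seed + 1L)
      pairs <- make_pairs(train, n_pairs, seed = train_cfg$seed)
      net <- train_siamese(net, pairs, train_cfg)$net
      score_fn <- function(te)
        siamese_score_multiclass(net, te, train, n_ref = n_ref,
                                 seed = train_cfg$seed)$scores
      combine_test(score_fn, test, aug, "max")$labels
    },
    siamese_ensemble = function(train, test) {
      train <- aug_train(train, aug)
      d <- dim(train$data)
      factory <- function() build_trunk(trunk_cfg, d[2], d[3])
      ens <- with_seed(train_cfg$seed,
        train_siamese_ensemble(factory, train, train_cfg,
                               n_pairs = n_pairs, K = ncol(bank$codes)))
      score_fn <- function(te)
        siamese_ensemble_score(ens, te, n_ref = n_ref,
                               seed = train_cfg$seed)$scores
      combine_test(score_fn, test, aug, "max")$labels
    })
}

#' Save / load a trained network with a JSON sidecar
#'
#' The checkpoint uses R's native serialization; the sidecar `<path>.json`
#' records the network kind, geometry and parameter counts.
#'
#' @param net A `cvep_net` or `cvep_siamese`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` invisibly; `load_net` returns the network.
#' @export
save_net <- function(net, path) {
  saveRDS(net, path)
  layers <- if (inherits(net, "cvep_siamese")) c(net$body, list(net$head))
            else net$layers
  jsonlite::write_json(
    list(class = class(net)[1], kind = net$kind %||% "siamese",
         n_channels = net$n_channels, n_time = net$n_time,
         params_with_bias = count_params(layers, TRUE),
         params_weights_only = count_params(layers, FALSE)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_net
#' @export
load_net <- function(path) readRDS(path)

#' Export a training history to CSV
#' @param history Numeric per-epoch metric vector.
#' @param path Output path.
#' @param metric Metric name for the header.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(history, path, metric = "metric") {
  df <- data.frame(epoch = seq_along(history), value = history)
  names(df)[2] <- metric
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
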