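# Classical decoding baselines: class-conditional channel templates,
# correlation and canonical-correlation features, Bayesian linear
# discriminant analysis (one-vs-rest) and plain template-correlation decoding.

#' Class-conditional channel templates
#'
#' `template[c, ch, ]` is the mean over training trials of class `c` of
#' channel `ch`; one template signal per electrode per class.
#'
#' @param train A `cvep_epochs` containing every class in `classes`.
#' @param classes Class alphabet (default all labels present, `1..max`).
#' @return A `cvep_templates` object: `templates` array
#'   `Nclasses x Ns x Nt`.
#' @export
build_templates <- function(train, classes = seq_len(max(train$labels))) {
  stopifnot(inherits(train, "cvep_epochs"))
  d <- dim(train$data)
  tpl <- array(0, c(length(classes), d[2], d[3]))
  for (k in seq_along(classes)) {
    idx <- train$labels == classes[k]
    if (!any(idx)) stop("no training trials for class ", classes[k])
    tpl[k, , ] <- apply(train$data[idx, , , drop = FALSE], c(2, 3), mean)
  }
  structure(list(templates = tpl, classes = as.integer(classes),
                 channel_names = train$channel_names),
            class = "cvep_templates")
}

# Pearson correlation of the rows of A against the rows of B; zero-variance
# rows correlate 0 instead of NA, flagged via attribute "zero_variance".
row_cor <- function(A, B) {
  flagged <- FALSE
  std <- function(M) {
    M <- M - rowMeans(M)
    s <- sqrt(rowSums(M^2))
    bad <- s < .Machine$double.eps * ncol(M)
    if (any(bad)) {
      flagged <<- TRUE
      s[bad] <- Inf
    }
    M / s
  }
  out <- tcrossprod(std(A), std(B))
  attr(out, "zero_variance") <- flagged
  out
}

#' Correlation features for one epoch
#'
#' Pearson correlation of every epoch channel with every template channel of
#' every class. Ordering is class-major, then epoch channel, then template
#' channel: feature `((c-1) Ns + (i-1)) Ns + j`. With 8 channels and 6
#' classes the vector has length `Ns * Ns * Nclasses = 384`.
#'
#' @param epoch Numeric `Ns x Nt` matrix.
#' @param templates A [build_templates()] bank.
#' @return Numeric feature vector in `[-1, 1]`.
#' @export
corr_features <- function(epoch, templates) {
  stopifnot(inherits(templates, "cvep_templates"))
  tp <- templates$templates
  if (!all(dim(epoch) == dim(tp)[2:3]))
    stop("epoch dimensions do not match the template bank")
  out <- lapply(seq_len(dim(tp)[1]), function(c) row_cor(epoch, tp[c, , ]))
  if (any(vapply(out, attr, logical(1), "zero_variance")))
    warning("zero-variance series: correlation features set to 0",
            call. = FALSE)
  unlist(lapply(out, function(m) as.vector(t(m))))
}

# Canonical correlations between the columns of X and Y (observations in
# rows), robust to rank deficiency: returns min(rank X, rank Y) values.
canon_cor <- function(X, Y, tol = 1e-7) {
  if (nrow(X) < 2L) stop("canonical correlation needs at least 2 time points")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  qx <- qr(Xc, tol = tol); qy <- qr(Yc, tol = tol)
  rx <- qx$rank; ry <- qy$rank
  if (rx == 0L || ry == 0L) return(numeric(0))
  Q1 <- qr.Q(qx)[, seq_len(rx), drop = FALSE]
  Q2 <- qr.Q(qy)[, seq_len(ry), drop = FALSE]
  d <- svd(crossprod(Q1, Q2), nu = 0, nv = 0)$d
  pmin(pmax(d[seq_len(min(rx, ry))], 0), 1)
}

#' Canonical-correlation features for one epoch
#'
#' Per class, the canonical correlations between the `Nt x Ns` epoch matrix
#' and the class template matrix, sorted descending and padded with exact
#' zeros to `Ns` slots (rank-deficient epochs yield fewer correlations, e.g.
#' a duplicated channel gives 7 values plus one zero). Concatenated over
#' classes: `Ns * Nclasses = 48` features under the default geometry.
#'
#' @inheritParams corr_features
#' @return Numeric feature vector in `[0, 1]` (plus exact-zero padding).
#' @export
cca_features <- function(epoch, templates) {
  stopifnot(inherits(templates, "cvep_templates"))
  tp <- templates$templates
  if (!all(dim(epoch) == dim(tp)[2:3]))
    stop("epoch dimensions do not match the template bank")
  ns <- nrow(epoch)
  out <- lapply(seq_len(dim(tp)[1]), function(c) {
    r <- canon_cor(t(epoch), t(tp[c, , ]))
    c(r, rep(0, ns - length(r)))[seq_len(ns)]
  })
  unlist(out)
}

#' Feature matrix for an epoch set
#'
#' @param epochs A `cvep_epochs`.
#' @param templates A [build_templates()] bank.
#' @param kind `"corr"` (384 features) or `"cca"` (48 features).
#' @return List with `X` (examples x features), `labels` and `kind`.
#' @export
feature_matrix <- function(epochs, templates, kind = c("corr", "cca")) {
  kind <- match.arg(kind)
  fn <- if (kind == "corr") corr_features else cca_features
  X <- t(vapply(seq_len(n_trials(epochs)),
                function(i) fn(epochs$data[i, , , drop = TRUE], templates),
                numeric(length(fn(epochs$data[1, , , drop = TRUE],
                                  templates)))))
  list(X = X, labels = epochs$labels, kind = kind)
}

#' Fit a Bayesian linear discriminant (binary, evidence maximization)
#'
#' Bayesian linear regression onto +/-1 targets with a shared Gaussian prior
#' precision on the weights and Gaussian noise precision, both set by
#' iterative evidence maximization (stop when the relative change of both
#' precisions falls below `tol`, or after `max_iter` iterations). The
#' automatic regularization keeps weights finite even with duplicated
#' feature columns.
#'
#' @param X Numeric feature matrix (examples x features), no NaN.
#' @param y_binary Targets, `+1` / `-1` (or coercible two-level vector).
#' @param tol Relative-change stopping tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 200).
#' @return A `cvep_blda` model: `w` (weights), `b` (bias), `alpha` (prior
#'   precision), `beta` (noise precision), `iterations`.
#' @export
fit_blda <- function(X, y_binary, tol = 1e-6, max_iter = 200L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("feature matrix contains NA/NaN")
  y <- as.numeric(y_binary)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  y <- ifelse(y == max(y), 1, -1)
  Xa <- cbind(X, 1)                      # bias as augmented column
  n <- nrow(Xa); d <- ncol(Xa)
  eg <- eigen(crossprod(Xa), symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  Vty <- crossprod(eg$vectors, crossprod(Xa, y))
  alpha <- 1; beta <- 1
  iter <- 0L
  repeat {
    iter <- iter + 1L
    h <- beta / (beta * lam + alpha)
    m <- eg$vectors %*% (h * Vty)
    gamma <- sum(beta * lam / (beta * lam + alpha))
    res <- y - Xa %*% m
    alpha_new <- gamma / max(sum(m^2), .Machine$double.eps)
    beta_new <- (n - gamma) / max(sum(res^2), .Machine$double.eps)
    if (iter >= max_iter ||
        (abs(alpha_new - alpha) < tol * alpha &&
         abs(beta_new - beta) < tol * beta)) {
      alpha <- alpha_new; beta <- beta_new
      break
    }
    alpha <- alpha_new; beta <- beta_new
  }
  h <- beta / (beta * lam + alpha)
  m <- as.numeric(eg$vectors %*% (h * Vty))
  structure(list(w = m[-d], b = m[d], alpha = alpha, beta = beta,
                 iterations = iter), class = "cvep_blda")
}

#' Discriminant score of a BLDA model
#' @param model A `cvep_blda`.
#' @param X Feature matrix (examples x features).
#' @return Numeric score vector.
#' @export
blda_score <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$w)) stop("feature dimension mismatch")
  as.numeric(X %*% model$w + model$b)
}

#' Fit a one-vs-rest BLDA ensemble
#'
#' @param X Feature matrix.
#' @param labels Integer class labels `1..Nclasses`.
#' @param n_classes Number of classes (default `max(labels)`).
#' @return A `cvep_blda_ovr`: list of per-class binary models.
#' @export
fit_blda_ovr <- function(X, labels, n_classes = max(labels)) {
  models <- lapply(seq_len(n_classes), function(k)
    fit_blda(X, ifelse(labels == k, 1, -1)))
  structure(list(models = models, n_classes = n_classes),
            class = "cvep_blda_ovr")
}

#' Predict with a one-vs-rest BLDA ensemble
#'
#' Class scores are the per-class discriminant values passed through a
#' softmax, so every row of the score matrix sums to 1; the label is the
#' argmax, ties broken toward the lowest class index.
#'
#' @param ovr A [fit_blda_ovr()] ensemble.
#' @param X Feature matrix.
#' @return List with `labels` and `scores` (examples x classes, rows sum 1).
#' @export
predict_ovr <- function(ovr, X) {
  stopifnot(inherits(ovr, "cvep_blda_ovr"))
  S <- do.call(cbind, lapply(ovr$models, function(m) blda_score(m, X)))
  P <- softmax_rows(S)
  list(labels = argmax_rows(P), scores = P)
}

#' Template-correlation decoding
#'
#' The simplest baseline: score of trial `i` against class `c` is the sum
#' over channels of the Pearson correlation with the class template; label =
#' argmax.
#'
#' @param epochs A `cvep_epochs`.
#' @param templates A [build_templates()] bank.
#' @return List with `labels` and `scores` (trials x classes).
#' @export
template_correlate_decode <- function(epochs, templates) {
  tp <- templates$templates
  nc <- dim(tp)[1]
  S <- vapply(seq_len(n_trials(epochs)), function(i) {
    e <- epochs$data[i, , , drop = TRUE]
    vapply(seq_len(nc), function(c) sum(diag(row_cor(e, tp[c, , ]))),
           numeric(1))
  }, numeric(nc))
  S <- t(S)
  list(labels = argmax_rows(S), scores = S)
}

#' Export a feature matrix to CSV
#'
#' Writes `label` plus one column per feature; a header comment line records
#' the ordering convention.
#'
#' @param fm A [feature_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(fm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# kind=%s ordering=class-major,epoch-channel,template-channel",
    fm$kind), con)
  utils::write.csv(data.frame(label = fm$labels, fm$X), con,
                   row.names = FALSE)
  invisible(path)
}

#' Serialize a BLDA one-vs-rest ensemble to JSON
#' @param ovr A `cvep_blda_ovr`.
#' @param path Output path.
#' @return `path` invisibly; `read_blda_json` returns the ensemble.
#' @export
write_blda_json <- function(ovr, path) {
  jsonlite::write_json(
    list(n_classes = ovr$n_classes,
         models = lapply(ovr$models, function(m)
           list(w = m$w, b = m$b, alpha = m$alpha, beta = m$beta,
                iterations = m$iterations))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_blda_json
#' @export
read_blda_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(seq_len(obj$n_classes), function(k) {
    m <- obj$models[k, ]
    structure(list(w = unlist(m$w), b = m$b, alpha = m$alpha,
                   beta = m$beta, iterations = m$iterations),
              class = "cvep_blda")
  })
  structure(list(models = models, n_classes = obj$n_classes),
            class = "cvep_blda_ovr")
}
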