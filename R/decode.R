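# Distance-based decoding of reconstructed bit sequences against the code
# bank: squared Euclidean, shrinkage-regularized Mahalanobis, CDF-form Earth
# Mover's Distance, and radius-constrained EMD.

# Optional 0.5-thresholding of reconstructed outputs (the default passes the
# continuous values through, which is ranking-equivalent and loses no
# information).
prep_recon <- function(recon, threshold = NULL) {
  Y <- as.matrix(recon)
  if (!is.null(threshold)) Y <- (Y >= threshold) * 1
  Y
}

#' Squared-Euclidean decoding
#'
#' `D[i, c] = sum_k (y[i, k] - code[c, k])^2`; the square root is omitted as
#' it does not change the ranking. Label = argmin, ties to the lowest class
#' index.
#'
#' @param recon Numeric `trials x K` matrix of reconstructed bit values in
#'   `[0, 1]`.
#' @param bank A [build_code_bank()] with matching `K`.
#' @param threshold Optional threshold (e.g. 0.5) applied to `recon` first;
#'   default `NULL` uses the continuous values.
#' @return List with `D` (trials x classes) and `labels`.
#' @export
euclidean_decode <- function(recon, bank, threshold = NULL) {
  stopifnot(inherits(bank, "cvep_codebank"))
  Y <- prep_recon(recon, threshold)
  if (ncol(Y) != ncol(bank$codes)) stop("K mismatch between recon and bank")
  C <- bank$codes
  D <- outer(rowSums(Y^2), rep(1, nrow(C))) - 2 * tcrossprod(Y, C) +
    outer(rep(1, nrow(Y)), rowSums(C^2))
  D <- unname(pmax(D, 0))
  dimnames(D) <- NULL
  list(D = D, labels = argmin_rows(D))
}

#' Shrinkage configuration for Mahalanobis decoding
#' @param lambda_shrink Shrinkage weight in `[0, 1]` (default 0.1).
#' @return A `cvep_shrinkage` list.
#' @export
shrinkage_config <- function(lambda_shrink = 0.1) {
  stopifnot(lambda_shrink >= 0, lambda_shrink <= 1)
  structure(list(lambda_shrink = lambda_shrink), class = "cvep_shrinkage")
}

#' Mahalanobis decoding with shrinkage-regularized covariance
#'
#' The bit-wise covariance `Sigma` is estimated from `cov_source` (by default
#' the reconstructions being decoded; pass training-set reconstructions to
#' avoid transduction) and regularized as
#' `Sigma_reg = (1 - lambda) Sigma + lambda alpha I`, `alpha` being the mean
#' of the diagonal of `Sigma`. `D[i, c]` is the quadratic form of
#' `y_i - code_c` under `Sigma_reg^{-1}`.
#'
#' @inheritParams euclidean_decode
#' @param cfg A [shrinkage_config()].
#' @param cov_source Matrix whose rows estimate the covariance (default
#'   `recon`); needs at least 2 rows.
#' @param cov_labels Optional class labels aligned with `cov_source`. When
#'   given, the covariance is estimated from the residuals of each row
#'   around its class codeword (pooled within-class covariance, the usual
#'   "shared covariance" of discriminant analysis). Without labels the raw
#'   covariance of `cov_source` is used, which also absorbs between-class
#'   scatter and can suppress the class-separating directions when
#'   reconstructions are accurate.
#' @return List with `D`, `labels`, `alpha_diag` and `Sigma_reg`.
#' @export
mahalanobis_decode <- function(recon, bank, cfg = shrinkage_config(),
                               cov_source = recon, cov_labels = NULL,
                               threshold = NULL) {
  stopifnot(inherits(bank, "cvep_codebank"), inherits(cfg, "cvep_shrinkage"))
  Y <- prep_recon(recon, threshold)
  S <- as.matrix(cov_source)
  if (nrow(S) < 2L) stop("cov_source needs at least 2 rows")
  if (!is.null(cov_labels)) {
    if (length(cov_labels) != nrow(S))
      stop("cov_labels must align with cov_source rows")
    S <- S - bank$codes[cov_labels, , drop = FALSE]
  }
  Sigma <- stats::cov(S)
  alpha <- mean(diag(Sigma))
  lam <- cfg$lambda_shrink
  Sreg <- (1 - lam) * Sigma + lam * alpha * diag(ncol(Sigma))
  R <- tryCatch(chol(Sreg),
                error = function(e) stop("regularized covariance is singular"))
  C <- bank$codes
  D <- matrix(0, nrow(Y), nrow(C))
  for (c in seq_len(nrow(C))) {
    Z <- backsolve(R, t(Y) - C[c, ], transpose = TRUE)
    D[, c] <- colSums(Z^2)
  }
  list(D = D, labels = argmin_rows(D), alpha_diag = alpha, Sigma_reg = Sreg)
}

#' Normalize a vector to a probability mass function
#'
#' Entries are clipped at 0 and divided by their sum:
#' `p_k = max(0, v_k) / sum_b max(0, v_b)`.
#'
#' @param v Numeric vector with at least one positive entry.
#' @return PMF of the same length (nonnegative, sums to 1).
#' @export
normalize_pmf <- function(v) {
  v <- pmax(as.numeric(v), 0)
  s <- sum(v)
  if (s <= 0) stop("degenerate PMF: no positive mass after clipping")
  v / s
}

#' CDF-form Earth Mover's Distance decoding
#'
#' Reconstruction and code rows are normalized to PMFs; the 1-D EMD is the
#' mean absolute difference of their cumulative distributions,
#' `D[i, c] = (1/K) sum_k |CDF_p(k) - CDF_q(k)|`. Label = argmin.
#'
#' @inheritParams euclidean_decode
#' @return List with `D` and `labels`.
#' @export
emd_decode <- function(recon, bank) {
  stopifnot(inherits(bank, "cvep_codebank"))
  Y <- as.matrix(recon)
  K <- ncol(bank$codes)
  if (ncol(Y) != K) stop("K mismatch between recon and bank")
  P <- t(apply(Y, 1, normalize_pmf))
  Q <- t(apply(bank$codes, 1, normalize_pmf))
  cP <- t(apply(P, 1, cumsum))
  cQ <- t(apply(Q, 1, cumsum))
  D <- matrix(0, nrow(P), nrow(Q))
  for (c in seq_len(nrow(Q)))
    D[, c] <- rowMeans(abs(sweep(cP, 2, cQ[c, ])))
  list(D = D, labels = argmin_rows(D))
}

#' Radius-constrained Earth Mover's Distance between two PMFs
#'
#' Minimizes the transported mass weighted by bit-index displacement
#' `sum |k - j| X[k, j]` subject to the marginals and the locality window
#' `X[k, j] = 0` whenever `|k - j| > R`. Because `|k - j|` is a Monge cost
#' and uncrossing two transport arcs never widens their displacements, the
#' monotone (north-west-corner) coupling is optimal and is feasible whenever
#' any plan is; it is computed directly, without a generic LP solver.
#' Infeasible problems (mass forced to move farther than `R`) are not an
#' error: they return cost `+Inf`. The cost is normalized by the total flow
#' (1 for PMFs; kept for generality with unnormalized inputs). With
#' `R >= K - 1` the result equals the unconstrained 1-D EMD,
#' `sum_k |CDF_p - CDF_q|` in bit units.
#'
#' @param p,q PMFs of equal length (see [normalize_pmf()]).
#' @param R Movement radius in bits, `>= 0`.
#' @return List with `cost` (possibly `Inf`) and `plan` (`K x K` flow matrix;
#'   all-NA when infeasible).
#' @export
constrained_emd <- function(p, q, R) {
  stopifnot(length(p) == length(q), R >= 0)
  K <- length(p)
  tol <- 1e-12
  if (abs(sum(p) - sum(q)) > 1e-8)
    stop("p and q must carry equal total mass")
  total <- sum(p)
  plan <- matrix(0, K, K)
  i <- 1L; j <- 1L
  pi_left <- p[1]; qj_left <- q[1]
  cost <- 0
  while (i <= K && j <= K) {
    f <- min(pi_left, qj_left)
    if (f > tol) {
      if (abs(i - j) > R)
        return(list(cost = Inf, plan = matrix(NA_real_, K, K)))
      plan[i, j] <- plan[i, j] + f
      cost <- cost + abs(i - j) * f
    }
    pi_left <- pi_left - f
    qj_left <- qj_left - f
    if (pi_left <= tol) {
      i <- i + 1L
      if (i <= K) pi_left <- p[i]
    }
    if (qj_left <= tol) {
      j <- j + 1L
      if (j <= K) qj_left <- q[j]
    }
  }
  list(cost = cost / total, plan = plan)
}

#' Constrained-EMD decoding
#'
#' `D[i, c]` is the [constrained_emd()] cost between the trial's PMF and the
#' class code PMF. Classes with infeasible (infinite) transport are excluded
#' from the argmin; if every class is infeasible for a trial, the decision
#' falls back to the unconstrained EMD for that trial (with a message).
#'
#' @inheritParams euclidean_decode
#' @param R Movement radius in bits (default 8, one class-shift granularity).
#' @return List with `D` and `labels`.
#' @export
cemd_decode <- function(recon, bank, R = 8) {
  stopifnot(inherits(bank, "cvep_codebank"))
  Y <- as.matrix(recon)
  K <- ncol(bank$codes)
  if (ncol(Y) != K) stop("K mismatch between recon and bank")
  Q <- apply(bank$codes, 1, normalize_pmf)            # K x classes
  D <- matrix(0, nrow(Y), ncol(Q))
  for (i in seq_len(nrow(Y))) {
    p <- normalize_pmf(Y[i, ])
    for (c in seq_len(ncol(Q)))
      D[i, c] <- constrained_emd(p, Q[, c], R)$cost
  }
  labels <- argmin_rows(D)
  dead <- is.na(labels)
  if (any(dead)) {
    message(sum(dead), " trial(s) had no admissible local transport for any ",
            "class; falling back to unconstrained EMD for those trials")
    fb <- emd_decode(Y[dead, , drop = FALSE], bank)
    labels[dead] <- fb$labels
  }
  list(D = D, labels = labels)
}

#' Export a distance/score matrix with labels to CSV
#' @param D Trials x classes matrix.
#' @param labels Predicted labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decode_csv <- function(D, labels, path) {
  df <- data.frame(D)
  names(df) <- paste0("class", seq_len(ncol(D)))
  df$label <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
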