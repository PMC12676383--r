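# Distance decoders: squared Euclidean, shrinkage Mahalanobis, CDF-form EMD
# and radius-constrained EMD with its optimality certificate.

test_that("squared-Euclidean decoding matches hand arithmetic", {
  ed <- euclidean_decode(matrix(0.5, 2, 63), the_bank)
  expect_equal(ed$D, matrix(63 * 0.25, 2, 6))
  expect_equal(ed$labels, c(1L, 1L))          # tie -> lowest index

  exact <- the_bank$codes[c(2, 5), ] * 1
  ed2 <- euclidean_decode(exact, the_bank)
  expect_equal(ed2$labels, c(2L, 5L))
  expect_equal(ed2$D[1, 2], 0)

  # ranking is invariant to the square root
  set.seed(20)
  Y <- matrix(runif(10 * 63), 10)
  D <- euclidean_decode(Y, the_bank)$D
  expect_equal(apply(D, 1, which.min), apply(sqrt(D), 1, which.min))
})

test_that("Mahalanobis reduces to squared Euclidean under identity covariance", {
  set.seed(21)
  Y <- matrix(runif(20 * 63), 20)
  # cov_source with exactly identity covariance: impossible to sample, so
  # substitute the computation: lambda = 1 makes Sigma_reg = alpha I
  src <- matrix(rnorm(300 * 63), 300)
  full <- mahalanobis_decode(Y, the_bank, shrinkage_config(1), cov_source = src)
  eu <- euclidean_decode(Y, the_bank)
  expect_equal(full$labels, eu$labels)
  alpha <- mean(diag(stats::cov(src)))
  expect_equal(full$D * alpha, eu$D, tolerance = 1e-10)

  # identity Sigma_reg via a constructed source whose covariance is I
  src_i <- rbind(diag(63), -diag(63)) * sqrt(126 / 2) / sqrt(63)
  # (rows chosen so cov = I exactly)
  S <- stats::cov(src_i)
  skip_if_not(max(abs(S - diag(63) * S[1, 1])) < 1e-12)
  m2 <- mahalanobis_decode(Y, the_bank, shrinkage_config(0.1),
                           cov_source = src_i)
  expect_equal(m2$D * S[1, 1], eu$D, tolerance = 1e-8)
})

test_that("Mahalanobis distance is zero at the matching code row", {
  set.seed(22)
  src <- matrix(runif(200 * 63), 200)
  md <- mahalanobis_decode(the_bank$codes[3, , drop = FALSE] * 1, the_bank,
                           cov_source = src)
  expect_equal(md$D[1, 3], 0)
  expect_equal(md$labels, 3L)
  expect_error(mahalanobis_decode(matrix(0.5, 1, 63), the_bank,
                                  cov_source = matrix(0.5, 1, 63)),
               "2 rows")
})

test_that("PMF normalization clips at zero and rejects degenerate input", {
  expect_equal(normalize_pmf(c(1, 1, 0, 0)), c(0.5, 0.5, 0, 0))
  expect_equal(normalize_pmf(c(-1, 2)), c(0, 1))
  expect_error(normalize_pmf(c(0, 0, 0)), "degenerate PMF")
  expect_error(normalize_pmf(c(-3, -1)), "degenerate PMF")
})

test_that("CDF-form EMD matches point-mass arithmetic and is symmetric", {
  p <- rep(0, 63); p[2] <- 1
  q <- rep(0, 63); q[3] <- 1
  bank_q <- build_code_bank(new_code(q), 0)
  expect_equal(emd_decode(rbind(p), bank_q)$D[1, 1], 1 / 63)
  bank_p <- build_code_bank(new_code(p), 0)
  expect_equal(emd_decode(rbind(q), bank_p)$D[1, 1], 1 / 63)

  ed <- emd_decode(the_bank$codes[4, , drop = FALSE] * 1, the_bank)
  expect_equal(ed$D[1, 4], 0)
  expect_equal(ed$labels, 4L)
})

test_that("constrained EMD solves the banded transport program optimally", {
  # identity
  p <- normalize_pmf(runif(16))
  expect_equal(constrained_emd(p, p, 0)$cost, 0)

  # point masses 3 bits apart, window 2: infeasible
  p2 <- c(1, rep(0, 9)); q2 <- c(0, 0, 0, 1, rep(0, 6))
  expect_identical(constrained_emd(p2, q2, 2)$cost, Inf)
  expect_equal(constrained_emd(p2, q2, 3)$cost, 3)

  # the LP transport solution on 200 random PMF pairs (K <= 16):
  # the unconstrained optimum must equal the CDF closed form to 1e-8, and
  # the returned plan must carry a feasible dual certificate (LP optimality)
  set.seed(23)
  for (i in 1:200) {
    K <- sample(3:16, 1)
    p <- random_pmf(K); q <- random_pmf(K)
    sol <- constrained_emd(p, q, K - 1)
    cdf <- sum(abs(cumsum(p - q)))
    expect_equal(sol$cost, cdf, tolerance = 1e-8)
    expect_equal(rowSums(sol$plan), p, tolerance = 1e-8)
    expect_equal(colSums(sol$plan), q, tolerance = 1e-8)
    expect_true(isTRUE(certify_optimal(sol$plan, K - 1)))
  }
})

test_that("banded transport is optimal or correctly infeasible", {
  set.seed(24)
  for (i in 1:60) {
    K <- sample(4:12, 1)
    R <- sample(0:4, 1)
    p <- random_pmf(K); q <- random_pmf(K)
    sol <- constrained_emd(p, q, R)
    feasible <- transport_feasible(p, q, R)   # independent Hall oracle
    if (!feasible) {
      expect_identical(sol$cost, Inf)
    } else {
      expect_true(is.finite(sol$cost))
      expect_true(all(abs(sol$plan[abs(row(sol$plan) - col(sol$plan)) > R])
                      < 1e-10))
      cert <- certify_optimal(sol$plan, R)
      expect_true(isTRUE(cert) || is.na(cert))
      expect_false(isFALSE(cert))
    }
  }
})

test_that("constrained cost is non-increasing in the radius", {
  set.seed(25)
  for (i in 1:20) {
    p <- random_pmf(63); q <- random_pmf(63)
    costs <- vapply(c(1, 2, 4, 8, 62),
                    function(R) constrained_emd(p, q, R)$cost, numeric(1))
    for (j in seq_len(length(costs) - 1))
      expect_true(costs[j + 1] <= costs[j] + 1e-10)
  }
})

test_that("constrained decoding matches EMD for large radii", {
  set.seed(26)
  Y <- matrix(runif(12 * 63), 12)
  ce <- cemd_decode(Y, the_bank, R = 62)
  em <- emd_decode(Y, the_bank)
  expect_equal(ce$labels, em$labels)
  expect_equal(ce$D / 63, em$D, tolerance = 1e-10)

  exact <- the_bank$codes[6, , drop = FALSE] * 1
  for (R in c(0, 1, 8))
    expect_equal(cemd_decode(exact, the_bank, R)$labels, 6L)
})

test_that("all decoders return distance zero at an exact code row", {
  exact <- the_bank$codes * 1
  src <- matrix(runif(200 * 63), 200)
  eu <- euclidean_decode(exact, the_bank)
  ma <- mahalanobis_decode(exact, the_bank, cov_source = src)
  em <- emd_decode(exact, the_bank)
  ce <- cemd_decode(exact, the_bank, R = 8)
  for (res in list(eu, ma, em, ce)) {
    expect_equal(res$labels, 1:6)
    expect_equal(unname(diag(res$D)), rep(0, 6), tolerance = 1e-12)
  }
})
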