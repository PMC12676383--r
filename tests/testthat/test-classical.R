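# Templates, correlation / CCA features and BLDA classification.

test_that("templates are class-conditional channel means", {
  dat <- array(0, c(4, 2, 10))
  dat[1, , ] <- 1; dat[2, , ] <- 3       # class 1: values 1 and 3 -> mean 2
  dat[3, , ] <- 5; dat[4, , ] <- 5       # class 2: identical trials
  ep <- new_epochs(dat, c(1L, 1L, 2L, 2L), rep(1L, 4), 512)
  tb <- build_templates(ep)
  expect_true(all(tb$templates[1, , ] == 2))
  expect_true(all(tb$templates[2, , ] == 5))

  one <- subset_epochs(ep, 1:3)          # single trial for class 2
  tb1 <- build_templates(one)
  expect_equal(tb1$templates[2, , ], matrix(dat[3, , ], 2, 10))

  ep$labels <- c(1L, 1L, 1L, 1L)
  expect_error(build_templates(ep, classes = 1:2), "class 2")
})

test_that("correlation features have the documented geometry and limits", {
  ep <- sim_small(seed = 41L)
  tb <- build_templates(ep)
  f <- corr_features(ep$data[1, , , drop = TRUE], tb)
  expect_length(f, 8 * 8 * 6)
  expect_true(all(f >= -1 - 1e-12 & f <= 1 + 1e-12))
  expect_false(anyNA(f))

  # an epoch equal to the class-3 template: diagonal features of class 3 = 1
  tpl3 <- tb$templates[3, , ]
  f3 <- corr_features(tpl3, tb)
  block <- matrix(f3[(2 * 64 + 1):(3 * 64)], 8, 8, byrow = TRUE)
  expect_equal(unname(diag(block)), rep(1, 8))
  fneg <- corr_features(-tpl3, tb)
  blockn <- matrix(fneg[(2 * 64 + 1):(3 * 64)], 8, 8, byrow = TRUE)
  expect_equal(unname(diag(blockn)), rep(-1, 8))
})

test_that("correlation features are invariant to per-channel affine maps", {
  ep <- sim_small(seed = 41L)
  tb <- build_templates(ep)
  e <- ep$data[2, , , drop = TRUE]
  scaled <- e * matrix(c(2, 0.5, 3, 1, 4, 10, 0.1, 7), 8, ncol(e)) +
    matrix(1:8, 8, ncol(e))
  expect_equal(corr_features(scaled, tb),
               corr_features(e, tb), tolerance = 1e-10)
})

test_that("zero-variance channels give zero features with a warning", {
  ep <- sim_small(seed = 41L)
  tb <- build_templates(ep)
  e <- ep$data[1, , , drop = TRUE]
  e[4, ] <- 2.5
  expect_warning(f <- corr_features(e, tb), "zero-variance")
  block1 <- matrix(f[1:64], 8, 8, byrow = TRUE)
  expect_true(all(block1[4, ] == 0))
})

test_that("CCA features pad rank-deficient epochs with exact zeros", {
  ep <- sim_small(seed = 42L)
  tb <- build_templates(ep)
  f <- cca_features(ep$data[1, , , drop = TRUE], tb)
  expect_length(f, 8 * 6)
  expect_true(all(f >= 0 & f <= 1))

  # epoch equal to a template: first canonical correlation is 1
  f1 <- cca_features(tb$templates[2, , ], tb)
  expect_equal(f1[8 + 1], 1, tolerance = 1e-8)

  # duplicated channel drops the rank to 7: one exact zero per class block
  e <- ep$data[1, , , drop = TRUE]
  e[8, ] <- e[1, ]
  fr <- cca_features(e, tb)
  for (c in 0:5) {
    blk <- fr[c * 8 + (1:8)]
    expect_identical(blk[8], 0)
    expect_true(all(blk[1:7] > 0))
  }
})

test_that("CCA features are invariant to invertible channel mixing", {
  ep <- sim_small(seed = 42L)
  tb <- build_templates(ep)
  e <- ep$data[3, , , drop = TRUE]
  set.seed(10)
  A <- matrix(rnorm(64), 8, 8)           # almost surely invertible
  expect_equal(cca_features(A %*% e, tb), cca_features(e, tb),
               tolerance = 1e-6)
})

test_that("canonical correlations agree with the reference implementation", {
  set.seed(13)
  X <- matrix(rnorm(60 * 4), 60, 4)
  Y <- matrix(rnorm(60 * 3), 60, 3)
  ours <- canon_cor(X, Y)
  ref <- stats::cancor(X, Y)$cor
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("BLDA separates Gaussian blobs and regularizes duplicates", {
  set.seed(14)
  X <- rbind(matrix(rnorm(100, 0, 1), 50, 2),
             matrix(rnorm(100, 10, 1), 50, 2))
  y <- rep(c(-1, 1), each = 50)
  m <- fit_blda(X, y)
  expect_equal(mean(sign(blda_score(m, X)) == y), 1)
  expect_gt(m$alpha, 0); expect_gt(m$beta, 0)

  md <- fit_blda(cbind(X, X[, 1], X[, 1]), y)
  expect_true(all(is.finite(md$w)))

  expect_error(fit_blda(X, rep(1, 100)), "both classes")
})

test_that("one-vs-rest prediction normalizes scores and breaks ties low", {
  set.seed(15)
  centers <- list(c(0, 0), c(10, 0), c(0, 10))
  X <- do.call(rbind, lapply(centers, function(mu)
    cbind(rnorm(30, mu[1], 0.5), rnorm(30, mu[2], 0.5))))
  labs <- rep(1:3, each = 30)
  ovr <- fit_blda_ovr(X, labs)
  pr <- predict_ovr(ovr, X)
  expect_equal(mean(pr$labels == labs), 1)
  expect_equal(rowSums(pr$scores), rep(1, 90), tolerance = 1e-9)
  expect_error(predict_ovr(ovr, X[, 1, drop = FALSE]), "dimension")

  # exact ties resolve to the lowest class index
  expect_equal(argmax_rows(matrix(c(0.4, 0.4, 0.2), 1)), 1L)
})

test_that("BLDA ensembles survive a JSON round trip", {
  set.seed(16)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  ovr <- fit_blda_ovr(X, rep(1:2, each = 20))
  f <- withr::local_tempfile(fileext = ".json")
  write_blda_json(ovr, f)
  ovr2 <- read_blda_json(f)
  expect_equal(ovr2$models[[1]]$w, ovr$models[[1]]$w)
  expect_equal(predict_ovr(ovr2, X)$labels, predict_ovr(ovr, X)$labels)
})

test_that("correlation features + BLDA decode the simulator above chance", {
  ep <- sim_small(n_sessions = 3L, n_trials = 30L, snr_db = 10, jitter = 2L,
                  seed = 55L)
  pipe <- make_pipeline("corr_blda")
  rep <- session_cv(ep, pipe, "corr_blda")
  expect_gt(rep$mean, 60)
})
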