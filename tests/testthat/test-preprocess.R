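# Great-circle geometry, surface Laplacian, detrending and bandpass.

test_that("great-circle distance handles canonical separations", {
  expect_equal(great_circle_distance(c(0.3, 1.2), c(0.3, 1.2)), 0)
  # antipodal points on the unit sphere
  expect_equal(great_circle_distance(c(0, 0), c(0, pi)), pi)
  expect_equal(great_circle_distance(c(pi / 4, 0.5), c(-pi / 4, 0.5 + pi)),
               pi)
  # quarter great circle
  expect_equal(great_circle_distance(c(0, 0), c(0, pi / 2)), pi / 2)
  # symmetry and radius scaling
  p1 <- c(0.7, -1.1); p2 <- c(-0.2, 2.3)
  expect_equal(great_circle_distance(p1, p2), great_circle_distance(p2, p1))
  expect_equal(great_circle_distance(p1, p2, r = 2.5),
               2.5 * great_circle_distance(p1, p2))
})

test_that("great-circle distance satisfies the triangle inequality", {
  set.seed(77)
  for (i in 1:1000) {
    lat <- asin(stats::runif(3, -1, 1))
    lon <- stats::runif(3, -pi, pi)
    d12 <- great_circle_distance(c(lat[1], lon[1]), c(lat[2], lon[2]))
    d23 <- great_circle_distance(c(lat[2], lon[2]), c(lat[3], lon[3]))
    d13 <- great_circle_distance(c(lat[1], lon[1]), c(lat[3], lon[3]))
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("Laplacian weights are inverse distances within the radius", {
  # two sensors a quarter circle apart: d = pi/2, weight = 2/pi
  lay <- sensor_layout(c("a", "b"), c(0, 0), c(0, pi / 2))
  lw <- laplacian_weights(lay, radius = 2)
  expect_equal(lw$W[1, 2], 2 / pi)
  expect_equal(diag(lw$W), c(0, 0), ignore_attr = TRUE)
  expect_equal(lw$W, t(lw$W))                      # symmetric layout

  # distance 0.5 -> weight 2
  lay2 <- sensor_layout(c("a", "b"), c(0, 0), c(0, 0.5))
  expect_equal(laplacian_weights(lay2, radius = 1)$W[1, 2], 2)

  # beyond the radius the weight is zero
  lay3 <- sensor_layout(c("a", "b", "c"), c(0, 0, 0), c(0, 0.5, 2.0))
  W <- laplacian_weights(lay3, radius = 1)$W
  expect_equal(W[1, 3], 0)
  expect_gt(W[1, 2], 0)

  expect_error(laplacian_weights(
    sensor_layout(c("a", "b"), c(0.2, 0.2), c(1, 1))), "zero inter-sensor")

  # normalized rows sum to one over nonzero entries
  Wn <- laplacian_weights(default_layout(), normalized = TRUE)$W
  expect_equal(unname(rowSums(Wn)), rep(1, 8))
})

test_that("the Laplacian matches the hand-computed two-sensor case", {
  lw <- structure(list(W = matrix(c(0, 2, 2, 0), 2), radius = 1,
                       normalized = FALSE), class = "cvep_lapweights")
  ep <- new_epochs(array(c(3, 1), c(1, 2, 1)), 1L, 1L, 512)
  out <- apply_laplacian(ep, lw)
  expect_equal(out$data[1, 1, 1], 3 - 2 * 1)
  expect_equal(out$data[1, 2, 1], 1 - 2 * 3)

  # neighbors at zero leave the target unchanged
  ep0 <- new_epochs(array(c(5, 0), c(1, 2, 1)), 1L, 1L, 512)
  expect_equal(apply_laplacian(ep0, lw)$data[1, 1, 1], 5)
})

test_that("identical channels vanish under a normalized Laplacian", {
  lay <- default_layout()
  lw <- laplacian_weights(lay, normalized = TRUE)
  x <- sin(2 * pi * 7 * seq_len(64) / 512)
  dat <- array(rep(x, each = 8), c(1, 8, 64))
  ep <- new_epochs(dat, 1L, 1L, 512)
  expect_lt(max(abs(apply_laplacian(ep, lw)$data)), 1e-10)
})

test_that("the Laplacian is linear", {
  lw <- laplacian_weights(default_layout())
  set.seed(3)
  X <- new_epochs(array(rnorm(2 * 8 * 30), c(2, 8, 30)), c(1L, 1L),
                  c(1L, 1L), 512)
  Y <- new_epochs(array(rnorm(2 * 8 * 30), c(2, 8, 30)), c(1L, 1L),
                  c(1L, 1L), 512)
  Z <- new_epochs(2 * X$data - 3 * Y$data, c(1L, 1L), c(1L, 1L), 512)
  lhs <- apply_laplacian(Z, lw)$data
  rhs <- 2 * apply_laplacian(X, lw)$data - 3 * apply_laplacian(Y, lw)$data
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("detrending removes lines exactly and is idempotent", {
  t <- seq_len(100)
  dat <- array(0, c(2, 2, 100))
  dat[1, 1, ] <- 7                      # constant
  dat[1, 2, ] <- 3 * t - 50             # ramp
  dat[2, 1, ] <- sin(t / 5) + 0.2 * t
  dat[2, 2, ] <- rnorm(100)
  ep <- new_epochs(dat, c(1L, 1L), c(1L, 1L), 512)
  dt <- detrend(ep)
  expect_lt(max(abs(dt$data[1, 1, ])), 1e-9)
  expect_lt(max(abs(dt$data[1, 2, ])), 1e-9 * max(abs(dat[1, 2, ])))
  expect_equal(detrend(dt)$data, dt$data, tolerance = 1e-9)
  expect_lt(abs(mean(dt$data[2, 1, ])), 1e-10)
})

test_that("the bandpass keeps the passband and rejects DC and 60 Hz", {
  t <- seq_len(538) / 512
  mk <- function(x) new_epochs(array(x, c(1, 1, 538)), 1L, 1L, 512)
  # gain of a probe sinusoid = amplitude of its fitted quadrature pair
  gain_at <- function(f0) {
    y <- as.numeric(bandpass(mk(sin(2 * pi * f0 * t)))$data)
    X <- cbind(sin(2 * pi * f0 * t), cos(2 * pi * f0 * t))
    sqrt(sum(qr.solve(X, y)^2))
  }
  # DC offset suppressed below 1%
  expect_lt(mean(abs(bandpass(mk(rep(1, 538)))$data)), 0.01)
  # 10 Hz passes nearly unattenuated
  expect_gte(gain_at(10), 0.9)
  # 60 Hz is outside the 42.66 Hz edge
  expect_lte(gain_at(60), 0.1)
  expect_error(bandpass(mk(rep(0, 538)), f_low = 50, f_high = 10), "invalid")
})

test_that("filtering and detrending commute on smooth inputs", {
  t <- seq_len(538) / 512
  x <- sin(2 * pi * 9 * t) + 0.4 * cos(2 * pi * 17 * t)
  ep <- new_epochs(array(x, c(1, 1, 538)), 1L, 1L, 512)
  a <- detrend(bandpass(ep))$data
  b <- bandpass(detrend(ep))$data
  expect_equal(a, b, tolerance = 1e-6)
})
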