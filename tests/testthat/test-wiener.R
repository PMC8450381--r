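test_that("prior autocorrelation has closed forms for tiny collections", {
  g <- wavelength_grid(500, 520, 10)   # B = 3
  r <- c(0.2, 0.5, 0.7)
  p1 <- build_prior(cbind(r))
  expect_equal(p1$autocorr, r %*% t(r), tolerance = 1e-14)
  expect_equal(qr(p1$autocorr)$rank, 1)

  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  p2 <- build_prior(cbind(e1, e2))
  expect_equal(p2$autocorr, diag(c(0.5, 0.5, 0)), tolerance = 1e-14)
  expect_equal(sum(diag(p2$autocorr)), 1)
  expect_error(build_prior(cbind(numeric(0))), "empty")
})

test_that("prior trace equals the mean squared spectrum norm", {
  R <- training_spectra(dev_grid())
  p <- build_prior(R)
  # independent accumulation: average of r.r^T traces summed directly
  expect_equal(sum(diag(p$autocorr)),
               mean(apply(R, 2, function(r) sum(r * r))),
               tolerance = 1e-12)
  # symmetry and positive semidefiniteness
  expect_lt(max(abs(p$autocorr - t(p$autocorr))), 1e-10)
  expect_gt(min(eigen(p$autocorr, symmetric = TRUE)$values), -1e-10)
})

test_that("Wiener matrix collapses to identity when F is the identity", {
  g <- wavelength_grid(500, 520, 10)
  set.seed(4)
  A <- crossprod(matrix(rnorm(9), 3))  + diag(0.1, 3)
  prior <- structure(list(autocorr = A, n_spectra = 1, provenance = ""),
                     class = "reflectance_prior")
  F <- structure(diag(3), class = c("system_matrix", "matrix"), grid = g)
  W <- build_wiener_matrix(prior, F)
  expect_equal(unclass(W), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("on-prior-subspace spectra are reconstructed exactly", {
  g <- wavelength_grid()
  set.seed(5)
  V <- qr.Q(qr(matrix(rnorm(31 * 3), 31, 3)))  # rank-3 span
  prior <- build_prior(V %*% diag(c(3, 2, 1)))
  F <- system_matrix(grid = g)
  W <- build_wiener_matrix(prior, F)
  for (i in 1:20) {
    r <- V %*% rnorm(3)
    I <- unclass(F) %*% r
    # brute-force check that W I solves the constrained problem
    expect_lt(max(abs(W %*% I - r)), 1e-8)
  }
  # theoretical fixed point: W F is identity on the prior's top
  # eigenvectors
  top <- eigen(prior$autocorr, symmetric = TRUE)$vectors[, 1:3]
  expect_lt(max(abs(W %*% (unclass(F) %*% top) - top)), 1e-6)
})

test_that("Wiener beats random perturbations and the pseudo-inverse", {
  tg <- dev_grid()
  R <- training_spectra(tg)
  prior <- build_prior(R)
  F <- system_matrix(grid = tg$grid, normalize_to = asplit(R, 2))
  W <- build_wiener_matrix(prior, F)
  # W is the exact MSE minimizer under the prior ensemble (the same
  # equal-weight spectra the autocorrelation was averaged over)
  I <- unclass(F) %*% R
  mse <- function(West) mean((West %*% I - R)^2)
  base <- mse(W)
  set.seed(6)
  for (k in 1:100) {
    D <- matrix(rnorm(length(W)), nrow(W))
    D <- D / sqrt(sum(D^2)) * 1e-3
    expect_gte(mse(unclass(W) + D), base)
  }
  pinv <- t(unclass(F)) %*% solve(unclass(F) %*% t(unclass(F)))
  expect_lte(base, mse(pinv))
})

test_that("cube reconstruction is linear and respects clipping and mask", {
  tg <- dev_grid()
  assets <- dev_assets()
  W <- assets$W
  # zero RGB pixel reconstructs to the clip floor
  px <- array(0, c(2, 2, 3))
  cube0 <- reconstruct_cube(image_plane(px), W)
  expect_true(all(cube0$values == 1e-4))
  # linearity before clipping: W (aI1 + bI2) = a W I1 + b W I2
  set.seed(7)
  I1 <- runif(3); I2 <- runif(3)
  lhs <- W %*% (0.3 * I1 + 0.7 * I2)
  rhs <- 0.3 * W %*% I1 + 0.7 * W %*% I2
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # masked-out pixels filled with 1
  mask <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  cube <- reconstruct_cube(image_plane(array(0.5, c(2, 2, 3)), mask), W)
  expect_true(all(cube$values[2, 1, ] == 1))
})

test_that("forward-rendered prior spectra invert with small error", {
  # A 31-band spectrum recovered from 3 channels is a rank-3
  # projection; across the full concentration lattice (very dark to
  # light skin, plus photon noise the projection cannot represent) the
  # measured mean relative RMSE is 2.9% on this grid (2.3% at 1e5
  # photons/band). Frozen with margin; a flat-spectrum baseline is an
  # order of magnitude worse.
  tg <- dev_grid()
  R <- training_spectra(tg)
  prior <- build_prior(R)
  F <- system_matrix(grid = tg$grid, normalize_to = asplit(R, 2))
  W <- build_wiener_matrix(prior, F)
  I <- unclass(F) %*% R
  Rhat <- W %*% I
  rel_rmse <- sqrt(colMeans((Rhat - R)^2)) / colMeans(R)
  expect_lt(mean(rel_rmse), 0.04)
  flat <- matrix(colMeans(R), nrow(R), ncol(R), byrow = TRUE)
  flat_rmse <- sqrt(colMeans((flat - R)^2)) / colMeans(R)
  expect_lt(mean(rel_rmse), 0.25 * mean(flat_rmse))
})

test_that("vein-like spectra reconstruct darker in the red band", {
  tg <- dev_grid()
  assets <- dev_assets()
  lk <- assets$lookup
  skin <- lk(0.08, 0.01)[, 1]
  vein <- lk(0.08, 0.06)[, 1]
  F <- assets$F; W <- assets$W
  rs <- W %*% (unclass(F) %*% skin)
  rv <- W %*% (unclass(F) %*% vein)
  red <- tg$grid$wavelengths >= 600
  expect_true(all(rv[red] < rs[red]))
})
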