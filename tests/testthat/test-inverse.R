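test_that("absorbance transform is the elementwise negative log10", {
  g <- wavelength_grid()
  r <- spectrum_curve(rep(c(1, 0.1, 0.01), length.out = 31), g,
                      "reflectance")
  A <- to_absorbance(r, g)
  expect_equal(A$values, rep(c(0, 1, 2), length.out = 31),
               tolerance = 1e-12)
  # default restriction to the 500-600 nm sub-grid
  As <- to_absorbance(r)
  expect_equal(As$grid$n_bands, 11)
  expect_equal(As$values, A$values[g$wavelengths >= 500 &
                                     g$wavelengths <= 600])
})

test_that("exact linear absorbance models are recovered perfectly", {
  ch <- chromophore_set()
  sub <- regression_grid()
  X <- veinviz:::absorbance_design(ch, sub)
  A <- spectrum_curve(2 * X[, 1] + 0.5 * X[, 2] + 0.1 * X[, 3] + 0.3, sub)
  cf <- fit_absorbance_regression(A, ch)
  expect_equal(cf$am, 2, tolerance = 1e-8)
  expect_equal(cf$aob, 0.5, tolerance = 1e-8)
  expect_equal(cf$adb, 0.1, tolerance = 1e-8)
  expect_equal(cf$a0, 0.3, tolerance = 1e-8)
  expect_equal(cf$atb, 0.6, tolerance = 1e-8)
  expect_equal(cf$r_squared, 1, tolerance = 1e-9)
  # constant absorbance loads only the intercept
  cc <- fit_absorbance_regression(spectrum_curve(rep(0.7, 11), sub), ch)
  expect_equal(abs(c(cc$am, cc$aob, cc$adb)), rep(0, 3), tolerance = 1e-8)
  expect_equal(cc$a0, 0.7, tolerance = 1e-8)
})

test_that("the spectral fit equals brute-force normal equations", {
  ch <- chromophore_set()
  sub <- regression_grid()
  X <- veinviz:::absorbance_design(ch, sub)
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(11, 1, 0.3)
    cf <- fit_absorbance_regression(spectrum_curve(a, sub), ch)
    beta <- solve(crossprod(X), crossprod(X, a))[, 1]
    expect_lt(max(abs(c(cf$am, cf$aob, cf$adb, cf$a0) - beta)), 1e-9)
  }
})

test_that("the 14-term feature vector is ordered as specified", {
  z <- build_feature_vector(list(am = 0, atb = 0, a0 = 0))
  expect_equal(z, c(1, rep(0, 13)))
  ones <- build_feature_vector(list(am = 1, atb = 1, a0 = 1))
  expect_equal(ones, rep(1, 14))
  two <- build_feature_vector(list(am = 2, atb = 0, a0 = 0))
  expect_equal(two, c(1, 2, 0, 0, 8, rep(0, 9)))
  expect_length(build_feature_vector(list(am = .3, atb = -.2, a0 = 5)), 14)
})

test_that("a linear feature-to-target map is recovered exactly", {
  tg <- dev_grid()
  ch <- chromophore_set(tg$grid)
  # overwrite targets with an exact linear function of the features
  R <- training_spectra(tg)
  sub <- regression_grid()
  idx <- veinviz:::band_index(tg$grid, sub)
  X <- veinviz:::absorbance_design(ch, sub)
  f <- veinviz:::fit_absorbance_matrix(-log10(R[idx, ]), X)
  Feat <- veinviz:::feature_matrix(f$coef[1, ], f$coef[2, ] + f$coef[3, ],
                                   f$coef[4, ])
  b_true <- c(0.02, 300, -200, 0.05, 1e5, -2e4, 0.01, 5e3, 1e4, -50,
              2e3, 80, -3, 7)
  tg2 <- tg
  tg2$pairs$Cm <- as.vector(Feat %*% b_true)
  tg2$pairs$Cb <- as.vector(Feat %*% rev(b_true))
  m <- train_concentration_map(tg2, ch)
  expect_lt(max(abs(Feat %*% m$bm - tg2$pairs$Cm)), 1e-6)
  expect_lt(max(abs(Feat %*% m$btb - tg2$pairs$Cb)), 1e-6)
})

test_that("leave-one-out blood prediction tracks the truth", {
  tg <- dev_grid()
  ch <- chromophore_set(tg$grid)
  R <- training_spectra(tg)
  sub <- regression_grid()
  idx <- veinviz:::band_index(tg$grid, sub)
  X <- veinviz:::absorbance_design(ch, sub)
  f <- veinviz:::fit_absorbance_matrix(-log10(R[idx, ]), X)
  Feat <- veinviz:::feature_matrix(f$coef[1, ], f$coef[2, ] + f$coef[3, ],
                                   f$coef[4, ])
  loo <- vapply(seq_len(nrow(Feat)), function(i) {
    scl <- apply(abs(Feat[-i, ]), 2, max)
    b <- qr.coef(qr(sweep(Feat[-i, ], 2, scl, "/")),
                 tg$pairs$Cb[-i]) / scl
    sum(Feat[i, ] * b)
  }, numeric(1))
  expect_gt(cor(loo, tg$pairs$Cb), 0.95)
  # monotone along every fixed-Cm grid line
  m <- train_concentration_map(tg, ch)
  pred <- as.vector(Feat %*% m$btb)
  for (cm in unique(tg$pairs$Cm)) {
    sel <- tg$pairs$Cm == cm
    expect_gt(cor(pred[sel], tg$pairs$Cb[sel], method = "spearman"), 0.95)
  }
})

test_that("inverse model JSON round-trips", {
  m <- train_concentration_map(dev_grid())
  tmp <- withr::local_tempfile(fileext = ".json")
  write_inverse_model(m, tmp)
  m2 <- read_inverse_model(tmp)
  expect_equal(m2$bm, m$bm, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(m2$btb, m$btb, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(m2$subgrid$wavelengths, m$subgrid$wavelengths)
})

test_that("concentration maps behave on constant and two-region cubes", {
  tg <- dev_grid()
  assets <- dev_assets()
  m <- assets$model
  lk <- assets$lookup
  B <- tg$grid$n_bands
  # constant cube -> spatially constant maps
  r <- lk(0.1, 0.02)[, 1]
  cube <- structure(list(
    values = array(rep(r, each = 12 * 16), c(12, 16, B)),
    grid = tg$grid, mask = matrix(TRUE, 12, 16), n_clipped = 0),
    class = "spectral_cube")
  maps <- predict_concentrations(cube, m)
  expect_lt(sd(maps$Cm_map) / abs(mean(maps$Cm_map)), 1e-6)
  expect_lt(sd(maps$Cb_map) / abs(mean(maps$Cb_map)), 1e-6)
  # uniform round trip: means within 20% of the true fractions
  expect_lt(abs(mean(maps$Cm_map) - 0.1) / 0.1, 0.2)
  expect_lt(abs(mean(maps$Cb_map) - 0.02) / 0.02, 0.2)
  # two-region cube: vein strip at Cb = 5% on 1% background
  rv <- lk(0.1, 0.05)[, 1]
  rb <- lk(0.1, 0.01)[, 1]
  vals <- array(rep(rb, each = 12 * 16), c(12, 16, B))
  for (b in seq_len(B)) vals[5:8, , b] <- rv[b]
  cube2 <- structure(list(values = vals, grid = tg$grid,
                          mask = matrix(TRUE, 12, 16), n_clipped = 0),
                     class = "spectral_cube")
  maps2 <- predict_concentrations(cube2, m)
  expect_gt(mean(maps2$Cb_map[5:8, ]) / mean(maps2$Cb_map[-(5:8), ]), 1.5)
  # untrained model errors
  expect_error(predict_concentrations(cube, list(btb = 1:14)), "untrained")
})

test_that("held-out lattice points rank correctly in blood fraction", {
  tg <- dev_grid()
  assets <- dev_assets()
  lk <- assets$lookup
  ch <- assets$chroms
  m <- assets$model
  # 5x5 lattice strictly inside, offset from the training nodes
  cms <- seq(0.05, 0.35, length.out = 5)
  cbs <- seq(0.005, 0.06, length.out = 5)
  des <- expand.grid(Cm = cms, Cb = cbs)
  R <- lk(des$Cm, des$Cb)
  idx <- veinviz:::band_index(tg$grid, m$subgrid)
  X <- veinviz:::absorbance_design(ch, m$subgrid)
  f <- veinviz:::fit_absorbance_matrix(-log10(R[idx, ]), X)
  Feat <- veinviz:::feature_matrix(f$coef[1, ], f$coef[2, ] + f$coef[3, ],
                                   f$coef[4, ])
  pred <- as.vector(Feat %*% m$btb)
  expect_gt(cor(pred, des$Cb, method = "spearman"), 0.9)
})

test_that("the 500-600 nm fit beats the full-range fit on MC spectra", {
  tg <- dev_grid()
  ch <- chromophore_set(tg$grid)
  R <- training_spectra(tg)
  sub <- regression_grid()
  idx <- veinviz:::band_index(tg$grid, sub)
  Xs <- veinviz:::absorbance_design(ch, sub)
  fs <- veinviz:::fit_absorbance_matrix(-log10(R[idx, ]), Xs)
  Xf <- veinviz:::absorbance_design(ch, tg$grid)
  ff <- veinviz:::fit_absorbance_matrix(-log10(R), Xf)
  expect_gt(mean(fs$r2), mean(ff$r2))
})
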