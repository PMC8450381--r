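#' Reflectance to absorbance
#'
#' `A(lambda) = -log10 r(lambda)`, restricted to the regression sub-grid.
#'
#' @param r reflectance `spectrum_curve` (values in (0, 1]).
#' @param subgrid target [wavelength_grid()]; default the 500--600 nm
#'   regression band. Use `r$grid` to keep the full range.
#' @return A `spectrum_curve` of role `"generic"` holding absorbance.
#' @export
to_absorbance <- function(r, subgrid = regression_grid()) {
  if (any(r$values <= 0)) stop("reflectance must be positive (pre-clip)")
  rs <- subset_spectrum(r, subgrid)
  spectrum_curve(-log10(rs$values), subgrid, "generic")
}

# design matrix [eps_m, eps_ob, eps_db, 1] on a sub-grid
absorbance_design <- function(chroms, subgrid) {
  X <- cbind(
    subset_spectrum(chroms$eps_melanin, subgrid)$values,
    subset_spectrum(chroms$eps_oxy, subgrid)$values,
    subset_spectrum(chroms$eps_deoxy, subgrid)$values,
    1)
  colnames(X) <- c("eps_m", "eps_ob", "eps_db", "intercept")
  X
}

#' Modified Beer-Lambert regression of one absorbance spectrum
#'
#' Ordinary least squares of `A(lambda)` on the melanin, oxyhemoglobin
#' and deoxyhemoglobin extinction curves plus an intercept. The
#' coefficients absorb the (unknown) mean photon path lengths; the
#' intercept absorbs scattering loss and minor chromophores.
#'
#' @param A absorbance `spectrum_curve` (from [to_absorbance()]).
#' @param chroms a [chromophore_set()] on the full working grid (it is
#'   resampled to `A`'s grid internally).
#' @return List of class `mbl_coefficients`: `am`, `aob`, `adb`, `a0`,
#'   `atb` (`= aob + adb`), `r_squared`.
#' @export
fit_absorbance_regression <- function(A, chroms) {
  if (A$grid$n_bands < 4) stop("need >= 4 bands to fit 4 parameters")
  X <- absorbance_design(chroms, A$grid)
  out <- fit_absorbance_matrix(cbind(A$values), X)
  cf <- unname(out$coef[, 1])
  structure(list(am = cf[1], aob = cf[2], adb = cf[3], a0 = cf[4],
                 atb = cf[2] + cf[3], r_squared = unname(out$r2[1])),
            class = "mbl_coefficients")
}

# Vectorized least squares: Amat is n_bands x N (one spectrum per column).
# Returns 4 x N coefficients and per-column R^2.
fit_absorbance_matrix <- function(Amat, X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("collinear extinction design; minimum-norm solution used")
    P <- MASS_ginv(X)
    coef <- P %*% Amat
  } else {
    coef <- qr.coef(qrX, Amat)
  }
  fitted <- X %*% coef
  res <- Amat - fitted
  ssres <- colSums(res^2)
  sstot <- colSums(sweep(Amat, 2, colMeans(Amat))^2)
  r2 <- ifelse(sstot > 0, 1 - ssres / sstot, 1)
  list(coef = coef, r2 = pmin(pmax(r2, 0), 1))
}

# Moore-Penrose pseudoinverse via SVD (degenerate-design fallback only).
MASS_ginv <- function(X, tol = 1e-10) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' The 14-term polynomial feature vector
#'
#' `[1, am, atb, a0, am^3, atb^3, a0^3, am*atb*a0, am^2*atb, am^2*a0,
#' atb^2*am, atb^2*a0, a0^2*am, a0^2*atb]` -- the regressors of the
#' coefficient-to-concentration map.
#'
#' @param coefs an `mbl_coefficients` (or any list with `am`, `atb`, `a0`).
#' @return Numeric vector of length 14.
#' @export
build_feature_vector <- function(coefs) {
  feature_matrix(coefs$am, coefs$atb, coefs$a0)[1, ]
}

# vectorized: N x 14 matrix
feature_matrix <- function(am, atb, a0) {
  cbind(1, am, atb, a0, am^3, atb^3, a0^3, am * atb * a0,
        am^2 * atb, am^2 * a0, atb^2 * am, atb^2 * a0,
        a0^2 * am, a0^2 * atb,
        deparse.level = 0)
}

#' Train the coefficient-to-concentration map
#'
#' For every training pair the absorbance spectrum is fitted by the
#' modified Beer-Lambert regression on the sub-grid; the resulting
#' `(am, atb, a0)` are expanded into the 14-term cubic feature vector,
#' and two least-squares problems give the weight vectors `bm` and `btb`
#' mapping features to `Cm` and `Cb` (volume fractions).
#'
#' @param tg a [build_training_grid()] result.
#' @param chroms a [chromophore_set()].
#' @param subgrid regression sub-grid (default 500--600 nm at 10 nm).
#' @param ridge diagonal loading used only if the feature Gram matrix is
#'   numerically singular.
#' @return Object of class `inverse_model`: `bm`, `btb` (length-14),
#'   `subgrid`, in-sample `rmse_cm`, `rmse_cb`, mean `r_squared` of the
#'   spectral fits, and provenance.
#' @export
train_concentration_map <- function(tg, chroms = chromophore_set(tg$grid),
                                    subgrid = regression_grid(),
                                    ridge = 1e-10) {
  R <- training_spectra(tg)
  idx <- band_index(tg$grid, subgrid)
  Amat <- -log10(R[idx, , drop = FALSE])
  X <- absorbance_design(chroms, subgrid)
  fit <- fit_absorbance_matrix(Amat, X)
  am <- fit$coef[1, ]; atb <- fit$coef[2, ] + fit$coef[3, ]
  a0 <- fit$coef[4, ]
  Feat <- feature_matrix(am, atb, a0)
  if (nrow(Feat) < 14) stop("need >= 14 training pairs")
  # column equilibration: exact reparametrization that keeps the raw
  # cubic features (whose magnitudes span ~15 decades) solvable by QR
  scl <- apply(abs(Feat), 2, max)
  scl[scl == 0] <- 1
  Fs <- sweep(Feat, 2, scl, "/")
  qrF <- qr(Fs)
  if (qrF$rank < ncol(Fs)) {
    warning("degenerate feature spread; ridge fallback")
    G <- crossprod(Fs) + diag(ridge, ncol(Fs))
    bm <- solve(G, crossprod(Fs, tg$pairs$Cm))[, 1] / scl
    btb <- solve(G, crossprod(Fs, tg$pairs$Cb))[, 1] / scl
  } else {
    bm <- qr.coef(qrF, tg$pairs$Cm) / scl
    btb <- qr.coef(qrF, tg$pairs$Cb) / scl
  }
  pm <- Feat %*% bm; pb <- Feat %*% btb
  structure(list(
    bm = bm, btb = btb, subgrid = subgrid,
    rmse_cm = sqrt(mean((pm - tg$pairs$Cm)^2)),
    rmse_cb = sqrt(mean((pb - tg$pairs$Cb)^2)),
    mean_r_squared = mean(fit$r2),
    n_pairs = nrow(tg$pairs),
    provenance = sprintf("%dx%d MC grid, %g photons/band, seed %g",
                         tg$n_m, tg$n_b, tg$config$n_photons,
                         tg$config$seed),
    fixture_hashes = tryCatch({
      files <- c("extinction_melanin.csv", "extinction_hbo2.csv",
                 "extinction_hb.csv")
      h <- tools::md5sum(vapply(files, veinviz_extdata, character(1)))
      as.list(stats::setNames(unname(h), files))
    }, error = function(e) NULL)),
    class = "inverse_model")
}

#' Save / load a trained inverse model as JSON
#' @param model an `inverse_model`.
#' @param path JSON file path.
#' @export
write_inverse_model <- function(model, path) {
  m <- unclass(model)
  m$subgrid <- m$subgrid[c("start_nm", "stop_nm", "step_nm")]
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_inverse_model
#' @return An `inverse_model`.
#' @export
read_inverse_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$subgrid <- wavelength_grid(m$subgrid$start_nm, m$subgrid$stop_nm,
                               m$subgrid$step_nm)
  structure(m, class = "inverse_model")
}

#' Per-pixel chromophore concentration maps
#'
#' Applies the two-stage inverse to every masked pixel of a reflectance
#' cube: absorbance on the model's sub-grid, modified Beer-Lambert fit,
#' cubic feature expansion, dot products with `bm` and `btb`.
#'
#' @param cube a [reconstruct_cube()] result (or any `spectral_cube`).
#' @param model a trained [train_concentration_map()] result.
#' @param chroms a [chromophore_set()] on the cube grid.
#' @param clip optional length-2 lists `list(cm = c(lo, hi), cb = ...)`
#'   soft display clip; default NULL leaves predictions unclipped so
#'   out-of-range values keep their vein contrast.
#' @return Object of class `concentration_map`: `Cm_map`, `Cb_map`
#'   (H x W, NA outside the mask), `mask`, `model`.
#' @export
predict_concentrations <- function(cube, model,
                                   chroms = chromophore_set(cube$grid),
                                   clip = NULL) {
  if (is.null(model$bm)) stop("untrained inverse model")
  idx <- band_index(cube$grid, model$subgrid)
  d <- dim(cube$values)
  m <- matrix(cube$values, ncol = d[3])     # Npix x B
  on <- as.vector(cube$mask)
  Amat <- -log10(t(m[on, idx, drop = FALSE]))  # bands x Non
  X <- absorbance_design(chroms, model$subgrid)
  fit <- fit_absorbance_matrix(Amat, X)
  Feat <- feature_matrix(fit$coef[1, ], fit$coef[2, ] + fit$coef[3, ],
                         fit$coef[4, ])
  cm <- as.vector(Feat %*% model$bm)
  cb <- as.vector(Feat %*% model$btb)
  if (!is.null(clip)) {
    if (!is.null(clip$cm)) cm <- pmin(pmax(cm, clip$cm[1]), clip$cm[2])
    if (!is.null(clip$cb)) cb <- pmin(pmax(cb, clip$cb[1]), clip$cb[2])
  }
  Cm_map <- matrix(NA_real_, d[1], d[2]); Cb_map <- Cm_map
  Cm_map[on] <- cm; Cb_map[on] <- cb
  structure(list(Cm_map = Cm_map, Cb_map = Cb_map, mask = cube$mask,
                 model = model), class = "concentration_map")
}
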