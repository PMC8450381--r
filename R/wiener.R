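#' Camera-illuminant system matrix
#'
#' The 3 x B forward color-formation matrix `F = S E`: rows are the R, G,
#' B camera response curves, `E` the diagonal illuminant. An optional
#' normalization rescales `F` so the brightest spectrum of a reference
#' collection maps to a maximum channel value of 1.
#'
#' @param camera 3 x B response matrix (rows R, G, B) or NULL to use the
#'   bundled model.
#' @param illuminant `spectrum_curve` or NULL for bundled D65.
#' @param grid working [wavelength_grid()].
#' @param normalize_to optional list of `spectrum_curve`s (or numeric
#'   vectors) used to set the exposure scale.
#' @param gain extra scalar gain applied after normalization.
#' @return 3 x B matrix of class `system_matrix` with the grid attached.
#' @export
system_matrix <- function(camera = NULL, illuminant = NULL,
                          grid = wavelength_grid(), normalize_to = NULL,
                          gain = 1) {
  if (is.null(camera) || is.null(illuminant)) {
    ci <- camera_illuminant(grid)
    if (is.null(camera)) camera <- ci$camera
    if (is.null(illuminant)) illuminant <- ci$illuminant
  }
  Evals <- if (inherits(illuminant, "spectrum_curve")) illuminant$values
           else as.numeric(illuminant)
  if (ncol(camera) != grid$n_bands || length(Evals) != grid$n_bands)
    stop("camera/illuminant dimensions do not match the grid")
  F <- camera %*% diag(Evals)
  if (qr(F)$rank < 3) stop("system matrix is rank deficient")
  if (!is.null(normalize_to)) {
    R <- spectra_matrix(normalize_to, grid)
    F <- F / max(F %*% R)
  }
  F <- F * gain
  rownames(F) <- c("R", "G", "B")
  structure(F, class = c("system_matrix", "matrix"), grid = grid)
}

# collection of spectrum_curve (or numeric vectors) -> B x N matrix
spectra_matrix <- function(spectra, grid = NULL) {
  cols <- lapply(spectra, function(s) {
    v <- if (inherits(s, "spectrum_curve")) s$values else as.numeric(s)
    if (!is.null(grid) && length(v) != grid$n_bands)
      stop("spectrum length does not match grid")
    v
  })
  do.call(cbind, cols)
}

#' Reflectance second-moment prior
#'
#' Averages the outer product r r^T over a collection of reflectance
#' spectra. This is the
#' only prior knowledge the Wiener estimator needs.
#'
#' @param spectra list of `spectrum_curve`s or numeric vectors on a common
#'   grid, or a B x N matrix of spectra in columns.
#' @param provenance free-text description of the spectra set.
#' @return Object of class `reflectance_prior` with fields `autocorr`
#'   (B x B symmetric PSD matrix), `n_spectra`, `provenance`.
#' @export
build_prior <- function(spectra, provenance = "unspecified") {
  R <- if (is.matrix(spectra)) spectra else spectra_matrix(spectra)
  if (is.null(R) || ncol(R) == 0 || nrow(R) == 0)
    stop("empty spectra collection")
  A <- tcrossprod(R) / ncol(R)
  A <- (A + t(A)) / 2
  structure(list(autocorr = A, n_spectra = ncol(R),
                 provenance = provenance), class = "reflectance_prior")
}

#' Wiener spectral-reconstruction matrix
#'
#' `W = <rr^T> F^T (F <rr^T> F^T)^-1`, the linear minimum-mean-squared-
#' error estimator of a B-band reflectance spectrum from an RGB triplet.
#'
#' @param prior a [build_prior()] result.
#' @param F a [system_matrix()].
#' @param ridge diagonal loading added to the 3 x 3 Gram matrix when it is
#'   numerically singular (with a warning).
#' @return B x 3 matrix of class `wiener_matrix`.
#' @export
build_wiener_matrix <- function(prior, F, ridge = 1e-10) {
  A <- prior$autocorr
  G <- F %*% A %*% t(F)
  if (!is.finite(rcond(G)) || rcond(G) < 1e-12) {
    warning("singular camera Gram matrix; applying ridge regularization")
    G <- G + diag(ridge * mean(diag(G)), 3)
  }
  W <- A %*% t(F) %*% solve(G)
  structure(W, class = c("wiener_matrix", "matrix"), grid = attr(F, "grid"))
}

#' Reconstruct a spectral reflectance cube from an RGB image
#'
#' Applies the estimator (reflectance = W I) per pixel and clips to
#' `(clip_floor, 1]`. Masked-out
#' pixels are filled with reflectance 1.
#'
#' @param rgb RGB [image_plane()] on the same intensity convention as the
#'   `F` used to build `W` (use `gain` for a per-image exposure factor).
#' @param W a [build_wiener_matrix()] result.
#' @param gain scalar exposure gain: the RGB values are divided by `gain`
#'   before reconstruction.
#' @param clip_floor lower reflectance clip (the inverse model takes logs).
#' @return List of class `spectral_cube`: `values` (H x W x B array),
#'   `grid`, `mask`, `n_clipped` (count of out-of-range reconstructions).
#' @export
reconstruct_cube <- function(rgb, W, gain = 1, clip_floor = 1e-4) {
  if (!is_rgb(rgb)) stop("reconstruct_cube needs an RGB image")
  B <- nrow(W)
  d <- dim(rgb$pixels)
  I <- rbind(as.vector(rgb$pixels[, , 1]), as.vector(rgb$pixels[, , 2]),
             as.vector(rgb$pixels[, , 3])) / (rgb$value_range[2] * gain)
  Rhat <- W %*% I                       # B x Npix
  n_clipped <- sum(Rhat < clip_floor | Rhat > 1)
  Rhat <- pmin(pmax(Rhat, clip_floor), 1)
  off <- !as.vector(rgb$mask)
  if (any(off)) {
    m <- t(Rhat)
    m[off, ] <- 1
    cube <- array(m, c(d[1], d[2], B))
  } else {
    cube <- array(t(Rhat), c(d[1], d[2], B))
  }
  structure(list(values = cube, grid = attr(W, "grid"), mask = rgb$mask,
                 n_clipped = n_clipped), class = "spectral_cube")
}

#' Render RGB from reflectance spectra
#'
#' Forward color formation `I = F r`, the counterpart of
#' [reconstruct_cube()]; used by the phantom generator and in tests.
#'
#' @param spectra B x N matrix (spectra in columns), a single
#'   `spectrum_curve`, or a list of them.
#' @param F a [system_matrix()].
#' @return 3 x N matrix of RGB triplets.
#' @export
render_rgb <- function(spectra, F) {
  R <- if (is.matrix(spectra)) spectra
       else if (inherits(spectra, "spectrum_curve")) cbind(spectra$values)
       else spectra_matrix(spectra)
  unclass(F) %*% R
}
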