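#' Image plane with a skin mask
#'
#' Thin wrapper around an `H x W` (scalar) or `H x W x 3` (RGB) numeric
#' array plus a logical skin mask. All region-dependent statistics (gamma
#' estimation, shading means, Otsu thresholds) are computed over the mask.
#'
#' @param pixels numeric matrix or 3-band array.
#' @param mask logical `H x W` matrix, `TRUE` = skin; default all `TRUE`.
#' @param value_range declared pixel domain, `c(0, 1)` or `c(0, 255)`.
#' @return An object of class `image_plane`.
#' @export
image_plane <- function(pixels, mask = NULL, value_range = c(0, 1)) {
  if (!(length(dim(pixels)) %in% c(2, 3)))
    stop("pixels must be H x W or H x W x 3")
  if (length(dim(pixels)) == 3 && dim(pixels)[3] != 3)
    stop("multi-band images must have exactly 3 bands")
  if (any(!is.finite(pixels))) stop("pixels must be finite")
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  if (!is.logical(mask) || !all(dim(mask) == c(H, W)))
    stop("mask must be a logical H x W matrix")
  lo <- value_range[1] - 1e-9; hi <- value_range[2] + 1e-9
  if (min(pixels) < lo || max(pixels) > hi)
    stop("pixels outside declared value_range")
  structure(list(pixels = pixels, mask = mask, value_range = value_range),
            class = "image_plane")
}

#' @export
print.image_plane <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_plane %dx%d%s, range [%g,%g], %d masked-in px>\n",
              d[1], d[2], if (length(d) == 3) "x3" else "",
              x$value_range[1], x$value_range[2], sum(x$mask)))
  invisible(x)
}

is_rgb <- function(im) length(dim(im$pixels)) == 3

# luminance in [0,1] regardless of declared range
to_gray01 <- function(im) {
  p <- im$pixels / im$value_range[2]
  if (is_rgb(im)) 0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
  else p
}

#' Entropy-optimal gamma exponent
#'
#' Closed-form restoration exponent `gamma* = -1 / mean(ln u)` over the
#' masked gray-scale pixels `u` in (0, 1]. This is the exponent that
#' maximizes the (differential) entropy of the power-transformed image, so
#' under- or over-exposed images are pulled back toward a full tonal
#' range. Zero pixels are clamped to a small floor (1/255) before the log.
#'
#' @param image an [image_plane()].
#' @param floor clamp applied before the logarithm (on the 0--1 scale).
#' @return Positive scalar `gamma*`.
#' @export
estimate_gamma <- function(image, floor = 1 / 255) {
  if (!any(image$mask)) stop("empty skin region")
  u <- to_gray01(image)[image$mask]
  u <- pmin(pmax(u, floor), 1)
  m <- mean(log(u))
  if (m > -1e-12)
    stop("degenerate image: all pixels at white point, gamma* unbounded")
  -1 / m
}

#' Apply a gamma exponent to every channel
#'
#' @param image an [image_plane()]; pixels are normalized to `[0, 1]`,
#'   raised elementwise to `gamma` (same exponent on all channels), and
#'   returned in the original declared range.
#' @param gamma positive exponent.
#' @return An `image_plane`.
#' @export
apply_gamma <- function(image, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be a positive scalar")
  hi <- image$value_range[2]
  image_plane((image$pixels / hi)^gamma * hi, image$mask, image$value_range)
}

#' Bilateral filter standard deviations
#'
#' Spatial sigma is 5% of the smaller image dimension; range sigma is 5%
#' of the maximum masked value of the current filter input.
#'
#' @param image an [image_plane()] (scalar or RGB): the current filter
#'   input.
#' @return Named vector `c(sigma1 = ..., sigma2 = ...)` (pixels, intensity
#'   units).
#' @export
bilateral_sigmas <- function(image) {
  d <- dim(image$pixels)
  sigma1 <- 0.05 * min(d[2], d[1])  # min(width, height)
  vals <- if (is_rgb(image)) {
    apply(image$pixels, 3, function(ch) max(ch[image$mask]))
  } else max(image$pixels[image$mask])
  c(sigma1 = sigma1, sigma2 = 0.05 * max(vals))
}

#' Shading removal by iterated bilateral decomposition
#'
#' Works per channel in the log domain. The image is scaled to
#' `[0, 255]` and floored at 1, the log image is filtered `n_iter` times
#' with an edge-preserving bilateral filter (sigmas recomputed from the
#' current filter input each pass, see [bilateral_sigmas()]) to isolate
#' the smooth illumination-and-geometry layer; the remaining
#' high-frequency detail carries the pigment structure. The corrected
#' image keeps the detail layer and restores the global mean of the base
#' layer over the skin region as a flat base color.
#'
#' @param image RGB or scalar [image_plane()].
#' @param n_iter number of bilateral passes (>= 1).
#' @return A list of class `shading_decomposition`: `base_log`,
#'   `detail_log` (log-domain layers on the 0--255 scale) and `corrected`
#'   (an `image_plane` in the input's declared range). Masked-out pixels
#'   pass through untouched.
#' @export
remove_shading <- function(image, n_iter = 5) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (!any(image$mask)) stop("empty skin region")
  hi <- image$value_range[2]
  px <- image$pixels * (255 / hi)
  px <- pmax(px, 1)                       # floor before the log
  nb <- if (is_rgb(image)) 3L else 1L
  dims <- dim(image$pixels)
  get_ch <- function(k) if (nb == 3L) px[, , k] else px
  base_log <- array(NA_real_, c(dims[1], dims[2], nb))
  detail_log <- array(NA_real_, c(dims[1], dims[2], nb))
  corrected <- array(NA_real_, c(dims[1], dims[2], nb))
  sigma1 <- 0.05 * min(dims[1], dims[2])
  for (k in seq_len(nb)) {
    L <- log(get_ch(k))
    base <- L
    for (it in seq_len(n_iter)) {
      sigma2 <- 0.05 * max(base[image$mask])
      base <- .bilateral_filter(base, sigma1, sigma2)
    }
    det <- L - base
    corr_log <- det + mean(base[image$mask])
    corr <- exp(corr_log)
    corr[!image$mask] <- (get_ch(k))[!image$mask]
    base_log[, , k] <- base
    detail_log[, , k] <- det
    corrected[, , k] <- pmin(pmax(corr, 0), 255)
  }
  if (nb == 1L) {
    base_log <- base_log[, , 1]; detail_log <- detail_log[, , 1]
    corrected <- corrected[, , 1]
  }
  structure(list(
    base_log = base_log, detail_log = detail_log,
    corrected = image_plane(corrected * (hi / 255), image$mask,
                            image$value_range)),
    class = "shading_decomposition")
}
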