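#' Oriented Gabor filter bank
#'
#' Real (even-symmetric) parts of Gabor kernels over a set of scales and
#' orientations; the default 2 scales x 8 orientations = 16 filters.
#' Kernels are zero-mean so a flat image gives zero response.
#'
#' @param sigmas Gaussian envelope scales in pixels.
#' @param n_theta number of orientations, evenly spaced over `[0, pi)`.
#' @param wavelength_factor carrier wavelength as a multiple of sigma.
#' @param gamma_aspect envelope aspect ratio (< 1 elongates the kernel
#'   along the line direction).
#' @return List of class `gabor_bank`; each element has the kernel matrix
#'   and its `sigma`, `theta`, `wavelength`.
#' @export
gabor_bank <- function(sigmas = c(2, 4), n_theta = 8,
                       wavelength_factor = 4, gamma_aspect = 0.5) {
  thetas <- seq(0, pi, length.out = n_theta + 1)[seq_len(n_theta)]
  bank <- list()
  for (s in sigmas) {
    half <- ceiling(3 * s)
    xs <- seq(-half, half)
    gridxy <- expand.grid(x = xs, y = xs)
    lam <- wavelength_factor * s
    for (th in thetas) {
      xr <- gridxy$x * cos(th) + gridxy$y * sin(th)
      yr <- -gridxy$x * sin(th) + gridxy$y * cos(th)
      k <- exp(-(xr^2 + gamma_aspect^2 * yr^2) / (2 * s^2)) *
        cos(2 * pi * xr / lam)
      k <- matrix(k, length(xs), length(xs))
      k <- k - mean(k)
      bank[[length(bank) + 1]] <-
        list(kernel = k, sigma = s, theta = th, wavelength = lam)
    }
  }
  structure(bank, class = "gabor_bank")
}

#' Extract a binary vein mask from a scalar visualization image
#'
#' Pipeline: per-filter convolution with the bank, maximum response over
#' the bank, contrast stretch over the skin region, Otsu binarization and
#' small-component removal. Veins are assumed darker than background (set
#' `dark_veins = FALSE` for bright-vein inputs such as raw blood maps).
#'
#' @param image scalar [image_plane()] (e.g. inverted blood map or NIR).
#' @param bank a [gabor_bank()].
#' @param dark_veins logical; TRUE when veins are darker than skin.
#' @param min_component_px connected components smaller than this are
#'   dropped.
#' @return Logical H x W matrix of class `vein_mask` (vein pixels inside
#'   the skin region only).
#' @export
extract_veins <- function(image, bank = gabor_bank(), dark_veins = TRUE,
                          min_component_px = 50) {
  if (is_rgb(image)) stop("extract_veins needs a scalar image")
  if (!any(image$mask)) stop("empty skin region")
  x <- image$pixels / image$value_range[2]
  if (dark_veins) x <- 1 - x          # line detectors respond to ridges
  resp <- NULL
  for (f in bank) {
    r <- EBImage::filter2(x, f$kernel, boundary = "replicate")
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  v <- resp[image$mask]
  rng <- range(v)
  if (diff(rng) < 1e-12) {
    out <- matrix(FALSE, nrow(x), ncol(x))
    class(out) <- c("vein_mask", class(out))
    return(out)
  }
  stretched <- (resp - rng[1]) / diff(rng)
  stretched[stretched < 0] <- 0; stretched[stretched > 1] <- 1
  thr <- otsu_threshold(stretched[image$mask])
  bin <- stretched > thr & image$mask
  # drop small components
  lab <- EBImage::bwlabel(bin)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= min_component_px)
    bin <- matrix(lab %in% keep, nrow(bin), ncol(bin))
  }
  out <- bin & image$mask
  class(out) <- c("vein_mask", class(out))
  out
}

# Otsu threshold of a value vector in [0,1] (region-restricted; 256 bins)
otsu_threshold <- function(v, n_bins = 256) {
  h <- tabulate(pmin(pmax(floor(v * n_bins) + 1, 1), n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  mids[which.max(sb2)]
}

#' Score a predicted vein mask against ground truth
#'
#' Pixelwise confusion counts over the valid skin region and the four
#' derived metrics: accuracy, precision, recall and F1. Ratios with a
#' zero denominator are returned as 0 and flagged in `undefined`.
#'
#' @param pred,truth logical vein masks of identical dimensions.
#' @param valid logical matrix of pixels to score (default: everywhere).
#' @return List of class `vein_score`: `TP`, `FP`, `FN`, `TN`,
#'   `accuracy`, `precision`, `recall`, `f1`, `undefined` (character
#'   vector of metric names whose denominator was zero).
#' @export
score_veins <- function(pred, truth, valid = NULL) {
  if (!all(dim(pred) == dim(truth))) stop("mask dimensions differ")
  if (is.null(valid)) valid <- matrix(TRUE, nrow(pred), ncol(pred))
  p <- as.vector(pred)[as.vector(valid)]
  t <- as.vector(truth)[as.vector(valid)]
  confusion_metrics(TP = sum(p & t), FP = sum(p & !t),
                    FN = sum(!p & t), TN = sum(!p & !t))
}

#' Metrics from raw confusion counts
#' @param TP,FP,FN,TN nonnegative pixel counts.
#' @return Same structure as [score_veins()].
#' @export
confusion_metrics <- function(TP, FP, FN, TN) {
  undef <- character()
  div <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); 0 } else num / den
  }
  precision <- div(TP, TP + FP, "precision")
  recall <- div(TP, TP + FN, "recall")
  f1 <- div(2 * precision * recall, precision + recall, "f1")
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                 accuracy = (TP + TN) / (TP + TN + FP + FN),
                 precision = precision, recall = recall, f1 = f1,
                 undefined = undef), class = "vein_score")
}

#' @export
print.vein_score <- function(x, ...) {
  cat(sprintf(
    "<vein_score TP=%d FP=%d FN=%d TN=%d acc=%.4f P=%.4f R=%.4f F1=%.4f>\n",
    x$TP, x$FP, x$FN, x$TN, x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}
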