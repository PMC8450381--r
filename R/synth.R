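#' Phantom specification
#'
#' Describes a synthetic skin image with known ground truth: uniform
#' background chromophore levels with optional spatial noise, tube-shaped
#' veins of elevated blood fraction, multiplicative shading, acquisition
#' gamma and sensor noise. Rendering a spec is fully determined by `seed`.
#'
#' @param width,height image size in pixels.
#' @param bg_cm,bg_cb background melanin / blood volume fractions.
#' @param noise_cm,noise_cb standard deviation of smooth spatial
#'   variation added to the background fields.
#' @param veins list of vein descriptors, each a list with `width` (px)
#'   and `cb_elevation` (added blood fraction inside the tube). Centerline
#'   geometry is a smooth random walk drawn from `seed`.
#' @param shading `"none"`, `"ramp"` (linear left-right) or `"spotlight"`
#'   (centered Gaussian falloff).
#' @param shading_amplitude fractional depth of the shading field
#'   (0 = flat, 0.4 = darkest pixel 40% below brightest).
#' @param gamma_true acquisition gamma distortion; the rendered image is
#'   raised to `1/gamma_true`.
#' @param sensor_sigma additive Gaussian sensor noise, digital numbers on
#'   the 0--255 scale.
#' @param auto_expose target geometric mean of the gray image before
#'   gamma distortion (camera auto-exposure emulation). The default
#'   `exp(-1)` is the exposure at which the entropy-optimal restoration
#'   exponent is 1, so a distortion-free phantom needs no correction.
#'   Set to 0 to disable.
#' @param seed integer seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 128, height = 96, bg_cm = 0.08,
                         bg_cb = 0.012, noise_cm = 0.004,
                         noise_cb = 0.0015,
                         veins = list(list(width = 6, cb_elevation = 0.03)),
                         shading = c("ramp", "none", "spotlight"),
                         shading_amplitude = 0.35, gamma_true = 0.7,
                         sensor_sigma = 1.5, auto_expose = exp(-1),
                         seed = 1) {
  shading <- match.arg(shading)
  for (v in veins)
    if (v$cb_elevation <= 0) stop("vein cb_elevation must be > 0")
  structure(list(width = width, height = height, bg_cm = bg_cm,
                 bg_cb = bg_cb, noise_cm = noise_cm, noise_cb = noise_cb,
                 veins = veins, shading = shading,
                 shading_amplitude = shading_amplitude,
                 gamma_true = gamma_true, sensor_sigma = sensor_sigma,
                 auto_expose = auto_expose, seed = seed),
            class = "phantom_spec")
}

#' A batch of phantom specs under varying illumination
#'
#' The standard evaluation batch: `n` synthetic subjects photographed
#' under illumination of varying quality. Illumination severity is a
#' single latent factor: the worst-lit capture is both dim (acquisition
#' gamma 0.5 -- median skin brightness about 1/8 of full scale, dimmer
#' captures being quantization-ruined for any method) and strongly
#' shaded (ramp depth 0.5); the best is well exposed (gamma 1.0) with
#' mild shading (depth 0.2). Per-subject vein geometry and noise come
#' from `seed_base + i`.
#'
#' @param n number of phantoms.
#' @param seed_base offset for per-phantom seeds.
#' @param ... overrides forwarded to every [phantom_spec()] call.
#' @return List of `phantom_spec`s.
#' @export
phantom_batch <- function(n = 10, seed_base = 0, ...) {
  gammas <- seq(0.5, 1.0, length.out = n)
  depths <- seq(0.5, 0.2, length.out = n)
  lapply(seq_len(n), function(i) {
    phantom_spec(gamma_true = gammas[i], shading_amplitude = depths[i],
                 seed = seed_base + i, ...)
  })
}

#' Read / write a phantom spec as YAML
#' @param spec a `phantom_spec`.
#' @param path YAML file path.
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path, precision = 15)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @return A `phantom_spec`.
#' @export
read_phantom_spec <- function(path) {
  do.call(phantom_spec, yaml::read_yaml(path))
}

# smooth spatial noise field (H x W), unit sd, from current RNG state
smooth_noise <- function(H, W, blur_sigma = 6) {
  z <- matrix(stats::rnorm(H * W), H, W)
  k <- outer(stats::dnorm(seq(-3, 3, length.out = 2 * blur_sigma + 1)),
             stats::dnorm(seq(-3, 3, length.out = 2 * blur_sigma + 1)))
  z <- EBImage::filter2(z, k / sum(k), boundary = "replicate")
  s <- stats::sd(z)
  if (s > 0) z / s else z
}

#' Reflectance lookup table from a training grid
#'
#' Per-band bilinear interpolation over the `(Cm, Cb)` simulation grid:
#' the fast forward model used by the phantom renderer.
#'
#' @param tg a [build_training_grid()] result.
#' @return A function `f(cm, cb)` mapping equal-length concentration
#'   vectors to a B x N reflectance matrix. Queries outside the grid hull
#'   raise an extrapolation error.
#' @export
reflectance_lookup <- function(tg) {
  cms <- sort(unique(tg$pairs$Cm)); cbs <- sort(unique(tg$pairs$Cb))
  B <- tg$grid$n_bands
  R <- array(NA_real_, c(length(cms), length(cbs), B))
  im <- match(tg$pairs$Cm, cms); ib <- match(tg$pairs$Cb, cbs)
  Rmat <- training_spectra(tg)            # B x N
  for (k in seq_len(nrow(tg$pairs))) R[im[k], ib[k], ] <- Rmat[, k]
  if (any(is.na(R))) stop("training grid is not a complete lattice")
  function(cm, cb) {
    if (any(cm < cms[1] - 1e-12) || any(cm > cms[length(cms)] + 1e-12) ||
        any(cb < cbs[1] - 1e-12) || any(cb > cbs[length(cbs)] + 1e-12))
      stop("concentration outside the lookup hull")
    cm <- pmin(pmax(cm, cms[1]), cms[length(cms)])
    cb <- pmin(pmax(cb, cbs[1]), cbs[length(cbs)])
    i <- pmin(findInterval(cm, cms), length(cms) - 1)
    j <- pmin(findInterval(cb, cbs), length(cbs) - 1)
    u <- (cm - cms[i]) / (cms[i + 1] - cms[i])
    v <- (cb - cbs[j]) / (cbs[j + 1] - cbs[j])
    out <- matrix(0, B, length(cm))
    for (b in seq_len(B)) {
      out[b, ] <- (1 - u) * (1 - v) * R[cbind(i, j, b)] +
        u * (1 - v) * R[cbind(i + 1, j, b)] +
        (1 - u) * v * R[cbind(i, j + 1, b)] +
        u * v * R[cbind(i + 1, j + 1, b)]
    }
    out
  }
}

#' Render a synthetic skin phantom
#'
#' Per pixel: `(Cm, Cb)` fields -> reflectance via the forward lookup ->
#' RGB through the system matrix -> multiplicative shading -> gamma
#' distortion -> 8-bit quantization with sensor noise. Ground-truth vein
#' mask and concentration maps are returned alongside.
#'
#' @param spec a [phantom_spec()].
#' @param F a [system_matrix()] (normalize it to the training spectra so
#'   rendered intensities stay in gamut).
#' @param forward a [reflectance_lookup()] function (or any
#'   `f(cm, cb) -> B x N` reflectance model).
#' @return List of class `phantom`: `rgb` (8-bit-quantized
#'   [image_plane()] on `[0, 1]`), `truth_mask` (`vein_mask`),
#'   `truth_cm`, `truth_cb` (H x W), `shading` (the applied field).
#' @export
render_phantom <- function(spec, F, forward) {
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  cm <- matrix(spec$bg_cm, H, W)
  cb <- matrix(spec$bg_cb, H, W)
  if (spec$noise_cm > 0) cm <- cm + spec$noise_cm * smooth_noise(H, W)
  if (spec$noise_cb > 0) cb <- cb + spec$noise_cb * smooth_noise(H, W)
  truth <- matrix(FALSE, H, W)
  rows <- matrix(seq_len(H), H, W)
  for (v in spec$veins) {
    # smooth random-walk centerline running left-right
    y0 <- stats::runif(1, 0.25 * H, 0.75 * H)
    steps <- stats::rnorm(W, 0, 0.8)
    center <- y0 + cumsum(steps)
    center <- stats::filter(center, rep(1 / 15, 15), circular = TRUE)
    center <- pmin(pmax(as.numeric(center), 0.15 * H), 0.85 * H)
    dist <- abs(sweep(rows, 2, center))
    inside <- dist <= v$width / 2
    cb[inside] <- cb[inside] + v$cb_elevation
    truth <- truth | inside
  }
  shade <- switch(spec$shading,
    none = matrix(1, H, W),
    ramp = matrix(rep(seq(1 - spec$shading_amplitude, 1, length.out = W),
                      each = H), H, W),
    spotlight = {
      cx <- W / 2; cy <- H / 2
      r2 <- sweep((rows - cy)^2, 2, (seq_len(W) - cx)^2, "+")
      1 - spec$shading_amplitude * (1 - exp(-r2 / (2 * (0.45 * max(H, W))^2)))
    })
  refl <- forward(as.vector(cm), as.vector(cb))      # B x Npix
  rgb <- render_rgb(refl, F)                         # 3 x Npix
  img <- array(t(rgb), c(H, W, 3))
  img <- img * as.vector(shade)
  exposure <- 1
  if (spec$auto_expose > 0) {
    gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    exposure <- spec$auto_expose / exp(mean(log(pmax(gray, 1e-6))))
    img <- img * exposure
  }
  img <- pmin(pmax(img, 0), 1)^(1 / spec$gamma_true)
  dn <- img * 255
  if (spec$sensor_sigma > 0)
    dn <- dn + stats::rnorm(length(dn), 0, spec$sensor_sigma)
  dn <- round(pmin(pmax(dn, 0), 255))
  class(truth) <- c("vein_mask", class(truth))
  structure(list(rgb = image_plane(dn / 255, value_range = c(0, 1)),
                 truth_mask = truth, truth_cm = cm, truth_cb = cb,
                 shading = shade, exposure = exposure, spec = spec),
            class = "phantom")
}
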