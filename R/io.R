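#' Read an RGB image as an image plane
#'
#' Supports PNG and TIFF. Gray inputs are replicated to 3 bands.
#'
#' @param path image file.
#' @param mask optional logical matrix, or path to a single-channel PNG
#'   mask (255 = skin).
#' @return An RGB [image_plane()] on `[0, 1]`.
#' @export
read_rgb_image <- function(path, mask = NULL) {
  px <- read_raster(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3]   # drop alpha
  if (is.character(mask)) mask <- read_mask(mask)
  image_plane(px, mask, c(0, 1))
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image format: ", ext)
}

#' Read / write a binary mask PNG (255 = skin/vein)
#' @param path PNG file.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  m <- read_raster(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' @rdname read_mask
#' @param mask logical matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write an RGB or scalar image plane to PNG
#' @param image an [image_plane()].
#' @param path PNG file path.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image$pixels / image$value_range[2], 0), 1), path)
  invisible(path)
}

#' Write a scalar map to 16-bit TIFF
#' @param map numeric matrix (NAs written as 0); values min-max scaled.
#' @param path TIFF file path.
#' @export
write_map_tiff <- function(map, path) {
  v <- map
  v[is.na(v)] <- min(v, na.rm = TRUE)
  rng <- range(v)
  v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  tiff::writeTIFF(v, path, bits.per.sample = 16)
  invisible(path)
}

#' Export a spectral cube band-wise to 16-bit TIFF
#'
#' One file per wavelength band (`band_400.tiff`, ...), values on the
#' native reflectance scale `[0, 1]`.
#' @param cube a `spectral_cube`.
#' @param dir output directory (created if needed).
#' @export
write_cube_tiff_stack <- function(cube, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in seq_len(cube$grid$n_bands)) {
    tiff::writeTIFF(pmin(pmax(cube$values[, , b], 0), 1),
                    file.path(dir, sprintf("band_%d.tiff",
                                           cube$grid$wavelengths[b])),
                    bits.per.sample = 16)
  }
  invisible(dir)
}

#' Persist / load a spectral cube
#'
#' Band-sequential doubles plus a JSON sidecar with dimensions, grid and
#' mask.
#' @param cube a `spectral_cube`.
#' @param path data file path; sidecar is `<path>.json`.
#' @export
write_spectral_cube <- function(cube, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(cube$values), con, size = 8)
  side <- list(dim = dim(cube$values),
               grid = cube$grid[c("start_nm", "stop_nm", "step_nm")],
               mask = as.vector(cube$mask), n_clipped = cube$n_clipped)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spectral_cube
#' @return A `spectral_cube`.
#' @export
read_spectral_cube <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- side$dim
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(d), size = 8)
  structure(list(values = array(v, d),
                 grid = wavelength_grid(side$grid$start_nm,
                                        side$grid$stop_nm,
                                        side$grid$step_nm),
                 mask = matrix(side$mask, d[1], d[2]),
                 n_clipped = side$n_clipped), class = "spectral_cube")
}
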