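#' Wavelength grid
#'
#' Defines the discrete wavelength axis every spectral quantity in the
#' package lives on. The default working grid is 400--700 nm at 10 nm
#' (31 bands); the inverse-model regression uses the 500--600 nm sub-grid.
#'
#' @param start_nm,stop_nm,step_nm grid limits and spacing in nanometres.
#' @return An object of class `wavelength_grid` with elements `start_nm`,
#'   `stop_nm`, `step_nm`, `wavelengths` and `n_bands`.
#' @export
#' @examples
#' g <- wavelength_grid()
#' g$n_bands # 31
wavelength_grid <- function(start_nm = 400, stop_nm = 700, step_nm = 10) {
  if (start_nm >= stop_nm) stop("start_nm must be < stop_nm")
  if (step_nm <= 0) stop("step_nm must be > 0")
  span <- stop_nm - start_nm
  if (abs(span / step_nm - round(span / step_nm)) > 1e-9)
    stop("(stop_nm - start_nm) must be divisible by step_nm")
  wl <- seq(start_nm, stop_nm, by = step_nm)
  structure(list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
                 wavelengths = wl, n_bands = length(wl)),
            class = "wavelength_grid")
}

#' The regression sub-grid (500--600 nm)
#' @param step_nm band spacing, 10 (default) or 20 nm.
#' @return A `wavelength_grid`.
#' @export
regression_grid <- function(step_nm = 10) {
  wavelength_grid(500, 600, step_nm)
}

#' Spectrum on a wavelength grid
#'
#' The universal carrier for every physical curve: illuminant power,
#' camera sensitivity, diffuse reflectance, molar extinction, absorption
#' and scattering coefficients.
#'
#' @param values numeric vector, one value per grid band.
#' @param grid a [wavelength_grid()].
#' @param role one of `"generic"`, `"reflectance"`, `"illuminant"`,
#'   `"response"`, `"extinction"`, `"mu_a"`, `"mu_s"`, `"g"`. Role-specific
#'   validation is applied (reflectance clipped to (0, 1], extinction and
#'   `mu_s` strictly positive, ...).
#' @return An object of class `spectrum_curve`.
#' @export
spectrum_curve <- function(values, grid = wavelength_grid(),
                           role = "generic") {
  values <- as.numeric(values)
  if (length(values) != grid$n_bands)
    stop("length(values) must equal grid$n_bands")
  if (any(!is.finite(values))) stop("spectrum values must be finite")
  role <- match.arg(role, c("generic", "reflectance", "illuminant",
                            "response", "extinction", "mu_a", "mu_s", "g"))
  switch(role,
    reflectance = {
      if (any(values > 1 + 1e-9)) stop("reflectance must be <= 1")
      values <- pmin(pmax(values, .Machine$double.eps), 1)
    },
    illuminant = , response = {
      if (any(values < 0)) stop(role, " values must be nonnegative")
    },
    extinction = , mu_s = {
      if (any(values <= 0)) stop(role, " values must be strictly positive")
    },
    mu_a = {
      if (any(values < 0)) stop("mu_a values must be nonnegative")
    },
    g = {
      if (any(values < -1 | values > 1)) stop("g must lie in [-1, 1]")
    },
    NULL)
  structure(list(grid = grid, values = values, role = role),
            class = "spectrum_curve")
}

#' @export
print.spectrum_curve <- function(x, ...) {
  cat(sprintf("<spectrum_curve role=%s %g-%g nm x %d bands>\n", x$role,
              x$grid$start_nm, x$grid$stop_nm, x$grid$n_bands))
  invisible(x)
}

#' Load a spectral table and resample it onto a working grid
#'
#' Reads a two-column CSV (`wavelength_nm,value`), checks that it covers
#' the grid, linearly interpolates onto the grid bands and applies the
#' role validation of [spectrum_curve()].
#'
#' @param path CSV file path.
#' @param role spectrum role, see [spectrum_curve()].
#' @param grid target [wavelength_grid()].
#' @return A `spectrum_curve` on `grid`.
#' @export
load_spectral_table <- function(path, role = "generic",
                                grid = wavelength_grid()) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("wavelength_nm", "value") %in% names(tab)))
    stop("spectral table must have columns wavelength_nm,value: ", path)
  wl <- tab$wavelength_nm
  if (is.unsorted(wl, strictly = TRUE))
    stop("wavelengths must be strictly increasing: ", path)
  if (min(wl) > grid$start_nm + 1e-9 || max(wl) < grid$stop_nm - 1e-9)
    stop(sprintf("table %s covers %g-%g nm but the grid needs %g-%g nm",
                 path, min(wl), max(wl), grid$start_nm, grid$stop_nm))
  v <- stats::approx(wl, tab$value, xout = grid$wavelengths)$y
  spectrum_curve(v, grid, role)
}

#' Write a spectrum to CSV
#'
#' Inverse of [load_spectral_table()]: full double precision, so a
#' write/reload round trip is lossless.
#' @param spec a `spectrum_curve`.
#' @param path output CSV path.
#' @export
write_spectral_table <- function(spec, path) {
  df <- data.frame(wavelength_nm = spec$grid$wavelengths,
                   value = format(spec$values, digits = 17))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a spectrum to a sub-grid
#'
#' @param spec a `spectrum_curve`.
#' @param subgrid a [wavelength_grid()] whose bands are a subset of the
#'   bands of `spec`.
#' @return A `spectrum_curve` on `subgrid`.
#' @export
subset_spectrum <- function(spec, subgrid) {
  idx <- match(subgrid$wavelengths, spec$grid$wavelengths)
  if (any(is.na(idx)))
    stop("subgrid bands are not a subset of the spectrum grid")
  spectrum_curve(spec$values[idx], subgrid, spec$role)
}

# indices of subgrid bands within grid (internal)
band_index <- function(grid, subgrid) {
  idx <- match(subgrid$wavelengths, grid$wavelengths)
  if (any(is.na(idx))) stop("subgrid is not contained in grid")
  idx
}
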