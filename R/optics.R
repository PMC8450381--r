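#' Path to a bundled spectral fixture
#' @param file file name under the package's `extdata` directory; empty
#'   string returns the directory itself.
#' @return Absolute file path.
#' @export
veinviz_extdata <- function(file = "") {
  system.file("extdata", file, package = "veinviz", mustWork = TRUE)
}

#' Bundled chromophore extinction curves
#'
#' Molar extinction spectra of melanin, oxyhemoglobin and deoxyhemoglobin
#' on the working grid. These are the predictor variables of the modified
#' Beer-Lambert regression.
#'
#' @param grid working [wavelength_grid()].
#' @param dir directory with `extinction_{melanin,hbo2,hb}.csv`; defaults
#'   to the bundled fixtures.
#' @return A list of class `chromophore_set` with `spectrum_curve` fields
#'   `eps_melanin`, `eps_oxy`, `eps_deoxy`.
#' @export
chromophore_set <- function(grid = wavelength_grid(),
                            dir = veinviz_extdata()) {
  cs <- list(
    eps_melanin = load_spectral_table(file.path(dir, "extinction_melanin.csv"),
                                      "extinction", grid),
    eps_oxy = load_spectral_table(file.path(dir, "extinction_hbo2.csv"),
                                  "extinction", grid),
    eps_deoxy = load_spectral_table(file.path(dir, "extinction_hb.csv"),
                                    "extinction", grid))
  structure(cs, class = "chromophore_set")
}

#' Layer optical properties
#'
#' @param mu_a,mu_s,g `spectrum_curve`s of absorption (cm^-1), scattering
#'   (cm^-1) and Henyey-Greenstein anisotropy.
#' @param n refractive index (>= 1).
#' @param d thickness in cm (> 0).
#' @param name layer label.
#' @return An object of class `layer_properties`.
#' @export
layer_properties <- function(mu_a, mu_s, g, n, d, name = "layer") {
  stopifnot(inherits(mu_a, "spectrum_curve"), inherits(mu_s, "spectrum_curve"),
            inherits(g, "spectrum_curve"))
  if (n < 1) stop("refractive index must be >= 1")
  if (d <= 0) stop("thickness must be > 0")
  if (any(mu_a$values < 0)) stop("mu_a must be nonnegative")
  if (any(mu_s$values <= 0)) stop("mu_s must be strictly positive")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n, d = d,
                 name = name), class = "layer_properties")
}

#' Default three-layer skin model
#'
#' Epidermis, dermis and hypodermis with bundled literature optical
#' properties. Absorption of the epidermis and dermis is parameterized by
#' the melanin and blood volume fractions via [compose_absorption()]; this
#' function returns the stack at given `(Cm, Cb)`.
#'
#' Refractive indices are 1.37 (epidermis, dermis) and 1.44 (hypodermis);
#' thicknesses 0.006, 0.09 and 0.03 cm.
#'
#' @param Cm melanin volume fraction in the epidermis (0.013--0.43).
#' @param Cb blood volume fraction in the dermis (0.001--0.07).
#' @param so2 oxygen saturation of the dermal blood mix (default 0.75,
#'   venous-dominant).
#' @param grid working [wavelength_grid()].
#' @param dir fixture directory.
#' @return A list of class `skin_stack` of three `layer_properties`,
#'   ordered top-down.
#' @export
default_skin_stack <- function(Cm = 0.10, Cb = 0.01, so2 = 0.75,
                               grid = wavelength_grid(),
                               dir = veinviz_extdata()) {
  fx <- skin_fixtures(grid, dir)
  ab <- compose_absorption(Cm, Cb, so2 = so2, fixtures = fx)
  stack <- list(
    layer_properties(ab$epidermis, fx$mus_epi, fx$g_ed, n = 1.37,
                     d = 0.006, name = "epidermis"),
    layer_properties(ab$dermis, fx$mus_der, fx$g_ed, n = 1.37,
                     d = 0.09, name = "dermis"),
    layer_properties(ab$hypodermis, fx$mus_hyp, fx$g_hyp, n = 1.44,
                     d = 0.03, name = "hypodermis"))
  structure(stack, class = "skin_stack")
}

# Load (and cache per grid) the layer fixture curves.
skin_fixtures <- function(grid = wavelength_grid(), dir = veinviz_extdata()) {
  key <- paste(dir, grid$start_nm, grid$stop_nm, grid$step_nm, sep = "|")
  cached <- .veinviz_cache[[key]]
  if (!is.null(cached)) return(cached)
  fx <- list(
    chrom = chromophore_set(grid, dir),
    mua_base = load_spectral_table(file.path(dir, "mua_baseline_skin.csv"),
                                   "mu_a", grid),
    mua_hyp = load_spectral_table(file.path(dir, "mua_hypodermis.csv"),
                                  "mu_a", grid),
    mus_epi = load_spectral_table(file.path(dir, "mus_epidermis.csv"),
                                  "mu_s", grid),
    mus_der = load_spectral_table(file.path(dir, "mus_dermis.csv"),
                                  "mu_s", grid),
    mus_hyp = load_spectral_table(file.path(dir, "mus_hypodermis.csv"),
                                  "mu_s", grid),
    g_ed = load_spectral_table(file.path(dir, "g_epidermis_dermis.csv"),
                               "g", grid),
    g_hyp = load_spectral_table(file.path(dir, "g_hypodermis.csv"),
                                "g", grid))
  .veinviz_cache[[key]] <- fx
  fx
}

.veinviz_cache <- new.env(parent = emptyenv())

# grams of hemoglobin per litre of whole blood / molar mass -> mol/L
.HB_MOLARITY <- 150 / 64500

#' Layer absorption at given chromophore concentrations
#'
#' Epidermal absorption mixes interior-melanosome absorption with the
#' pigment-free baseline by the melanin volume fraction; dermal absorption
#' mixes whole-blood absorption (oxy/deoxy at saturation `so2`) with the
#' baseline by the blood volume fraction. Hypodermis absorption is a fixed
#' fixture curve.
#'
#' @param Cm melanin volume fraction, in `[0, 0.43]`.
#' @param Cb blood volume fraction, in `[0, 1]` (training range 0.001--0.07).
#' @param so2 blood oxygen saturation in `[0, 1]`.
#' @param fixtures result of an internal fixture load; defaults to the
#'   bundled set on the default grid.
#' @param grid,dir forwarded to the fixture loader when `fixtures` is NULL.
#' @return List of `mu_a` `spectrum_curve`s: `epidermis`, `dermis`,
#'   `hypodermis`, plus `mua_blood` (whole blood, cm^-1).
#' @export
compose_absorption <- function(Cm, Cb, so2 = 0.75, fixtures = NULL,
                               grid = wavelength_grid(),
                               dir = veinviz_extdata()) {
  if (Cm < 0 || Cm > 0.43) stop("Cm outside [0, 0.43]")
  if (Cb < 0 || Cb > 1) stop("Cb outside [0, 1]")
  if (so2 < 0 || so2 > 1) stop("so2 outside [0, 1]")
  fx <- if (is.null(fixtures)) skin_fixtures(grid, dir) else fixtures
  g <- fx$mua_base$grid
  eps_mix <- so2 * fx$chrom$eps_oxy$values +
    (1 - so2) * fx$chrom$eps_deoxy$values
  mua_blood <- log(10) * .HB_MOLARITY * eps_mix
  mua_mel <- fx$chrom$eps_melanin$values   # interior-melanosome scale
  list(
    epidermis = spectrum_curve(Cm * mua_mel + (1 - Cm) * fx$mua_base$values,
                               g, "mu_a"),
    dermis = spectrum_curve(Cb * mua_blood + (1 - Cb) * fx$mua_base$values,
                            g, "mu_a"),
    hypodermis = fx$mua_hyp,
    mua_blood = spectrum_curve(mua_blood, g, "mu_a"))
}

#' Bundled illuminant and camera model
#'
#' @param grid working [wavelength_grid()].
#' @param dir fixture directory (override to substitute measured camera
#'   curves; files `camera_response_{r,g,b}.csv`, `illuminant_d65.csv`).
#' @return List with `illuminant` (a `spectrum_curve`, normalized to unit
#'   mean) and `camera` (3 x B matrix, rows R, G, B).
#' @export
camera_illuminant <- function(grid = wavelength_grid(),
                              dir = veinviz_extdata()) {
  E <- load_spectral_table(file.path(dir, "illuminant_d65.csv"),
                           "illuminant", grid)
  E <- spectrum_curve(E$values / mean(E$values), grid, "illuminant")
  S <- rbind(
    load_spectral_table(file.path(dir, "camera_response_r.csv"),
                        "response", grid)$values,
    load_spectral_table(file.path(dir, "camera_response_g.csv"),
                        "response", grid)$values,
    load_spectral_table(file.path(dir, "camera_response_b.csv"),
                        "response", grid)$values)
  rownames(S) <- c("R", "G", "B")
  list(illuminant = E, camera = S)
}
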