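#' Photon run configuration
#'
#' @param n_photons photons launched per wavelength band.
#' @param seed integer seed; identical seed and configuration give
#'   bit-identical results, independent of how runs are chunked.
#' @param weight_threshold photon weight below which Russian roulette is
#'   played.
#' @param roulette_chance survival probability of the roulette.
#' @param max_steps hard cap on random-walk steps per photon (guards
#'   non-absorbing media; leftover weight is booked as absorbed).
#' @return Object of class `photon_config`.
#' @export
photon_config <- function(n_photons = 1e5, seed = 1,
                          weight_threshold = 1e-4, roulette_chance = 0.1,
                          max_steps = 1e7) {
  stopifnot(n_photons >= 1, weight_threshold > 0, weight_threshold < 1,
            roulette_chance > 0, roulette_chance < 1)
  structure(list(n_photons = as.integer(n_photons), seed = seed,
                 weight_threshold = weight_threshold,
                 roulette_chance = roulette_chance, max_steps = max_steps),
            class = "photon_config")
}

#' Simulate diffuse reflectance of a layered medium
#'
#' MCML-style photon random walk: specular deduction at entry, free path
#' `-ln(xi) / (mu_a + mu_s)`, Henyey-Greenstein scattering, Fresnel
#' reflection/refraction at refractive-index mismatches, absorption by
#' fractional weight drop, and Russian roulette termination. Only total
#' (angle- and radius-integrated) quantities are tallied.
#'
#' @param stack a `skin_stack` / list of [layer_properties()] (top-down);
#'   ambient medium above and below has n = 1.
#' @param cfg a [photon_config()].
#' @return data.frame with one row per band: `wavelength_nm`, `diffuse`,
#'   `specular`, `transmitted`, `absorbed`, `std_error`. The four
#'   fractions sum to 1 up to the roulette bookkeeping (<= 1e-3).
#' @export
simulate_reflectance <- function(stack, cfg = photon_config()) {
  L <- length(stack)
  grid <- stack[[1]]$mu_a$grid
  B <- grid$n_bands
  mua <- t(vapply(stack, function(l) l$mu_a$values, numeric(B)))
  mus <- t(vapply(stack, function(l) l$mu_s$values, numeric(B)))
  g <- t(vapply(stack, function(l) l$g$values, numeric(B)))
  n <- vapply(stack, function(l) l$n, numeric(1))
  d <- vapply(stack, function(l) l$d, numeric(1))
  if (any(n < 1) || any(d <= 0) || any(mus <= 0) || any(mua < 0))
    stop("nonphysical layer properties")
  m <- .mc_run(mua, mus, g, n, d, cfg$n_photons, cfg$seed,
               cfg$weight_threshold, cfg$roulette_chance, cfg$max_steps)
  data.frame(wavelength_nm = grid$wavelengths, diffuse = m[, 1],
             specular = m[, 2], transmitted = m[, 3], absorbed = m[, 4],
             std_error = m[, 5])
}

#' Simulate the (Cm, Cb) training grid
#'
#' Runs the three-layer forward model over a uniform grid of melanin and
#' blood volume fractions, one diffuse reflectance spectrum per pair --
#' the prior dataset of the inverse model. `n_m = n_b = 50` reproduces the
#' full 2500-pair design.
#'
#' @param n_m,n_b number of grid points for `Cm` and `Cb` (>= 2).
#' @param cfg a [photon_config()]; each pair gets a distinct deterministic
#'   sub-seed derived from `cfg$seed`.
#' @param grid working [wavelength_grid()].
#' @param cm_range,cb_range concentration ranges (volume fractions).
#' @param so2 dermal blood oxygen saturation.
#' @param checkpoint optional CSV path: completed rows are appended as
#'   they finish and are skipped when the call is repeated (resumable).
#' @param verbose print progress.
#' @return Object of class `training_grid`: data.frame `pairs` with
#'   columns `Cm`, `Cb` and one reflectance column per band
#'   (`r_400` ... `r_700`), plus `grid`, `config`, `so2`.
#' @export
build_training_grid <- function(n_m = 50, n_b = 50, cfg = photon_config(),
                                grid = wavelength_grid(),
                                cm_range = c(0.013, 0.43),
                                cb_range = c(0.001, 0.07), so2 = 0.75,
                                checkpoint = NULL, verbose = FALSE) {
  stopifnot(n_m >= 2, n_b >= 2)
  cms <- seq(cm_range[1], cm_range[2], length.out = n_m)
  cbs <- seq(cb_range[1], cb_range[2], length.out = n_b)
  design <- expand.grid(Cm = cms, Cb = cbs, KEEP.OUT.ATTRS = FALSE)
  rcols <- paste0("r_", grid$wavelengths)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint)
  }
  fx <- skin_fixtures(grid)
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    Cm <- design$Cm[i]; Cb <- design$Cb[i]
    if (!is.null(done)) {
      hit <- which(abs(done$Cm - Cm) < 1e-12 & abs(done$Cb - Cb) < 1e-12)
      if (length(hit)) { rows[[i]] <- done[hit[1], c("Cm", "Cb", rcols)]; next }
    }
    stack <- default_skin_stack(Cm, Cb, so2 = so2, grid = grid)
    sub <- photon_config(cfg$n_photons,
                         seed = cfg$seed + 7919 * (i - 1),
                         weight_threshold = cfg$weight_threshold,
                         roulette_chance = cfg$roulette_chance,
                         max_steps = cfg$max_steps)
    sim <- simulate_reflectance(stack, sub)
    row <- as.data.frame(c(list(Cm = Cm, Cb = Cb),
                           stats::setNames(as.list(sim$diffuse), rcols)))
    rows[[i]] <- row
    if (!is.null(checkpoint))
      utils::write.table(row, checkpoint, sep = ",", append = file.exists(checkpoint),
                         col.names = !file.exists(checkpoint), row.names = FALSE)
    if (verbose && i %% 10 == 0)
      message(sprintf("training grid %d/%d", i, nrow(design)))
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, grid = grid, config = cfg, so2 = so2,
                 cm_range = cm_range, cb_range = cb_range,
                 n_m = n_m, n_b = n_b), class = "training_grid")
}

#' Reflectance spectra of a training grid as a matrix
#' @param tg a [build_training_grid()] result.
#' @return B x N matrix, spectra in columns (clipped to (0, 1]).
#' @export
training_spectra <- function(tg) {
  rcols <- paste0("r_", tg$grid$wavelengths)
  R <- t(as.matrix(tg$pairs[, rcols]))
  pmin(pmax(R, .Machine$double.eps), 1)
}

#' Write / read a training grid dataset
#'
#' CSV of pairs plus a JSON sidecar with the full run configuration.
#' @param tg a `training_grid`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @export
write_training_grid <- function(tg, path) {
  utils::write.csv(tg$pairs, path, row.names = FALSE)
  side <- list(grid = tg$grid[c("start_nm", "stop_nm", "step_nm")],
               config = unclass(tg$config), so2 = tg$so2,
               cm_range = tg$cm_range, cb_range = tg$cb_range,
               n_m = tg$n_m, n_b = tg$n_b)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_training_grid
#' @param path CSV path written by [write_training_grid()].
#' @return A `training_grid`.
#' @export
read_training_grid <- function(path) {
  pairs <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- wavelength_grid(side$grid$start_nm, side$grid$stop_nm,
                       side$grid$step_nm)
  cfg <- do.call(photon_config, as.list(side$config))
  structure(list(pairs = pairs, grid = g, config = cfg, so2 = side$so2,
                 cm_range = side$cm_range, cb_range = side$cb_range,
                 n_m = side$n_m, n_b = side$n_b), class = "training_grid")
}
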