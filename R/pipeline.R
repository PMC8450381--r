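#' Pipeline configuration
#'
#' Switches and parameters for the full visualization chain. The whole
#' configuration is stamped into every output bundle for provenance.
#'
#' @param light_correction apply entropy-optimal gamma correction.
#' @param shading_removal apply iterated bilateral shading removal.
#' @param n_iter bilateral passes for shading removal.
#' @param subgrid_step_nm inverse-model application band spacing within
#'   500--600 nm: 10 (default, matches training) or 20.
#' @param extraction named list passed to [extract_veins()]
#'   (`min_component_px`, ...).
#' @param seed seed for any stochastic stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(light_correction = TRUE,
                            shading_removal = TRUE, n_iter = 5,
                            subgrid_step_nm = 10,
                            extraction = list(min_component_px = 50),
                            seed = 1) {
  if (!subgrid_step_nm %in% c(10, 20))
    stop("subgrid_step_nm must be 10 or 20")
  structure(list(light_correction = light_correction,
                 shading_removal = shading_removal, n_iter = n_iter,
                 subgrid_step_nm = subgrid_step_nm,
                 extraction = extraction, seed = seed),
            class = "pipeline_config")
}

#' Build the shared model assets for the pipeline
#'
#' From one Monte Carlo training grid: the normalized system matrix, the
#' reflectance prior and Wiener matrix, the trained inverse model and the
#' phantom forward lookup. All pipeline runs against the same assets are
#' mutually comparable.
#'
#' @param tg a [build_training_grid()] result.
#' @param config a [pipeline_config()] (controls the inverse sub-grid).
#' @return Object of class `pipeline_assets` with fields `F`, `prior`,
#'   `W`, `model`, `lookup`, `chroms`, `grid`, `ref_gray` (median rendered
#'   luminance of the training spectra, used for per-image exposure fit).
#' @export
pipeline_assets <- function(tg, config = pipeline_config()) {
  grid <- tg$grid
  R <- training_spectra(tg)
  F <- system_matrix(grid = grid, normalize_to = asplit(R, 2))
  prior <- build_prior(R, provenance = "MC training spectra")
  W <- build_wiener_matrix(prior, F)
  chroms <- chromophore_set(grid)
  model <- train_concentration_map(
    tg, chroms, subgrid = regression_grid(config$subgrid_step_nm))
  rgb_ref <- render_rgb(R, F)
  ref_gray <- stats::median(0.299 * rgb_ref[1, ] + 0.587 * rgb_ref[2, ] +
                              0.114 * rgb_ref[3, ])
  structure(list(F = F, prior = prior, W = W, model = model,
                 lookup = reflectance_lookup(tg), chroms = chroms,
                 grid = grid, ref_gray = ref_gray),
            class = "pipeline_assets")
}

#' Run the full vein visualization chain on one image
#'
#' Stage order: light correction -> shading removal -> exposure fit ->
#' Wiener spectral reconstruction -> per-pixel concentration maps ->
#' vein visualization (inverted, contrast-normalized blood map) -> Gabor
#' vein extraction.
#'
#' @param rgb an RGB [image_plane()] or a PNG/TIFF path.
#' @param assets a [pipeline_assets()] result.
#' @param config a [pipeline_config()].
#' @param mask optional logical skin mask (overrides the one in `rgb`).
#' @return List of class `vein_bundle`: `cm_map`, `cb_map`
#'   (a `concentration_map`), `visualization` (scalar `image_plane`,
#'   veins dark), `vein_mask`, `preprocessed` (the corrected RGB),
#'   `provenance` (config, gamma_star, exposure gain, clip count).
#' @export
run_pipeline <- function(rgb, assets, config = pipeline_config(),
                         mask = NULL) {
  if (is.character(rgb)) rgb <- read_rgb_image(rgb)
  if (!is.null(mask)) rgb <- image_plane(rgb$pixels, mask, rgb$value_range)
  gamma_star <- NA_real_
  if (config$light_correction) {
    gamma_star <- estimate_gamma(rgb)
    rgb <- apply_gamma(rgb, gamma_star)
  }
  if (config$shading_removal) {
    rgb <- remove_shading(rgb, n_iter = config$n_iter)$corrected
  }
  gray <- to_gray01(rgb)
  gain <- stats::median(gray[rgb$mask]) / assets$ref_gray
  if (!is.finite(gain) || gain <= 0) gain <- 1
  cube <- reconstruct_cube(rgb, assets$W, gain = gain)
  maps <- predict_concentrations(cube, assets$model, assets$chroms)
  vis <- visualization_image(maps)
  vm <- do.call(extract_veins,
                c(list(image = vis, dark_veins = TRUE), config$extraction))
  structure(list(
    cm_map = maps$Cm_map, cb_map = maps$Cb_map, maps = maps,
    visualization = vis, vein_mask = vm, preprocessed = rgb,
    provenance = list(config = unclass(config), gamma_star = gamma_star,
                      exposure_gain = gain, n_clipped = cube$n_clipped,
                      model = assets$model$provenance)),
    class = "vein_bundle")
}

#' Vein visualization image from concentration maps
#'
#' The blood map min-max normalized within the skin region and inverted,
#' so high blood fraction renders dark -- the NIR appearance convention.
#'
#' @param maps a [predict_concentrations()] result.
#' @return Scalar [image_plane()] on `[0, 1]`.
#' @export
visualization_image <- function(maps) {
  cb <- maps$Cb_map
  v <- cb[maps$mask]
  rng <- range(v)
  out <- matrix(1, nrow(cb), ncol(cb))
  scl <- if (diff(rng) > 0) (cb - rng[1]) / diff(rng) else cb * 0
  out[maps$mask] <- 1 - scl[maps$mask]
  image_plane(pmin(pmax(out, 0), 1), maps$mask, c(0, 1))
}

#' Write the output bundle of one pipeline run to a directory
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_map_tiff(bundle$cm_map, file.path(dir, "cm_map.tiff"))
  write_map_tiff(bundle$cb_map, file.path(dir, "cb_map.tiff"))
  write_image(bundle$visualization, file.path(dir, "visualization.png"))
  write_mask(bundle$vein_mask, file.path(dir, "vein_mask.png"))
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Score a batch of images against ground truth
#'
#' Pairs files by base name, runs the pipeline on every image, extracts a
#' ground-truth mask from the paired truth file (binary PNG masks are
#' used directly; gray NIR-like images go through the same Gabor
#' extractor as the predictions) and tabulates the four metrics plus a
#' mean row.
#'
#' @param image_dir directory of RGB images (PNG/TIFF).
#' @param truth_dir directory of ground-truth images or masks with
#'   matching base names.
#' @param assets a [pipeline_assets()] result.
#' @param config a [pipeline_config()].
#' @return data.frame with one row per image and a final `"mean"` row:
#'   `image`, `accuracy`, `precision`, `recall`, `f1`.
#' @export
evaluate_batch <- function(image_dir, truth_dir, assets,
                           config = pipeline_config()) {
  imgs <- sort(list.files(image_dir, "\\.(png|tiff?)$", ignore.case = TRUE))
  if (!length(imgs)) {
    warning("no images found in ", image_dir)
    return(data.frame(image = character(), accuracy = numeric(),
                      precision = numeric(), recall = numeric(),
                      f1 = numeric()))
  }
  truths <- list.files(truth_dir, "\\.(png|tiff?)$", ignore.case = TRUE)
  base <- tools::file_path_sans_ext(imgs)
  tbase <- tools::file_path_sans_ext(truths)
  miss <- setdiff(base, tbase)
  if (length(miss)) stop("unpaired images: ", paste(miss, collapse = ", "))
  rows <- lapply(seq_along(imgs), function(i) {
    bundle <- run_pipeline(file.path(image_dir, imgs[i]), assets, config)
    tpath <- file.path(truth_dir, truths[match(base[i], tbase)])
    traster <- read_raster(tpath)
    if (length(dim(traster)) == 3) traster <- traster[, , 1]
    uv <- unique(as.vector(traster))
    truth <- if (all(uv %in% c(0, 1))) traster > 0.5
      else extract_veins(image_plane(traster, bundle$preprocessed$mask,
                                     c(0, 1)),
                         dark_veins = TRUE)
    s <- score_veins(bundle$vein_mask, truth, bundle$preprocessed$mask)
    data.frame(image = base[i], accuracy = s$accuracy,
               precision = s$precision, recall = s$recall, f1 = s$f1)
  })
  tab <- do.call(rbind, rows)
  mean_row <- data.frame(image = "mean", accuracy = mean(tab$accuracy),
                         precision = mean(tab$precision),
                         recall = mean(tab$recall), f1 = mean(tab$f1))
  rbind(tab, mean_row)
}
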