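#' Structure stage: CHM, scene classification, crowns, per-tree metrics
#'
#' @param scene orchard_scene (or any list with dsm, dtm, bands, trees).
#' @param thresholds classification thresholds, see
#'   \code{\link{classify_scene}}.
#' @return list with chm, classes, crowns and \code{structure} (per-tree
#'   data.frame).
#' @export
run_structure <- function(scene, thresholds = list()) {
  chm <- compute_chm(scene$dsm, scene$dtm)
  classes <- classify_scene(scene$bands, chm, thresholds)
  crowns <- segment_crowns(classes, chm, scene$trees)
  metrics <- tree_structure_metrics(crowns, chm, scene$trees)
  list(chm = chm, classes = classes, crowns = crowns, structure = metrics)
}

#' Traits stage: VIs, RT inversion and daily interception per tree
#'
#' Vegetation indices from the grid-cell mean reflectances; RT-model trait
#' predictions both from the full cell mean (the operational input) and
#' from the vegetation-masked mean (canopy-only spectra, used for recovery
#' checks); daily intercepted fraction from the hourly hedgerow model with
#' porosity calibrated on the instantaneous RT fiPAR.
#'
#' @param scene orchard_scene.
#' @param structure result of \code{\link{run_structure}}.
#' @param model inversion_model; trained (n = 5000, scene seed) when NULL.
#' @return list with \code{traits} (per-tree data.frame) and \code{model}.
#' @export
run_traits <- function(scene, structure, model = NULL) {
  if (is.null(model))
    model <- rt_train(n_samples = 5000, seed = scene$config$seed,
                      zenith_deg = scene$weather$zenith_deg,
                      soil = scene$config$soil_spectrum)
  veg <- class_mask(structure$classes, "vegetation")
  cellmean <- sapply(scene$bands$bands, function(b)
    zonal_stats(b, scene$trees, statistic = "mean")$value)
  vegmean <- sapply(scene$bands$bands, function(b)
    zonal_stats(b, scene$trees, mask = veg, statistic = "mean")$value)
  vi <- vegetation_indices(cellmean[, 1], cellmean[, 2], cellmean[, 3],
                           cellmean[, 4], cellmean[, 5], cellmean[, 6])
  pr_cell <- rt_predict(model, pmin(pmax(cellmean, 0), 1))
  ok <- stats::complete.cases(vegmean)
  pr_veg <- data.frame(LAI = rep(NA_real_, nrow(vegmean)),
                       fiPAR = NA_real_)
  if (any(ok))
    pr_veg[ok, ] <- rt_predict(model, pmin(pmax(vegmean[ok, , drop = FALSE],
                                                0), 1))
  n <- nrow(scene$trees)
  por <- fd <- rep(NA_real_, n)
  w <- scene$weather
  for (k in seq_len(n)) {
    fi <- pr_veg$fiPAR[k] * 2 * scene$truth$crown_radius_true[k] /
      scene$config$spacing_across
    fi <- min(max(ifelse(is.na(fi), 0, fi), 0), 0.95)
    df <- daily_fipar(hedge_height = max(structure$structure$height_max[k],
                                         0.5),
                      hedge_width = max(2 * sqrt(
                        structure$structure$crown_area[k] / pi), 0.5),
                      row_azimuth_deg = 90,
                      fiPAR_noon_obs = fi, lat = w$lat, lon = w$lon,
                      doy = w$doy,
                      row_spacing = scene$config$spacing_across)
    por[k] <- df$porosity; fd[k] <- df$fiPAR_d
  }
  traits <- data.frame(tree_id = scene$trees$tree_id, vi,
                       LAI_rt = pr_cell$LAI, fiPAR_rt = pr_cell$fiPAR,
                       LAI_rt_canopy = pr_veg$LAI,
                       fiPAR_rt_canopy = pr_veg$fiPAR,
                       porosity = por, fiPAR_d = fd,
                       stringsAsFactors = FALSE)
  list(traits = traits, model = model)
}

#' Energy stage: per-tree TSEB actual and S-W potential fluxes
#'
#' Canopy temperature is the vegetation-masked thermal zonal mean per grid
#' cell, soil temperature the mean over sunlit plus shaded bare-soil
#' pixels. Ground-truth LAI drives radiation partitioning and wind
#' attenuation when available (the documented preference), remote LAI
#' otherwise; canopy height comes from the structure stage.
#'
#' @param scene orchard_scene.
#' @param structure result of \code{\link{run_structure}}.
#' @param traits result of \code{\link{run_traits}} (fallback LAI source).
#' @param lai_source "ground" (scene$truth$LAI_true) or "remote".
#' @return per-tree data.frame \code{energy} with TSEB fluxes, S-W
#'   potential fluxes, ET_inst/ET_day/ET_p and flags.
#' @export
run_energy <- function(scene, structure, traits, lai_source = "ground") {
  cls_thermal <- raster_resample_nearest(structure$classes$classes,
                                         scene$thermal)
  vcl <- raster_values(cls_thermal)
  veg_mask <- !is.na(vcl) & vcl == 1
  soil_mask <- !is.na(vcl) & (vcl == 3 | vcl == 4)
  Tc <- zonal_stats(scene$thermal, scene$trees, mask = veg_mask)$value
  Ts <- zonal_stats(scene$thermal, scene$trees, mask = soil_mask)$value
  lai <- if (lai_source == "ground" && !is.null(scene$truth$LAI_true))
    scene$truth$LAI_true else traits$traits$LAI_rt_canopy
  meteo <- scene$weather$meteo
  zen <- scene$weather$zenith_deg
  n <- nrow(scene$trees)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    if (is.na(Tc[k]) || is.na(Ts[k]) || is.na(lai[k]) || lai[k] <= 0.05) {
      rows[[k]] <- data.frame(tree_id = scene$trees$tree_id[k],
                              flag = "missing_inputs")
      next
    }
    h_c <- max(structure$structure$height_max[k], 0.5)
    f_cov <- min(structure$structure$crown_area[k] /
                   (scene$config$spacing_row * scene$config$spacing_across),
                 1)
    fx <- solve_tseb(Tc[k], Ts[k], meteo, lai[k], h_c, zen,
                     f_cover = f_cov)
    swr <- sw_resistances(meteo, lai[k], h_c)
    swf <- sw_potential_et(meteo, fx$Rn, fx$Rn_s, fx$G, swr)
    rows[[k]] <- data.frame(
      tree_id = scene$trees$tree_id[k], Tc = Tc[k], Ts = Ts[k],
      LAI = lai[k], h_c = h_c, f_cover = f_cov,
      Rn = fx$Rn, Rn_c = fx$Rn_c, Rn_s = fx$Rn_s, G = fx$G,
      H = fx$H, H_c = fx$H_c, H_s = fx$H_s,
      LE = fx$LE, LE_c = fx$LE_c, LE_s = fx$LE_s, T_ac = fx$T_ac,
      ET_inst = fx$ET_inst, ET_day = fx$ET_day,
      PM_c = swf$PM_c, PM_s = swf$PM_s, C_c = swf$C_c, C_s = swf$C_s,
      LE_p = swf$LE_p, ET_p = swf$ET_p,
      iterations = fx$iterations, flag = fx$flag,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(names(rows[[which.max(vapply(rows, ncol, 0L))]]),
                    names(r))
    for (m in miss) r[[m]] <- NA
    r
  }))
}

#' Water-status stage: CWSI, Tc - Ta and optional productivity
#'
#' @param energy result of \code{\link{run_energy}}.
#' @param scene orchard_scene (for Ta and optional yield columns).
#' @return per-tree data.frame with ET_a, ET_p, CWSI, Tc_minus_Ta, flags.
#' @export
run_water_status <- function(energy, scene) {
  Ta <- scene$weather$meteo$Ta
  ok <- !is.na(energy$ET_day) & !is.na(energy$ET_p) & energy$ET_p > 0
  cw <- rep(NA_real_, nrow(energy)); fl <- rep("missing", nrow(energy))
  if (any(ok)) {
    cc <- cwsi(energy$ET_day[ok], energy$ET_p[ok])
    cw[ok] <- cc$value; fl[ok] <- cc$flag
  }
  out <- data.frame(tree_id = energy$tree_id,
                    ET_a = energy$ET_day, ET_p = energy$ET_p,
                    CWSI = cw, Tc_minus_Ta = energy$Tc - Ta,
                    flag = fl, stringsAsFactors = FALSE)
  if (!is.null(scene$truth$stress)) out$stress <- scene$truth$stress
  out
}

#' End-to-end synthetic pipeline
#'
#' Generates a scene (or takes one), runs structure, traits, energy and
#' water-status stages, and returns every stage table.
#'
#' @param config orchard_config.
#' @param seed seed for weather and scene (overrides config$seed).
#' @param scene optional pre-generated orchard_scene.
#' @param model optional pre-trained inversion_model (reused across scenes).
#' @param lai_source passed to \code{\link{run_energy}}.
#' @return list with scene, structure, traits, energy, water_status.
#' @export
run_pipeline <- function(config = orchard_config(), seed = config$seed,
                         scene = NULL, model = NULL,
                         lai_source = "ground") {
  if (is.null(scene)) {
    weather <- generate_weather(seed = seed)
    config$seed <- seed
    scene <- generate_orchard(config, weather, seed = seed)
  }
  st <- run_structure(scene)
  tr <- run_traits(scene, st, model)
  en <- run_energy(scene, st, tr, lai_source)
  ws <- run_water_status(en, scene)
  list(scene = scene, structure = st, traits = tr, energy = en,
       water_status = ws)
}
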