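#' Configuration of the synthetic orchard generator
#'
#' The defaults mimic a hedgerow almond rootstock trial: 4.5 m within-row
#' by 5.0 m across-row spacing, three rows (one per irrigation treatment)
#' of ten trees (one per rootstock label), 0.10 m multispectral and 0.25 m
#' thermal cells, measured canopy heights within 2.7-5.5 m, tree LAI within
#' 0.5-2.0, and the default bare-soil spectrum.
#'
#' @param n_rows,trees_per_row orchard layout.
#' @param spacing_row,spacing_across tree spacing (m).
#' @param cell_ms,cell_thermal multispectral/thermal cell sizes (m).
#' @param margin bare-soil margin around the planting (m).
#' @param height_range,lai_range,crown_radius_range per-tree truth ranges.
#' @param stress_range imposed stress factor range in [0, 1].
#' @param sigma_dsm DSM noise standard deviation (m); the noise field is
#'   spatially correlated (0.5 m grid, bilinear upsampling), emulating the
#'   smooth error of photogrammetric surfaces.
#' @param sigma_reflectance per-band reflectance noise sd.
#' @param sigma_thermal thermal noise sd (K).
#' @param soil_spectrum six-band soil reflectance.
#' @param insertion_height branch insertion height (m).
#' @param seed generator seed.
#' @return list of class \code{orchard_config}.
#' @export
orchard_config <- function(n_rows = 3, trees_per_row = 10,
                           spacing_row = 4.5, spacing_across = 5.0,
                           cell_ms = 0.10, cell_thermal = 0.25,
                           margin = 2.5,
                           height_range = c(2.7, 5.5),
                           lai_range = c(0.5, 2.0),
                           crown_radius_range = c(1.0, 1.8),
                           stress_range = c(0, 1),
                           sigma_dsm = 0.08, sigma_reflectance = 0.008,
                           sigma_thermal = 0.3,
                           soil_spectrum = rt_default_soil(),
                           insertion_height = 0.8, seed = 42) {
  stopifnot(height_range[2] <= 7, lai_range[2] <= 6,
            stress_range[1] >= 0, stress_range[2] <= 1,
            crown_radius_range[2] <= min(spacing_row, spacing_across) / 2)
  if (abs(spacing_row / cell_ms - round(spacing_row / cell_ms)) > 1e-6 ||
      abs(spacing_across / cell_ms - round(spacing_across / cell_ms)) > 1e-6)
    stop("multispectral cell size must divide the spacing")
  structure(as.list(environment()), class = "orchard_config")
}

#' Synthetic clear-sky diurnal weather
#'
#' Half-hourly clear-sky irradiance scaled to a ~930 W m-2 midday peak,
#' sinusoidal air temperature (dawn minimum 18 C, mid-afternoon maximum
#' 34 C), relative humidity in anti-phase with temperature, constant
#' 2 m s-1 wind, no rain; plus the meteorological state at the image
#' acquisition time.
#'
#' @param doy day of year (default 205, late July).
#' @param lat,lon site coordinates (default 41.5, 0.85).
#' @param seed RNG seed (thermometer noise on Ta).
#' @param acquisition_hour acquisition decimal hour UTC (default 12.5).
#' @param elevation_m site elevation for pressure (default 323).
#' @param peak_Wm2 midday irradiance peak (default 930).
#' @return list with \code{table} (half-hourly weather data.frame),
#'   \code{meteo} (meteo_state at acquisition), \code{zenith_deg} and
#'   \code{azimuth_deg} at acquisition, doy, lat, lon, acquisition_hour.
#' @export
generate_weather <- function(doy = 205, lat = 41.5, lon = 0.85, seed = 42,
                             acquisition_hour = 12.5, elevation_m = 323,
                             peak_Wm2 = 930) {
  set.seed(seed)
  prof <- clear_sky_profile(lat, lon, doy, step_min = 30)
  Rs <- prof$irradiance_Wm2 * peak_Wm2 / max(prof$irradiance_Wm2)
  ta_curve <- function(h) 26 + 8 * sin(pi * (h - 9) / 12)
  Ta_C <- ta_curve(prof$decimal_hour) + stats::rnorm(nrow(prof), 0, 0.2)
  RH <- pmin(95, pmax(15, 65 - 35 * (Ta_C - 18) / 16))
  P <- 101.3 * ((293 - 0.0065 * elevation_m) / 293)^5.26
  tab <- data.frame(decimal_hour = prof$decimal_hour, Ta_C = Ta_C,
                    RH_pct = RH, u_ms = 2, P_kPa = P, Rs_Wm2 = Rs,
                    Rs_daily_Wm2 = mean(Rs), rain_mm = 0,
                    ETo_mm = NA_real_)
  sp <- solar_position(lat, lon, doy, acquisition_hour, "utc")
  Ta_acq <- ta_curve(acquisition_hour)
  RH_acq <- pmin(95, pmax(15, 65 - 35 * (Ta_acq - 18) / 16))
  Rs_acq <- peak_Wm2 * cos(sp$zenith_deg * pi / 180) /
    max(prof$cos_zenith)
  meteo <- meteo_state(Ta_acq + 273.15, RH_acq, u = 2, pressure = P,
                       Rs_inst = Rs_acq, Rs_daily_mean = mean(Rs))
  list(table = tab, meteo = meteo, zenith_deg = sp$zenith_deg,
       azimuth_deg = sp$azimuth_deg, doy = doy, lat = lat, lon = lon,
       acquisition_hour = acquisition_hour)
}

# spatially correlated Gaussian field: coarse grid + bilinear upsampling
correlated_noise <- function(nr, nc, cell, sigma, corr_length = 0.5) {
  step <- max(1L, round(corr_length / cell))
  crs <- ceiling(nr / step) + 1
  ccs <- ceiling(nc / step) + 1
  coarse <- matrix(stats::rnorm(crs * ccs, 0, sigma), crs, ccs)
  ri <- (seq_len(nr) - 1) / step + 1
  ci <- (seq_len(nc) - 1) / step + 1
  i0 <- pmin(floor(ri), crs - 1); fi <- ri - i0
  j0 <- pmin(floor(ci), ccs - 1); fj <- ci - j0
  a <- coarse[i0, j0] * outer(1 - fi, 1 - fj) +
    coarse[i0 + 1, j0] * outer(fi, 1 - fj) +
    coarse[i0, j0 + 1] * outer(1 - fi, fj) +
    coarse[i0 + 1, j0 + 1] * outer(fi, fj)
  a
}

#' Generate a synthetic orchard scene bundle
#'
#' Renders a row orchard over a gently sloping terrain: tree crowns as
#' half-ellipsoids on the planting grid (DSM = DTM + crown surface +
#' correlated noise), per-pixel six-band reflectance (crown pixels from the
#' forward reflectance model at the tree's true LAI plus noise, bare soil
#' from the soil spectrum with a sunlit/shadow brightness split on the
#' shaded side of each crown), and a thermal layer in which canopy
#' temperature carries the imposed stress signal
#' (Tc = Ta + 1 + 9 s K) while soil temperature is stress-independent
#' (Ta + 12 K sunlit, Ta + 4 K shaded). Fully reproducible from the seed.
#'
#' @param config orchard_config.
#' @param weather result of \code{\link{generate_weather}}.
#' @param seed RNG seed (defaults to config$seed).
#' @return list of class \code{orchard_scene}: dsm, dtm, thermal
#'   (raster_grid), bands (band_stack), trees (data.frame with grid cells),
#'   truth (data.frame with every generator parameter), weather, config.
#' @export
generate_orchard <- function(config, weather, seed = config$seed) {
  set.seed(seed)
  cfg <- config
  n <- cfg$n_rows * cfg$trees_per_row
  rootstocks <- c("Adesoto", "Cadaman", "Garnem", "GF-677", "IRTA-1",
                  "IRTA-2", "Ishtara", "Rootpac-R", "Rootpac-40",
                  "Rootpac-20")
  treatments <- c("I100", "I50", "I0")
  width <- cfg$trees_per_row * cfg$spacing_row + 2 * cfg$margin
  height <- cfg$n_rows * cfg$spacing_across + 2 * cfg$margin
  truth <- expand.grid(position = seq_len(cfg$trees_per_row),
                       row = seq_len(cfg$n_rows))
  truth$tree_id <- sprintf("T%02d%02d", truth$row, truth$position)
  truth$rootstock <- rootstocks[(truth$position - 1) %% 10 + 1]
  truth$treatment <- treatments[(truth$row - 1) %% 3 + 1]
  truth$x <- cfg$margin + (truth$position - 0.5) * cfg$spacing_row
  truth$y <- cfg$margin + (truth$row - 0.5) * cfg$spacing_across
  truth$height_true <- stats::runif(n, cfg$height_range[1],
                                    cfg$height_range[2])
  truth$LAI_true <- stats::runif(n, cfg$lai_range[1], cfg$lai_range[2])
  truth$crown_radius_true <- stats::runif(n, cfg$crown_radius_range[1],
                                          cfg$crown_radius_range[2])
  truth$stress <- stats::runif(n, cfg$stress_range[1], cfg$stress_range[2])
  truth$insertion_height <- cfg$insertion_height
  Ta <- weather$meteo$Ta
  truth$Tc_true <- Ta + 1 + 9 * truth$stress
  truth$Ts_sunlit_true <- Ta + 12
  truth$Ts_shaded_true <- Ta + 4
  # leaf parameters shared by all trees (one cultivar)
  leaf <- list(N_leaf = 1.6, Cab = 40, Car = 10, Cbrown = 0.05,
               Cw = 0.007, Cdm = 0.007, average_leaf_angle_deg = 57,
               hotspot = 0.2)

  render <- function(cell) {
    nc <- round(width / cell); nr <- round(height / cell)
    xs <- (seq_len(nc) - 0.5) * cell
    ys <- height - (seq_len(nr) - 0.5) * cell   # row 1 = north
    list(nr = nr, nc = nc, xs = xs, ys = ys)
  }
  ms <- render(cfg$cell_ms)
  th <- render(cfg$cell_thermal)
  origin <- c(0, height)

  # crown surface and per-pixel tree ownership at a given resolution
  crown_fields <- function(g) {
    surf <- matrix(0, g$nr, g$nc)
    owner <- matrix(0L, g$nr, g$nc)
    shadow <- matrix(FALSE, g$nr, g$nc)
    sh_len <- truth$height_true * tan(weather$zenith_deg * pi / 180)
    for (k in seq_len(n)) {
      R <- truth$crown_radius_true[k]
      jx <- which(abs(g$xs - truth$x[k]) <= R)
      iy <- which(abs(g$ys - truth$y[k]) <= R)
      if (length(jx) == 0 || length(iy) == 0) next
      dx <- (g$xs[jx] - truth$x[k]) / R
      dy <- (g$ys[iy] - truth$y[k]) / R
      d2 <- outer(dy^2, dx^2, "+")
      inside <- d2 < 1
      z <- truth$height_true[k] * sqrt(pmax(0, 1 - d2))
      cur <- surf[iy, jx]
      upd <- inside & z > cur
      cur[upd] <- z[upd]
      surf[iy, jx] <- cur
      ow <- owner[iy, jx]; ow[upd] <- k; owner[iy, jx] <- ow
      # cast shadow toward the anti-solar azimuth (north side for a
      # southern sun)
      sx <- which(abs(g$xs - truth$x[k]) <= 0.8 * R)
      sy <- which(g$ys - truth$y[k] > 0 &
                    g$ys - truth$y[k] <= R + sh_len[k])
      if (length(sx) > 0 && length(sy) > 0) shadow[sy, sx] <- TRUE
    }
    list(surf = surf, owner = owner, shadow = shadow & owner == 0)
  }
  fms <- crown_fields(ms)
  fth <- crown_fields(th)

  # terrain and surface models (multispectral resolution)
  dtm_v <- 100 + 0.005 * outer(rep(1, ms$nr), ms$xs) +
    0.003 * outer(ms$ys, rep(1, ms$nc)) +
    correlated_noise(ms$nr, ms$nc, cfg$cell_ms, 0.01, 2)
  dsm_v <- dtm_v + fms$surf +
    correlated_noise(ms$nr, ms$nc, cfg$cell_ms, cfg$sigma_dsm, 0.5)
  dtm <- raster_grid(dtm_v, cfg$cell_ms, origin = origin, crs_tag = "local")
  dsm <- raster_grid(dsm_v, cfg$cell_ms, origin = origin, crs_tag = "local")

  # six-band reflectance
  crown_spec <- vapply(seq_len(n), function(k) {
    rt_forward(c(leaf, LAI = truth$LAI_true[k]),
               zenith_deg = weather$zenith_deg,
               soil = cfg$soil_spectrum)$reflectance
  }, numeric(6))
  bands <- vector("list", 6)
  for (b in 1:6) {
    v <- matrix(cfg$soil_spectrum[b], ms$nr, ms$nc)
    v[fms$shadow] <- cfg$soil_spectrum[b] * 0.4
    ow <- fms$owner
    sel <- ow > 0
    v[sel] <- crown_spec[b, ow[sel]]
    v <- v + matrix(stats::rnorm(length(v), 0, cfg$sigma_reflectance),
                    ms$nr, ms$nc)
    v <- pmin(pmax(v, 0.001), 0.999)
    bands[[b]] <- raster_grid(v, cfg$cell_ms, origin = origin,
                              crs_tag = "local")
  }

  # thermal layer
  tv <- matrix(Ta + 12, th$nr, th$nc)
  tv[fth$shadow] <- Ta + 4
  selt <- fth$owner > 0
  tv[selt] <- truth$Tc_true[fth$owner[selt]]
  tv <- tv + matrix(stats::rnorm(length(tv), 0, cfg$sigma_thermal),
                    th$nr, th$nc)
  thermal <- raster_grid(tv, cfg$cell_thermal, origin = origin,
                         crs_tag = "local")

  trees <- tree_grid_cells(
    truth[, c("tree_id", "row", "position", "rootstock", "treatment",
              "x", "y", "insertion_height")],
    cfg$spacing_row, cfg$spacing_across)
  structure(list(dsm = dsm, dtm = dtm, thermal = thermal,
                 bands = band_stack(bands), trees = trees, truth = truth,
                 weather = weather, config = cfg, leaf_params = leaf),
            class = "orchard_scene")
}

#' Write / read a scene bundle on disk
#'
#' Layout: \code{dsm.asc, dtm.asc, thermal.asc, band_1.asc ... band_6.asc,
#' trees.csv, truth.csv, weather.csv, config.yaml} (all plain text).
#'
#' @param scene orchard_scene.
#' @param dir bundle directory.
#' @return invisibly the directory (save) / orchard_scene (load; the
#'   weather meteo state is rebuilt from config.yaml).
#' @export
save_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  raster_write_asc(scene$dsm, file.path(dir, "dsm.asc"))
  raster_write_asc(scene$dtm, file.path(dir, "dtm.asc"))
  raster_write_asc(scene$thermal, file.path(dir, "thermal.asc"))
  for (b in 1:6)
    raster_write_asc(scene$bands$bands[[b]],
                     file.path(dir, sprintf("band_%d.asc", b)))
  utils::write.csv(scene$trees, file.path(dir, "trees.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$weather$table, file.path(dir, "weather.csv"),
                   row.names = FALSE)
  cfg <- scene$config
  yaml::write_yaml(list(config = cfg[setdiff(names(cfg), "")],
                        weather = scene$weather[c("doy", "lat", "lon",
                                                  "acquisition_hour")],
                        leaf_params = scene$leaf_params,
                        band_centers_nm = scene$bands$centers_nm),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname save_scene
#' @export
load_scene <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- do.call(orchard_config, meta$config[names(meta$config) %in%
                                               names(formals(orchard_config))])
  w <- meta$weather
  weather <- generate_weather(w$doy, w$lat, w$lon, seed = cfg$seed,
                              acquisition_hour = w$acquisition_hour)
  weather$table <- utils::read.csv(file.path(dir, "weather.csv"))
  bands <- lapply(1:6, function(b)
    raster_read_asc(file.path(dir, sprintf("band_%d.asc", b))))
  structure(list(dsm = raster_read_asc(file.path(dir, "dsm.asc")),
                 dtm = raster_read_asc(file.path(dir, "dtm.asc")),
                 thermal = raster_read_asc(file.path(dir, "thermal.asc")),
                 bands = band_stack(bands, meta$band_centers_nm),
                 trees = utils::read.csv(file.path(dir, "trees.csv")),
                 truth = utils::read.csv(file.path(dir, "truth.csv")),
                 weather = weather, config = cfg,
                 leaf_params = meta$leaf_params),
            class = "orchard_scene")
}
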