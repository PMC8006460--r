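# small in-code fixtures shared across test files

# uniform-valued raster, 1 m cells, origin at (0, nrows)
uniform_raster <- function(nr, nc, value, cell = 1, nodata = -9999) {
  raster_grid(matrix(value, nr, nc), cell, origin = c(0, nr * cell),
              nodata = nodata)
}

# one tree whose 4.5 x 5.0 m cell sits fully inside a raster extent
single_tree <- function(x = 5, y = 5) {
  tree_grid_cells(data.frame(tree_id = "T1", x = x, y = y))
}

# tiny scene: flat soil, gaussian-dome crowns at given centers, six bands
# consistent with the forward model at the given LAIs; no noise
toy_scene <- function(centers, heights, radii, lais,
                      extent = c(20, 15), cell = 0.25) {
  nc <- round(extent[1] / cell); nr <- round(extent[2] / cell)
  xs <- (seq_len(nc) - 0.5) * cell
  ys <- extent[2] - (seq_len(nr) - 0.5) * cell
  surf <- matrix(0, nr, nc)
  owner <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(centers))) {
    dx <- outer(rep(1, nr), (xs - centers$x[k]) / radii[k])
    dy <- outer((ys - centers$y[k]) / radii[k], rep(1, nc))
    d2 <- dx^2 + dy^2
    z <- heights[k] * sqrt(pmax(0, 1 - d2))
    upd <- d2 < 1 & z > surf
    surf[upd] <- z[upd]
    owner[upd] <- k
  }
  origin <- c(0, extent[2])
  dtm <- raster_grid(matrix(50, nr, nc), cell, origin = origin)
  dsm <- raster_grid(50 + surf, cell, origin = origin)
  soil <- rt_default_soil()
  leaf <- list(N_leaf = 1.6, Cab = 40, Car = 10, Cbrown = 0.05,
               Cw = 0.007, Cdm = 0.007, average_leaf_angle_deg = 57,
               hotspot = 0.2)
  spec <- vapply(lais, function(L)
    rt_forward(c(leaf, LAI = L), zenith_deg = 20, soil = soil)$reflectance,
    numeric(6))
  bands <- lapply(1:6, function(b) {
    v <- matrix(soil[b], nr, nc)
    v[owner > 0] <- spec[b, owner[owner > 0]]
    raster_grid(v, cell, origin = origin)
  })
  trees <- tree_grid_cells(cbind(data.frame(tree_id = sprintf(
    "T%02d", seq_len(nrow(centers)))), centers))
  list(dsm = dsm, dtm = dtm, bands = band_stack(bands), trees = trees,
       owner = owner, surf = surf, cell = cell)
}

# default meteorology used by flux tests: hot dry midday
midday_meteo <- function(Ta_C = 33.4, RH = 30, u = 2, Rs = 930,
                         Rs_daily = 280) {
  meteo_state(Ta_C + 273.15, RH, u = u, pressure = 97.5,
              Rs_inst = Rs, Rs_daily_mean = Rs_daily)
}
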