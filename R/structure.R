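#' Canopy height model from DSM and DTM
#'
#' CHM = max(DSM - DTM, 0); nodata in either layer propagates.
#'
#' @param dsm,dtm co-registered raster_grid layers (m).
#' @return raster_grid of canopy height (m).
#' @export
compute_chm <- function(dsm, dtm) {
  if (!same_grid(dsm, dtm)) stop("DSM and DTM grids differ")
  v <- pmax(raster_values(dsm) - raster_values(dtm), 0)
  v[is.na(v)] <- dsm$nodata
  raster_grid(v, dsm$cell_size_x, dsm$cell_size_y, dsm$origin,
              nodata = dsm$nodata, crs_tag = dsm$crs_tag)
}

#' Scene classification into vegetation, weed and soil classes
#'
#' Deterministic threshold rule: vegetation when NDVI >= ndvi_veg and
#' CHM >= h_canopy; weed when NDVI >= ndvi_veg but the surface is low;
#' remaining pixels split into sunlit vs shaded bare soil on NIR brightness.
#'
#' @param bands band_stack (CHM is resampled to its grid if needed).
#' @param chm raster_grid of canopy height (m).
#' @param thresholds list with ndvi_veg (default 0.4), h_canopy (m, default
#'   0.3) and nir_shadow (default 0.15).
#' @return list of class \code{scene_classification} with \code{classes}
#'   (raster_grid of integer codes) and \code{labels} (code -> name map:
#'   1 vegetation, 2 weed, 3 sunlit_soil, 4 shaded_soil).
#' @export
classify_scene <- function(bands, chm,
                           thresholds = list(ndvi_veg = 0.4, h_canopy = 0.3,
                                             nir_shadow = 0.15)) {
  th <- utils::modifyList(list(ndvi_veg = 0.4, h_canopy = 0.3,
                               nir_shadow = 0.15), thresholds)
  ref <- bands$bands[[1]]
  if (!same_grid(chm, ref)) chm <- raster_resample_nearest(chm, ref)
  red <- raster_values(bands$bands[[3]])
  nir <- raster_values(bands$bands[[6]])
  h <- raster_values(chm)
  ndvi <- (nir - red) / (nir + red)
  cls <- matrix(NA_real_, nrow(red), ncol(red))
  veg <- ndvi >= th$ndvi_veg & h >= th$h_canopy
  weed <- ndvi >= th$ndvi_veg & h < th$h_canopy
  sun <- ndvi < th$ndvi_veg & nir >= th$nir_shadow
  sha <- ndvi < th$ndvi_veg & nir < th$nir_shadow
  cls[which(veg)] <- 1; cls[which(weed)] <- 2
  cls[which(sun)] <- 3; cls[which(sha)] <- 4
  cls[is.na(cls)] <- ref$nodata
  structure(list(classes = raster_grid(cls, ref$cell_size_x, ref$cell_size_y,
                                       ref$origin, nodata = ref$nodata,
                                       crs_tag = ref$crs_tag),
                 labels = c(vegetation = 1, weed = 2, sunlit_soil = 3,
                            shaded_soil = 4)),
            class = "scene_classification")
}

#' Class mask as a logical matrix
#' @param classes scene_classification.
#' @param which_class one of "vegetation", "weed", "sunlit_soil",
#'   "shaded_soil", or "soil" (sunlit + shaded).
#' @return logical matrix.
#' @export
class_mask <- function(classes, which_class) {
  v <- raster_values(classes$classes)
  if (which_class == "soil") v %in% c(3, 4) & !is.na(v)
  else !is.na(v) & v == classes$labels[[which_class]]
}

#' Marker-controlled watershed crown delineation
#'
#' Seeded watershed (region growing on the inverted CHM via
#' \code{EBImage::propagate}) restricted to vegetation pixels, one marker per
#' tree at its mapped center. A marker falling on a non-vegetation pixel is
#' snapped to the nearest vegetation pixel within 1 m; failing that the tree
#' gets an empty crown and a flag. Each crown is clipped to a 1.5x dilation
#' of its own grid cell.
#'
#' @param classes scene_classification.
#' @param chm raster_grid of canopy height on the same grid.
#' @param trees data.frame from \code{\link{tree_grid_cells}}.
#' @return list with \code{labels} (raster_grid; value k = crown of
#'   trees[k, ], 0 = background) and \code{flags} (character per tree,
#'   "empty_crown" where no vegetation was reachable).
#' @export
segment_crowns <- function(classes, chm, trees) {
  grid <- classes$classes
  if (!same_grid(chm, grid)) chm <- raster_resample_nearest(chm, grid)
  veg <- class_mask(classes, "vegetation")
  cen <- raster_centers(grid)
  nr <- nrow(veg); nc <- ncol(veg)
  n <- nrow(trees)
  seeds <- matrix(0L, nr, nc)
  flags <- character(n)
  ord <- order(trees$tree_id)          # deterministic marker indexing
  vidx <- which(veg, arr.ind = TRUE)
  for (k in ord) {
    j <- which.min(abs(cen$x - trees$x[k]))
    i <- which.min(abs(cen$y - trees$y[k]))
    if (!veg[i, j]) {
      if (nrow(vidx) > 0) {
        d2 <- (cen$x[vidx[, 2]] - trees$x[k])^2 +
          (cen$y[vidx[, 1]] - trees$y[k])^2
        m <- which.min(d2)
        if (d2[m] <= 1) { i <- vidx[m, 1]; j <- vidx[m, 2] } else i <- NA
      } else i <- NA
    }
    if (is.na(i)) { flags[k] <- "empty_crown"; next }
    if (seeds[i, j] == 0) seeds[i, j] <- k
  }
  h <- raster_values(chm); h[is.na(h)] <- 0
  inv <- max(h) - h                    # watershed floods low values first
  lab <- if (any(seeds > 0)) {
    img <- EBImage::Image(t(inv))      # EBImage is column-major x, y
    sd_img <- EBImage::Image(t(seeds))
    msk <- EBImage::Image(t(veg * 1))
    t(EBImage::imageData(EBImage::propagate(img, sd_img, mask = msk)))
  } else matrix(0, nr, nc)
  lab[!veg] <- 0
  # clip each crown to 1.5x its grid cell
  for (k in seq_len(n)) {
    px <- which(lab == k, arr.ind = TRUE)
    if (nrow(px) == 0) { if (flags[k] == "") flags[k] <- "empty_crown"; next }
    hw <- 1.5 * (trees$cell_xmax[k] - trees$cell_xmin[k]) / 2
    hh <- 1.5 * (trees$cell_ymax[k] - trees$cell_ymin[k]) / 2
    keep <- abs(cen$x[px[, 2]] - trees$x[k]) <= hw &
      abs(cen$y[px[, 1]] - trees$y[k]) <= hh
    lab[px[!keep, , drop = FALSE]] <- 0
  }
  list(labels = raster_grid(lab, grid$cell_size_x, grid$cell_size_y,
                            grid$origin, nodata = -1,
                            crs_tag = grid$crs_tag),
       flags = flags)
}

#' Per-tree architectural metrics from the CHM and crown labels
#'
#' Crown area is pixel count times cell area; total canopy volume sums
#' CHM times cell area over crown pixels; net volume subtracts the prism
#' between the ground and the branch-insertion height under the crown
#' footprint, floored at zero.
#'
#' @param crowns result of \code{\link{segment_crowns}}.
#' @param chm raster_grid of canopy height on the same grid.
#' @param trees data.frame; an insertion_height column is used when present
#'   (default 0.8 m).
#' @return data.frame with tree_id, height_max, height_mean, crown_area,
#'   volume_total, volume_net, n_pixels, flag.
#' @export
tree_structure_metrics <- function(crowns, chm, trees) {
  lab <- raster_values(crowns$labels)
  if (!same_grid(chm, crowns$labels))
    chm <- raster_resample_nearest(chm, crowns$labels)
  h <- raster_values(chm)
  ca <- crowns$labels$cell_size_x * crowns$labels$cell_size_y
  ins <- if ("insertion_height" %in% names(trees))
    trees$insertion_height else rep(0.8, nrow(trees))
  out <- data.frame(tree_id = trees$tree_id, height_max = 0, height_mean = 0,
                    crown_area = 0, volume_total = 0, volume_net = 0,
                    n_pixels = 0L, flag = "", stringsAsFactors = FALSE)
  for (k in seq_len(nrow(trees))) {
    hk <- h[!is.na(lab) & lab == k]
    hk <- hk[!is.na(hk)]
    if (length(hk) == 0) { out$flag[k] <- "empty_crown"; next }
    out$n_pixels[k] <- length(hk)
    out$height_max[k] <- max(hk)
    out$height_mean[k] <- mean(hk)
    out$crown_area[k] <- length(hk) * ca
    out$volume_total[k] <- sum(hk) * ca
    out$volume_net[k] <- max(0, out$volume_total[k] -
                               out$crown_area[k] * ins[k])
  }
  out
}
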