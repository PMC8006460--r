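#' Georeferenced raster grid
#'
#' A minimal in-memory raster: a numeric matrix with square or rectangular
#' cells, the map coordinates of the upper-left corner, a nodata sentinel and
#' an opaque CRS tag. Row 1 is the northernmost row; pixel (i, j) (row, col)
#' has its center at
#' \code{origin + ((j - 0.5) * cell_size_x, -(i - 0.5) * cell_size_y)}.
#'
#' @param values numeric matrix (rows = north to south).
#' @param cell_size_x,cell_size_y cell size in map units (m), > 0.
#' @param origin length-2 numeric, map x/y of the upper-left corner.
#' @param nodata sentinel value marking invalid cells.
#' @param crs_tag opaque CRS string; "" means unknown.
#' @return object of class \code{raster_grid}.
#' @export
raster_grid <- function(values, cell_size_x, cell_size_y = cell_size_x,
                        origin = c(0, 0), nodata = -9999, crs_tag = "") {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) >= 1, ncol(values) >= 1,
            length(origin) == 2)
  if (!is.finite(cell_size_x) || !is.finite(cell_size_y) ||
      cell_size_x <= 0 || cell_size_y <= 0)
    stop("cell sizes must be positive")
  structure(list(values = values,
                 cell_size_x = as.numeric(cell_size_x),
                 cell_size_y = as.numeric(cell_size_y),
                 origin = as.numeric(origin),
                 nodata = as.numeric(nodata),
                 crs_tag = as.character(crs_tag)),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d px, cell %.4g x %.4g m, origin (%.6g, %.6g)\n",
              nrow(x$values), ncol(x$values), x$cell_size_x, x$cell_size_y,
              x$origin[1], x$origin[2]))
  v <- raster_values(x)
  cat(sprintf("  valid px: %d, range [%.4g, %.4g], nodata = %g, crs = '%s'\n",
              sum(!is.na(v)), suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), x$nodata, x$crs_tag))
  invisible(x)
}

#' Valid-data mask of a raster
#'
#' @param r raster_grid.
#' @return logical matrix, TRUE where valid (not the nodata sentinel, not NA).
#' @export
raster_mask <- function(r) {
  !(is.na(r$values) | r$values == r$nodata)
}

#' Values with nodata replaced by NA
#' @param r raster_grid.
#' @return numeric matrix.
#' @export
raster_values <- function(r) {
  v <- r$values
  v[!raster_mask(r)] <- NA_real_
  v
}

#' Map coordinates of pixel centers
#'
#' @param r raster_grid.
#' @return list with vectors \code{x} (length ncol) and \code{y} (length nrow).
#' @export
raster_centers <- function(r) {
  list(x = r$origin[1] + (seq_len(ncol(r$values)) - 0.5) * r$cell_size_x,
       y = r$origin[2] - (seq_len(nrow(r$values)) - 0.5) * r$cell_size_y)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$cell_size_x - b$cell_size_x) < tol &&
    abs(a$cell_size_y - b$cell_size_y) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

#' Read or write a raster in Esri ASCII grid format
#'
#' Text raster interchange: `ncols/nrows/xllcorner/yllcorner/cellsize` (or
#' `dx`/`dy` for rectangular cells) header, `NODATA_value`, then rows north to
#' south. A CRS tag, when present, travels in a `.prj` sidecar next to the
#' grid. Values are written with 17 significant digits so a write-then-read
#' roundtrip is bit-exact for doubles.
#'
#' @param path_or_raster file path (read) or raster_grid (write).
#' @param mode "read" or "write".
#' @param path output path when mode = "write".
#' @return raster_grid (read) or invisibly the path written (write).
#' @export
raster_io <- function(path_or_raster, mode = c("read", "write"), path = NULL) {
  mode <- match.arg(mode)
  if (mode == "read") raster_read_asc(path_or_raster)
  else raster_write_asc(path_or_raster, path)
}

#' @rdname raster_io
#' @export
raster_read_asc <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!(key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                     "cellsize", "dx", "dy", "nodata_value"))) break
    hdr[[key]] <- as.numeric(parts[2]); i <- i + 1
  }
  csx <- if (!is.null(hdr$dx)) hdr$dx else hdr$cellsize
  csy <- if (!is.null(hdr$dy)) hdr$dy else hdr$cellsize
  nod <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("grid body does not match ncols x nrows")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  origin <- c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * csy)
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  crs <- if (file.exists(prj)) paste(readLines(prj, warn = FALSE),
                                     collapse = "\n") else {
    warning("no CRS sidecar for ", basename(path), "; using unit-cell fallback tag")
    ""
  }
  raster_grid(m, csx, csy, origin, nodata = nod, crs_tag = crs)
}

#' @rdname raster_io
#' @export
raster_write_asc <- function(r, path) {
  stopifnot(inherits(r, "raster_grid"))
  nr <- nrow(r$values); nc <- ncol(r$values)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
               sprintf("xllcorner %.17g", r$origin[1]),
               sprintf("yllcorner %.17g", r$origin[2] - nr * r$cell_size_y)),
             con)
  if (r$cell_size_x == r$cell_size_y) {
    writeLines(sprintf("cellsize %.17g", r$cell_size_x), con)
  } else {
    writeLines(c(sprintf("dx %.17g", r$cell_size_x),
                 sprintf("dy %.17g", r$cell_size_y)), con)
  }
  writeLines(sprintf("NODATA_value %.17g", r$nodata), con)
  body <- r$values
  body[is.na(body)] <- r$nodata
  writeLines(apply(body, 1, function(row)
    paste(sprintf("%.17g", row), collapse = " ")), con)
  if (nzchar(r$crs_tag))
    writeLines(r$crs_tag, paste0(tools::file_path_sans_ext(path), ".prj"))
  invisible(path)
}

#' Nearest-neighbor resampling onto a target grid
#'
#' Used to align the coarser thermal layer with the finer multispectral grid
#' (or vice versa) when a per-pixel operation needs both.
#'
#' @param src raster_grid to resample.
#' @param target raster_grid defining the output geometry.
#' @return raster_grid on the target geometry with src values.
#' @export
raster_resample_nearest <- function(src, target) {
  ct <- raster_centers(target)
  cs <- raster_centers(src)
  j <- pmin(pmax(round((ct$x - src$origin[1]) / src$cell_size_x + 0.5), 1),
            ncol(src$values))
  i <- pmin(pmax(round((src$origin[2] - ct$y) / src$cell_size_y + 0.5), 1),
            nrow(src$values))
  out <- src$values[i, j, drop = FALSE]
  # centers falling outside the source extent become nodata
  outside_x <- ct$x < cs$x[1] - src$cell_size_x / 2 |
    ct$x > cs$x[length(cs$x)] + src$cell_size_x / 2
  outside_y <- ct$y > cs$y[1] + src$cell_size_y / 2 |
    ct$y < cs$y[length(cs$y)] - src$cell_size_y / 2
  out[outside_y, ] <- src$nodata
  out[, outside_x] <- src$nodata
  raster_grid(out, target$cell_size_x, target$cell_size_y, target$origin,
              nodata = src$nodata, crs_tag = src$crs_tag)
}

#' Six-band reflectance stack
#'
#' @param bands list of six raster_grid layers on a common grid,
#'   reflectance in [0, 1] or nodata.
#' @param centers_nm the six band-center wavelengths, strictly increasing.
#' @return object of class \code{band_stack}.
#' @export
band_stack <- function(bands, centers_nm = orchardet_band_centers()) {
  stopifnot(length(bands) == 6, length(centers_nm) == 6,
            all(diff(centers_nm) > 0))
  for (b in bands[-1]) if (!same_grid(bands[[1]], b))
    stop("all bands must share one grid")
  for (b in bands) {
    v <- raster_values(b)
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("reflectance outside [0, 1]")
  }
  structure(list(bands = bands, centers_nm = as.numeric(centers_nm)),
            class = "band_stack")
}

#' Band-center wavelengths of the six-band camera (nm)
#' @return numeric vector of length 6.
#' @export
orchardet_band_centers <- function() c(515.3, 570.9, 682.2, 710.5, 781.1, 871.8)

#' Build per-tree rectangular grid cells
#'
#' Lays the 4.5 m (within-row) x 5.0 m (across-rows) sampling rectangle
#' around each tree center, with the 4.5 m side along the row direction (x).
#' Cells of distinct trees must not overlap.
#'
#' @param trees data.frame with columns tree_id, x, y (map coords of the
#'   tree center) and optionally row, position, rootstock, treatment,
#'   insertion_height.
#' @param spacing_row within-row tree spacing (m), default 4.5.
#' @param spacing_across row-to-row spacing (m), default 5.0.
#' @return the input with cell_xmin/xmax/ymin/ymax columns appended.
#' @export
tree_grid_cells <- function(trees, spacing_row = 4.5, spacing_across = 5.0) {
  stopifnot(all(c("tree_id", "x", "y") %in% names(trees)))
  trees$cell_xmin <- trees$x - spacing_row / 2
  trees$cell_xmax <- trees$x + spacing_row / 2
  trees$cell_ymin <- trees$y - spacing_across / 2
  trees$cell_ymax <- trees$y + spacing_across / 2
  area <- (trees$cell_xmax - trees$cell_xmin) *
    (trees$cell_ymax - trees$cell_ymin)
  stopifnot(all(abs(area - spacing_row * spacing_across) < 1e-6))
  n <- nrow(trees)
  if (n > 1) {
    ov <- function(a1, a2, b1, b2) (a1 < b2 - 1e-9) & (b1 < a2 - 1e-9)
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      bad <- ov(trees$cell_xmin[i], trees$cell_xmax[i],
                trees$cell_xmin[j], trees$cell_xmax[j]) &
        ov(trees$cell_ymin[i], trees$cell_ymax[i],
           trees$cell_ymin[j], trees$cell_ymax[j])
      if (any(bad)) stop("overlapping tree grid cells")
    }
  }
  trees
}

#' Per-tree zonal statistics
#'
#' Summarizes raster values over each tree's grid cell. A pixel belongs to a
#' cell when its center falls inside the half-open rectangle
#' \code{[xmin, xmax) x [ymin, ymax)} (min edges inclusive, max edges
#' exclusive), so adjacent cells never share a pixel.
#'
#' @param raster raster_grid to summarize.
#' @param trees data.frame from \code{\link{tree_grid_cells}}.
#' @param mask optional logical matrix (or raster_grid of 0/1) on the same
#'   grid; only TRUE/1 pixels are used. A mask on a different grid is
#'   resampled by nearest neighbor first.
#' @param statistic one of "mean", "max", "sum", "count".
#' @return data.frame with tree_id, value, n (valid pixel count) and flag
#'   ("empty" when no valid pixel; value is NA then).
#' @export
zonal_stats <- function(raster, trees, mask = NULL,
                        statistic = c("mean", "max", "sum", "count")) {
  statistic <- match.arg(statistic)
  cen <- raster_centers(raster)
  vals <- raster_values(raster)
  keep <- raster_mask(raster)
  if (!is.null(mask)) {
    if (inherits(mask, "raster_grid")) {
      if (!same_grid(mask, raster))
        mask <- raster_resample_nearest(mask, raster)
      mask <- raster_values(mask) > 0 & !is.na(raster_values(mask))
    }
    stopifnot(all(dim(mask) == dim(vals)))
    keep <- keep & mask
  }
  out <- data.frame(tree_id = trees$tree_id,
                    value = NA_real_, n = 0L, flag = "",
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(trees))) {
    jx <- which(cen$x >= trees$cell_xmin[k] - 1e-12 &
                  cen$x < trees$cell_xmax[k] - 1e-12)
    iy <- which(cen$y >= trees$cell_ymin[k] - 1e-12 &
                  cen$y < trees$cell_ymax[k] - 1e-12)
    if (length(jx) == 0 || length(iy) == 0) { out$flag[k] <- "empty"; next }
    sel <- keep[iy, jx, drop = FALSE]
    v <- vals[iy, jx, drop = FALSE][sel]
    out$n[k] <- length(v)
    if (length(v) == 0) { out$flag[k] <- "empty"; next }
    out$value[k] <- switch(statistic,
                           mean = mean(v), max = max(v),
                           sum = sum(v), count = as.numeric(length(v)))
  }
  if (statistic == "count") out$value[out$flag == "empty"] <- 0
  out
}
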