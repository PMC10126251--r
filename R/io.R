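# Raster and tabular output: ESRI ASCII grids, patch layouts, run outputs.

#' Resample a field from the graded grid to a uniform raster
#'
#' Nearest-neighbor sampling at uniform cell centers, as needed for ESRI
#' ASCII export (which requires square cells).
#'
#' @param field nx x ny matrix on `grid`.
#' @param grid `flood_grid`.
#' @param cellsize uniform cell size (m).
#' @return list: `values` (ncol x nrow matrix, x along rows), `cellsize`.
#' @export
resample_uniform <- function(field, grid, cellsize = 0.5) {
  xs <- seq(cellsize / 2, grid$domain[1] - cellsize / 2, by = cellsize)
  ys <- seq(cellsize / 2, grid$domain[2] - cellsize / 2, by = cellsize)
  ix <- pmin(pmax(findInterval(xs, grid$xe, all.inside = TRUE), 1), grid$nx)
  iy <- pmin(pmax(findInterval(ys, grid$ye, all.inside = TRUE), 1), grid$ny)
  list(values = field[ix, iy, drop = FALSE], cellsize = cellsize,
       x = xs, y = ys)
}

#' Write a matrix as an ESRI ASCII grid
#'
#' @param values matrix with x along rows, y along columns (south to north).
#' @param file output path.
#' @param cellsize cell size (m).
#' @param xll,yll lower-left corner coordinates.
#' @param nodata NODATA value.
#' @export
write_esri_ascii <- function(values, file, cellsize, xll = 0, yll = 0,
                             nodata = -9999) {
  v <- values
  v[!is.finite(v)] <- nodata
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nrow(v)), paste("nrows", ncol(v)),
    paste("xllcorner", xll), paste("yllcorner", yll),
    paste("cellsize", cellsize), paste("NODATA_value", nodata)), con)
  for (j in rev(seq_len(ncol(v))))  # rows run north -> south
    writeLines(paste(formatC(v[, j], format = "g", digits = 8),
                     collapse = " "), con)
  invisible(file)
}

#' Read an ESRI ASCII grid
#' @param file path.
#' @return list: `values` (x along rows), `cellsize`, `xll`, `yll`.
#' @export
read_esri_ascii <- function(file) {
  hdr <- readLines(file, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  g <- as.numeric(kv[, 2]); names(g) <- tolower(kv[, 1])
  dat <- scan(file, skip = 6, quiet = TRUE)
  m <- matrix(dat, nrow = g[["ncols"]], ncol = g[["nrows"]])
  m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  m[m == g[["nodata_value"]]] <- NA
  list(values = m, cellsize = g[["cellsize"]], xll = g[["xllcorner"]],
       yll = g[["yllcorner"]])
}

#' Write a patch layout as CSV (x, y, diameter)
#' @param patches `root_patch` or list of them.
#' @param file path.
#' @export
write_patch_csv <- function(patches, file) {
  if (inherits(patches, "root_patch")) patches <- list(patches)
  df <- do.call(rbind, lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    data.frame(patch = i, x = p$centers[, 1], y = p$centers[, 2],
               diameter = p$diameter)
  }))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write the outputs of a flood run to a directory
#'
#' Final bed elevation, depth and the obstacle mask as ESRI ASCII rasters
#' (resampled to a uniform grid), probe time series and tidy metrics as
#' CSV, layout as CSV, manifest as JSON.
#'
#' @param run `flood_run`.
#' @param dir output directory (created).
#' @param cellsize raster resampling cell size (m).
#' @export
write_run_outputs <- function(run, dir, cellsize = 0.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rz <- resample_uniform(run$flow$z, run$grid, cellsize)
  write_esri_ascii(rz$values, file.path(dir, "bed_elevation.asc"), cellsize)
  rh <- resample_uniform(run$flow$h, run$grid, cellsize)
  write_esri_ascii(rh$values, file.path(dir, "depth.asc"), cellsize)
  rm_ <- resample_uniform(run$grid$mask * 1.0, run$grid, cellsize)
  write_esri_ascii(rm_$values, file.path(dir, "obstacle_mask.asc"), cellsize)
  utils::write.csv(run$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(run$probes))
    utils::write.csv(run$probes, file.path(dir, "probes.csv"),
                     row.names = FALSE)
  write_patch_csv(run$scenario$patches, file.path(dir, "patches.csv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
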