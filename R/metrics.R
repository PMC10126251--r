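# Analysis metrics: viable downstream area, percent velocity change,
# bar-peak distance, optimum detection, cooperativity normalization.

#' Default downstream analysis region for a patch
#'
#' Rectangle from the patch trailing edge to `length_PL` patch lengths
#' downstream, spanning the full cross-stream width (1 PL = 5 m).
#'
#' @param grid `flood_grid`.
#' @param patch `root_patch`.
#' @param length_PL downstream extent in patch lengths.
#' @param PL patch length unit (m).
#' @return c(xmin, xmax, ymin, ymax).
#' @export
downstream_region <- function(grid, patch, length_PL = 10, PL = 5) {
  xe <- patch$center[1] + patch$patch_diameter / 2
  c(xe, min(xe + length_PL * PL, grid$domain[1]), 0, grid$domain[2])
}

#' Viable downstream area above an elevation threshold
#'
#' Total area of unmasked cells inside `region` whose bed elevation is at or
#' above `threshold`.
#'
#' @param z bed-elevation matrix (m).
#' @param grid `flood_grid`.
#' @param threshold elevation threshold (m).
#' @param region c(xmin, xmax, ymin, ymax) analysis rectangle (m).
#' @return area (m^2).
#' @export
viable_area <- function(z, grid, threshold, region) {
  if (region[1] > grid$domain[1] || region[3] > grid$domain[2] ||
      region[2] < 0 || region[4] < 0)
    stop("analysis region lies outside the domain")
  inx <- grid$xc >= region[1] & grid$xc <= region[2]
  iny <- grid$yc >= region[3] & grid$yc <= region[4]
  A <- cell_areas(grid)
  sel <- outer(inx, iny) & z >= threshold & grid$mask == 0L
  sum(A[sel])
}

#' Percent velocity change across a vegetation patch
#'
#' `100 (1 - <|V|>_downstream / <|V|>_upstream)`, where the downstream
#' window is one patch diameter deep directly behind the trailing edge and
#' one diameter wide, and the upstream window is the same size centered
#' `upstream_D` patch diameters upstream of the patch center.
#'
#' @param u,v velocity matrices (m/s).
#' @param grid `flood_grid`.
#' @param patch `root_patch`.
#' @param upstream_D upstream window offset in patch diameters.
#' @return percent velocity change (positive = slowed wake).
#' @export
percent_velocity_change <- function(u, v, grid, patch, upstream_D = 4) {
  D <- patch$patch_diameter
  cx <- patch$center[1]; cy <- patch$center[2]
  win_mean <- function(x0, x1, y0, y1) {
    sel <- outer(grid$xc >= x0 & grid$xc <= x1,
                 grid$yc >= y0 & grid$yc <= y1) & grid$mask == 0L
    if (!any(sel)) stop("velocity window contains no wet cells")
    A <- cell_areas(grid)
    sum((sqrt(u^2 + v^2) * A)[sel]) / sum(A[sel])
  }
  down <- win_mean(cx + D / 2, cx + 3 * D / 2, cy - D / 2, cy + D / 2)
  upx <- cx - upstream_D * D
  if (upx - D / 2 < 0) upx <- D / 2  # clamp window into the domain
  up <- win_mean(upx - D / 2, upx + D / 2, cy - D / 2, cy + D / 2)
  if (up <= 0) stop("zero upstream velocity: percent change undefined")
  100 * (1 - down / up)
}

#' Streamwise distance from the patch to the downstream bar peak
#'
#' Averages the bed elevation over a centerline band one patch diameter wide
#' and finds the streamwise maximum downstream of the trailing edge. The
#' distance (trailing edge to argmax) is reported in patch lengths
#' (1 PL = 5 m); ties break toward the patch. Returns `NA` (undefined
#' marker) when no band elevation exceeds the far-field elevation plus one
#' standard deviation of the far-field bed noise.
#'
#' @param z bed-elevation matrix (m).
#' @param grid `flood_grid`.
#' @param patch `root_patch`.
#' @param PL patch length unit (m).
#' @param far_field optional far-field elevation; when NULL it is the
#'   median bed elevation over downstream cells more than one patch
#'   diameter off the centerline.
#' @return distance in PL, or `NA_real_`.
#' @export
bar_peak_distance <- function(z, grid, patch, PL = 5, far_field = NULL) {
  D <- patch$patch_diameter
  cx <- patch$center[1]; cy <- patch$center[2]
  xe <- cx + D / 2
  ix <- which(grid$xc > xe)
  iy <- which(abs(grid$yc - cy) <= D / 2)
  if (!length(ix) || !length(iy)) return(NA_real_)
  off <- which(abs(grid$yc - cy) > D)
  if (is.null(far_field)) {
    ref <- z[ix, off, drop = FALSE]
    far_field <- stats::median(ref)
    tol <- stats::sd(ref)
  } else tol <- 0
  wy <- grid$dy[iy]
  band <- as.vector(z[ix, iy, drop = FALSE] %*% wy) / sum(wy)
  if (max(band) <= far_field + tol) return(NA_real_)
  (grid$xc[ix[which.max(band)]] - xe) / PL
}

#' Optimal root density from a sweep
#'
#' Argmax of viable area by quadratic interpolation through the top three
#' sweep points, reported with the bracketing interval. A monotone curve
#' returns the boundary point with `boundary = TRUE`.
#'
#' @param density sweep densities (>= 4 values, increasing).
#' @param area corresponding viable areas.
#' @return list: `optimum`, `bracket` (length 2), `boundary` flag,
#'   `area_max` (interpolated).
#' @export
optimum_density <- function(density, area) {
  stopifnot(length(density) >= 4, length(area) == length(density))
  o <- order(density)
  density <- density[o]; area <- area[o]
  i <- which.max(area)
  n <- length(density)
  if (i == 1L || i == n) {
    return(list(optimum = density[i], bracket = range(density),
                boundary = TRUE, area_max = area[i]))
  }
  xs <- density[(i - 1):(i + 1)]; ys <- area[(i - 1):(i + 1)]
  co <- solve(cbind(1, xs, xs^2), ys)
  opt <- if (co[3] < 0) -co[2] / (2 * co[3]) else density[i]
  opt <- min(max(opt, xs[1]), xs[3])
  list(optimum = opt, bracket = c(xs[1], xs[3]), boundary = FALSE,
       area_max = co[1] + co[2] * opt + co[3] * opt^2)
}

#' Inter-patch cooperativity curve
#'
#' Viable area normalized to patch count as a function of the edge gap
#' between two patches, with the single-patch baseline for comparison.
#' In the infinite-gap limit the normalized area approaches the baseline;
#' cooperativity is the excess above it.
#'
#' @param gap edge gaps (m).
#' @param area viable areas of the two-patch runs (m^2).
#' @param patch_count number of patches in each run (typically 2).
#' @param baseline_area single-patch viable area (m^2).
#' @param baseline_count patches in the baseline run (1).
#' @param threshold the elevation threshold shared by all runs (recorded).
#' @return data.frame of class `cooperativity_curve` with columns `gap`,
#'   `normalized_area`, `cooperativity` (excess over baseline); baseline in
#'   attribute `"baseline"`.
#' @export
cooperativity_curve <- function(gap, area, patch_count = 2, baseline_area,
                                baseline_count = 1, threshold = NULL) {
  stopifnot(length(gap) == length(area))
  base <- baseline_area / baseline_count
  out <- data.frame(gap = gap, normalized_area = area / patch_count)
  out$cooperativity <- out$normalized_area - base
  attr(out, "baseline") <- base
  attr(out, "threshold") <- threshold
  class(out) <- c("cooperativity_curve", "data.frame")
  out
}
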