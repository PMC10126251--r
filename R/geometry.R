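# Scenario geometry: vegetation patches, grain mixtures, computational grids
# and boundary conditions.

#' Build a hexagonal array of vertical roots
#'
#' Places `n_roots` circular roots of diameter `diameter` at the vertices of
#' an equilateral triangular (hexagonal) lattice with nearest-neighbor
#' distance `spacing`, grown ring by ring around `center`. Within a ring,
#' ties are broken by angle from the +x axis, so a fixed `n_roots` always
#' yields the same deterministic layout even when the outer ring is partial.
#'
#' The patch diameter `D` is the circumscribed circle of the root centers
#' plus one root diameter, the solid volume fraction is `phi = N (d/D)^2`,
#' and the areal density is `N / (pi D^2 / 4)`.
#'
#' @param center numeric length-2, patch center (m).
#' @param spacing nearest-neighbor spacing s (m); must exceed `diameter`.
#' @param n_roots number of roots N (>= 1).
#' @param diameter root diameter d (m).
#' @return An object of class `root_patch`: list with `centers` (N x 2
#'   matrix), `diameter` (length-N vector), `patch_diameter`, `n_roots`,
#'   `spacing`, `density` (roots/m^2) and `phi`.
#' @export
build_hex_array <- function(center = c(0, 0), spacing, n_roots, diameter) {
  stopifnot(n_roots >= 1, diameter > 0)
  if (n_roots > 1 && spacing <= diameter)
    stop("overlapping roots: spacing (", spacing, " m) must exceed diameter (",
         diameter, " m)")
  if (n_roots == 1) {
    pts <- matrix(0, 1, 2)
  } else {
    rmax <- ceiling(sqrt(n_roots)) + 2
    ij <- expand.grid(i = -rmax:rmax, j = -rmax:rmax)
    x <- spacing * (ij$i + ij$j / 2)
    y <- spacing * (ij$j * sqrt(3) / 2)
    d2 <- x^2 + y^2
    ang <- atan2(y, x) %% (2 * pi)
    ord <- order(round(sqrt(d2), 9), round(ang, 9))
    pts <- cbind(x, y)[ord[seq_len(n_roots)], , drop = FALSE]
  }
  pts <- sweep(pts, 2, center, `+`)
  dmax <- if (n_roots == 1) 0 else max(stats::dist(pts))
  root_patch(centers = pts, diameter = rep(diameter, n_roots),
             spacing = spacing, patch_diameter = dmax + diameter)
}

#' Construct a vegetation patch from explicit root positions
#'
#' @param centers N x 2 matrix of root center coordinates (m).
#' @param diameter root diameter(s), scalar or length-N (m).
#' @param spacing nominal nearest-neighbor spacing (m), or NA.
#' @param patch_diameter circumscribing patch diameter D (m); computed as
#'   max pairwise center distance + max diameter when missing.
#' @return `root_patch` object.
#' @export
root_patch <- function(centers, diameter, spacing = NA_real_,
                       patch_diameter = NULL) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  n <- nrow(centers)
  diameter <- rep_len(as.numeric(diameter), n)
  if (is.null(patch_diameter)) {
    dmax <- if (n == 1) 0 else max(stats::dist(centers))
    patch_diameter <- dmax + max(diameter)
  }
  phi <- if (length(unique(diameter)) == 1L)
    n * (diameter[1] / patch_diameter)^2
  else sum((diameter / patch_diameter)^2)
  structure(list(
    centers = centers, diameter = diameter, n_roots = n, spacing = spacing,
    patch_diameter = patch_diameter,
    density = n / (pi * patch_diameter^2 / 4), phi = phi,
    center = colMeans(centers)), class = "root_patch")
}

#' @export
print.root_patch <- function(x, ...) {
  cat("<root_patch> N =", x$n_roots, " d =",
      paste(signif(range(x$diameter), 3), collapse = "-"),
      "m  D =", signif(x$patch_diameter, 4), "m  phi =", signif(x$phi, 4),
      " density =", signif(x$density, 4), "roots/m^2\n")
  invisible(x)
}

#' Solid volume fraction of a circular obstacle patch
#'
#' `phi = N (d/D)^2`: the fraction of the circular patch plan area occupied
#' by the root cross-sections.
#'
#' @param N number of roots.
#' @param d root diameter (m).
#' @param D patch diameter (m).
#' @return Dimensionless solid volume fraction.
#' @export
solid_volume_fraction <- function(N, d, D) {
  stopifnot(N >= 1, d > 0)
  if (any(d > D)) stop("geometry error: root diameter d exceeds patch diameter D")
  N * (d / D)^2
}

#' Build a mixed grain-size sediment description
#'
#' Log-spaced class diameters on `[d_min, d_max]` with fractions drawn from a
#' lognormal cumulative curve whose median is calibrated so the piecewise
#' log-linear interpolated cumulative fraction crosses 0.5 exactly at
#' `target_d50`. `sdlog` sets the geometric spread of the (truncated,
#' renormalized) distribution.
#'
#' @param d_min,d_max smallest/largest grain diameter (m).
#' @param target_d50 median diameter D50 (m).
#' @param n_classes number of representative size classes.
#' @param sdlog lognormal spread (natural-log units).
#' @param s_g relative submerged weight (sigma/rho - 1), default 1.65.
#' @param nu_w kinematic viscosity of water (m^2/s) for settling velocities.
#' @return An object of class `grain_mixture` with `class_diameters`,
#'   `fractions`, `mean_diameter`, `s_g`, `settling_velocities`, and the
#'   class `edges` used for the cumulative curve.
#' @export
build_grain_mixture <- function(d_min = 0.001e-3, d_max = 34e-3,
                                target_d50 = 3.2e-3, n_classes = 5,
                                sdlog = 2.0, s_g = 1.65, nu_w = 1e-6) {
  stopifnot(d_min > 0, d_max > d_min, n_classes >= 1)
  if (n_classes == 1L) {
    mix <- list(class_diameters = target_d50, fractions = 1,
                edges = c(d_min, d_max))
  } else {
    if (!(d_min < target_d50 && target_d50 < d_max))
      stop("parameter error: target d50 must lie strictly inside [d_min, d_max]")
    ld <- seq(log(d_min), log(d_max), length.out = n_classes)
    dk <- exp(ld)
    edges <- exp(c(log(d_min), (ld[-1] + ld[-n_classes]) / 2, log(d_max)))
    cdf_at_d50 <- function(mu) {
      p <- diff(stats::plnorm(edges, meanlog = mu, sdlog = sdlog))
      p <- p / sum(p)
      cum <- c(0, cumsum(p))
      stats::approx(log(edges), cum, xout = log(target_d50), rule = 2)$y - 0.5
    }
    lo <- log(d_min); hi <- log(d_max)
    mu <- stats::uniroot(cdf_at_d50, c(lo - 5 * sdlog, hi + 5 * sdlog),
                         tol = 1e-14)$root
    p <- diff(stats::plnorm(edges, meanlog = mu, sdlog = sdlog))
    # representative diameter per class = bin mass centroid (conditional
    # mean of the lognormal), so the mixture mean diameter is insensitive
    # to the number of hierarchy classes
    pe <- diff(stats::pnorm((log(edges) - mu - sdlog^2) / sdlog)) *
      exp(mu + sdlog^2 / 2)
    dk <- ifelse(p > 1e-300, pe / p, dk)
    p <- p / sum(p)
    mix <- list(class_diameters = dk, fractions = p, edges = edges)
  }
  mix$mean_diameter <- sum(mix$fractions * mix$class_diameters)
  mix$d50 <- target_d50
  mix$s_g <- s_g
  mix$settling_velocities <- settling_rubey(mix$class_diameters, s_g, nu_w)
  structure(mix, class = "grain_mixture")
}

#' @export
print.grain_mixture <- function(x, ...) {
  cat("<grain_mixture>", length(x$class_diameters), "classes,",
      signif(min(x$class_diameters) * 1e3, 3), "-",
      signif(max(x$class_diameters) * 1e3, 3), "mm, d50 =",
      signif(x$d50 * 1e3, 3), "mm, dm =", signif(x$mean_diameter * 1e3, 3),
      "mm\n")
  invisible(x)
}

# 1-D graded spacing from a mesh-density integral: the target size is
# h_near inside refined intervals, growing linearly with distance (slope
# 1 - 1/grading, so the adjacent-cell ratio stays within `grading`) up to
# h_far. Edges are placed at equal increments of the integral of 1/target,
# which is deterministic and symmetric for symmetric refined intervals.
grade_axis <- function(L, refined, h_near, h_far, grading = 1.3) {
  target <- function(x) {
    if (nrow(refined) == 0) return(rep(h_far, length(x)))
    d <- vapply(x, function(xx) {
      min(vapply(seq_len(nrow(refined)), function(r) {
        a <- refined[r, 1]; b <- refined[r, 2]
        if (xx < a) a - xx else if (xx > b) xx - b else 0
      }, numeric(1)))
    }, numeric(1))
    pmin(h_far, h_near + (1 - 1 / grading) * d)
  }
  nf <- max(1000L, ceiling(4 * L / h_near))
  xf <- seq(0, L, length.out = nf + 1)
  dens <- 1 / target(xf)
  cum <- c(0, cumsum((dens[-1] + dens[-(nf + 1)]) / 2 * diff(xf)))
  n_cells <- max(2L, ceiling(cum[nf + 1]))
  edges <- stats::approx(cum, xf, xout = seq(0, cum[nf + 1],
                                             length.out = n_cells + 1))$y
  edges[1] <- 0
  edges[n_cells + 1] <- L
  edges
}

#' Build the graded computational grid
#'
#' Structured Cartesian tensor-product grid over the rectangular domain, with
#' cell sizes `sqrt(near_cell_area)` inside a margin around every vegetation
#' patch, grading geometrically (adjacent size ratio <= `grading`) up to
#' `sqrt(far_cell_area)` in the far field. Obstacle cells are those whose
#' centers fall inside any root footprint; they carry zero flux.
#'
#' @param domain_extent c(Lx, Ly): streamwise and cross-stream extent (m).
#' @param patches a `root_patch` or list of them (may be empty).
#' @param near_cell_area target cell area near roots (m^2).
#' @param far_cell_area target far-field cell area (m^2).
#' @param margin refined margin around each patch bounding box (m).
#' @param grading maximum adjacent cell size ratio.
#' @return Object of class `flood_grid`.
#' @export
build_grid <- function(domain_extent, patches = list(),
                       near_cell_area = 0.001, far_cell_area = 1.3,
                       margin = 1, grading = 1.3) {
  stopifnot(near_cell_area < far_cell_area)
  if (inherits(patches, "root_patch")) patches <- list(patches)
  hn <- sqrt(near_cell_area); hf <- sqrt(far_cell_area)
  for (p in patches) {
    if (any(p$diameter < 2 * hn))
      stop("resolution error: root diameter ", min(p$diameter),
           " m smaller than 2 near-zone cells (", signif(2 * hn, 3), " m)")
  }
  box <- function(p, ax) {
    r <- p$diameter / 2
    rng <- range(p$centers[, ax] + r, p$centers[, ax] - r)
    c(rng[1] - margin, rng[2] + margin)
  }
  refx <- if (length(patches)) t(vapply(patches, box, numeric(2), ax = 1))
          else matrix(numeric(0), 0, 2)
  refy <- if (length(patches)) t(vapply(patches, box, numeric(2), ax = 2))
          else matrix(numeric(0), 0, 2)
  xe <- grade_axis(domain_extent[1], refx, hn, hf, grading)
  ye <- grade_axis(domain_extent[2], refy, hn, hf, grading)
  xc <- (xe[-1] + xe[-length(xe)]) / 2
  yc <- (ye[-1] + ye[-length(ye)]) / 2
  nx <- length(xc); ny <- length(yc)
  mask <- matrix(0L, nx, ny)
  for (p in patches) {
    for (r in seq_len(p$n_roots)) {
      cx <- p$centers[r, 1]; cy <- p$centers[r, 2]; rad <- p$diameter[r] / 2
      ix <- which(abs(xc - cx) <= rad)
      iy <- which(abs(yc - cy) <= rad)
      if (!length(ix) || !length(iy)) next
      sub <- outer((xc[ix] - cx)^2, (yc[iy] - cy)^2, `+`) <= rad^2
      mask[ix, iy][sub] <- 1L
    }
  }
  structure(list(
    xe = xe, ye = ye, xc = xc, yc = yc,
    dx = diff(xe), dy = diff(ye), nx = nx, ny = ny,
    mask = mask, domain = domain_extent, patches = patches,
    near_cell_area = near_cell_area, far_cell_area = far_cell_area),
    class = "flood_grid")
}

#' @export
print.flood_grid <- function(x, ...) {
  cat("<flood_grid>", x$nx, "x", x$ny, "cells over",
      paste(x$domain, collapse = " x "), "m;",
      sum(x$mask), "obstacle cells\n")
  invisible(x)
}

#' Cell areas of a grid
#' @param grid `flood_grid`.
#' @return nx x ny matrix of cell areas (m^2).
#' @export
cell_areas <- function(grid) outer(grid$dx, grid$dy)

#' Flood boundary conditions
#'
#' Discharge `Q` enters the upstream (x = 0) edge; the other three edges hold
#' a fixed water height (depth) `stage`, open to both water and sediment.
#'
#' @param Q inflow discharge (m^3/s), >= 0.
#' @param stage boundary water height (m), > 0.
#' @param sediment boundary mode for sediment (only "open" supported).
#' @export
boundary_conditions <- function(Q = 40, stage = 1, sediment = "open") {
  stopifnot(Q >= 0, stage > 0)
  sediment <- match.arg(sediment, "open")
  structure(list(Q = Q, stage = stage, sediment = sediment),
            class = "boundary_conditions")
}
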