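# Scenario presets reproducing the flood-experiment families.

preset_names <- c("tree_with_knees", "tree_without_knees",
                  "density_sweep_fixed_area", "spacing_sweep_fixed_N",
                  "count_sweep_fixed_spacing", "trunk_knee_mixture",
                  "two_patch_gap", "tree_cluster")

# hexagonal lattice spacing giving an areal density rho (points per m^2)
hex_spacing_for_density <- function(rho) sqrt(2 / (sqrt(3) * rho))

#' Scenario presets for the flood experiments
#'
#' Returns a complete simulation configuration (domain, vegetation patches,
#' grain mixture, boundary conditions, grid resolution targets, spin-up and
#' flood durations, analysis thresholds). Defaults: 80 m x 30 m domain with
#' the patch centered 20 m from the inflow, discharge 40 m^3/s, 1 m initial
#' depth over a 10 m bed, 500 s spin-up, 25000 s flood, mixed sediment
#' 0.001-34 mm with D50 = 3.2 mm. Near-root cell area follows the root
#' size: 0.0006 m^2 below 20 cm roots, 0.001 m^2 at or above, grading to
#' 1.3 m^2 in the far field.
#'
#' Presets:
#' * `tree_without_knees`: a single 40 cm trunk.
#' * `tree_with_knees`: 40 cm trunk surrounded by 20 cm knees on a 0.6 m
#'   hexagonal lattice (61 roots, patch diameter ~5 m).
#' * `density_sweep_fixed_area`: 20 cm roots on a patch of fixed diameter
#'   (`patch_diameter`, default 4 m) at areal density `density` (roots/m^2).
#' * `spacing_sweep_fixed_N`: `n_roots` (37) roots at spacing `spacing`.
#' * `count_sweep_fixed_spacing`: `n_roots` roots at fixed `spacing` (0.55).
#' * `trunk_knee_mixture`: hexagonal array of `n_trunks` trunks of diameter
#'   `trunk_d` (0.4 or 0.8 m) at `trunk_spacing`, with optional 10 cm knees
#'   on the dual (offset) lattice (`knees = TRUE`).
#' * `two_patch_gap`: two 37-root patches of 20 cm roots, edges aligned in
#'   the streamwise direction, separated cross-stream by edge gap `gap` (m).
#' * `tree_cluster`: `n_trees` knee patches at the vertices of a regular
#'   polygon of circumradius `cluster_radius`.
#'
#' @param name preset name.
#' @param overrides named list merged over the preset defaults; unknown
#'   names are an error. Preset-specific parameters (e.g. `density`, `gap`,
#'   `trunk_d`) are passed here too.
#' @return list of class `flood_scenario`.
#' @export
scenario_preset <- function(name, overrides = list()) {
  name <- match.arg(name, preset_names)
  cfg <- list(
    name = name,
    domain = c(80, 30),          # streamwise x cross-stream (m)
    patch_center = c(20, 15),
    Q = 40, stage = 1, bed = 10, depth = 1,
    spin_up = 500, flood_duration = 25000,
    mixture = list(d_min = 0.001e-3, d_max = 34e-3, target_d50 = 3.2e-3,
                   n_classes = 5, sdlog = 2.0, s_g = 1.65),
    near_cell_area = NULL,       # chosen from root size when NULL
    far_cell_area = 1.3,
    grid_margin = 1, grading = 1.3,
    thresholds = c(9.7, 9.84, 9.97),
    # preset-specific parameters and their defaults
    root_d = 0.2, density = 3.5, patch_diameter = 4, n_roots = 37,
    spacing = 0.55, trunk_d = 0.4, trunk_spacing = 1.5, n_trunks = 7,
    knees = TRUE, knee_d = 0.1, gap = 1, n_trees = 3, cluster_radius = 5)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop("unknown overrides: ", paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, overrides)
  }
  ctr <- cfg$patch_center
  cfg$patches <- switch(name,
    tree_without_knees = list(build_hex_array(ctr, 1, 1, cfg$trunk_d)),
    tree_with_knees = {
      # defaults: 61 knees of 20 cm at 0.6 m spacing (patch ~ 5 m) around
      # a 40 cm trunk; n_roots/spacing/root_d scale the patch down
      n <- if (identical(cfg$n_roots, 37)) 61 else cfg$n_roots
      s <- if (identical(cfg$spacing, 0.55)) 0.6 else cfg$spacing
      p <- build_hex_array(ctr, s, n, cfg$root_d)
      p$diameter[1] <- cfg$trunk_d   # central trunk
      list(root_patch(p$centers, p$diameter, p$spacing))
    },
    density_sweep_fixed_area = {
      N <- max(1L, round(cfg$density * pi * cfg$patch_diameter^2 / 4))
      s <- hex_spacing_for_density(cfg$density)
      list(build_hex_array(ctr, s, N, cfg$root_d))
    },
    spacing_sweep_fixed_N =
      list(build_hex_array(ctr, cfg$spacing, cfg$n_roots, cfg$root_d)),
    count_sweep_fixed_spacing =
      list(build_hex_array(ctr, cfg$spacing, cfg$n_roots, cfg$root_d)),
    trunk_knee_mixture = {
      trunks <- build_hex_array(ctr, cfg$trunk_spacing, cfg$n_trunks,
                                cfg$trunk_d)
      if (isTRUE(cfg$knees)) {
        # knees on the dual lattice (triangle centroids of the trunk lattice)
        off <- cfg$trunk_spacing * c(0.5, sqrt(3) / 6)
        kc <- sweep(trunks$centers, 2, off, `+`)
        rad <- trunks$patch_diameter / 2
        keep <- sqrt((kc[, 1] - ctr[1])^2 + (kc[, 2] - ctr[2])^2) <= rad
        if (any(keep)) {
          centers <- rbind(trunks$centers, kc[keep, , drop = FALSE])
          dvec <- c(trunks$diameter, rep(cfg$knee_d, sum(keep)))
          list(root_patch(centers, dvec, cfg$trunk_spacing))
        } else list(trunks)
      } else list(trunks)
    },
    two_patch_gap = {
      p0 <- build_hex_array(c(0, 0), cfg$spacing, cfg$n_roots, cfg$root_d)
      D <- p0$patch_diameter
      off <- (D + cfg$gap) / 2
      p1 <- root_patch(sweep(p0$centers, 2, ctr + c(0, -off), `+`),
                       p0$diameter, p0$spacing)
      p2 <- root_patch(sweep(p0$centers, 2, ctr + c(0, off), `+`),
                       p0$diameter, p0$spacing)
      list(p1, p2)
    },
    tree_cluster = {
      p0 <- build_hex_array(c(0, 0), 0.6, 61, 0.2)
      p0$diameter[1] <- cfg$trunk_d
      ang <- 2 * pi * (seq_len(cfg$n_trees) - 1) / cfg$n_trees
      lapply(ang, function(a) {
        ct <- ctr + cfg$cluster_radius * c(cos(a), sin(a)) *
          (cfg$n_trees > 1)
        root_patch(sweep(p0$centers, 2, ct, `+`), p0$diameter, p0$spacing)
      })
    })
  if (is.null(cfg$near_cell_area)) {
    dmin <- min(unlist(lapply(cfg$patches, `[[`, "diameter")))
    cfg$near_cell_area <- if (dmin < 0.2) 0.0006 else 0.001
  }
  cfg$bc <- boundary_conditions(Q = cfg$Q, stage = cfg$stage)
  structure(cfg, class = "flood_scenario")
}

#' @export
print.flood_scenario <- function(x, ...) {
  cat("<flood_scenario>", x$name, "|", length(x$patches), "patch(es) | Q =",
      x$Q, "m^3/s | domain", paste(x$domain, collapse = " x "), "m | flood",
      x$flood_duration, "s\n")
  for (p in x$patches) print(p)
  invisible(x)
}

#' Build the grid for a scenario
#' @param scenario `flood_scenario`.
#' @param near_cell_area,far_cell_area optional overrides (m^2).
#' @return `flood_grid`.
#' @export
scenario_grid <- function(scenario, near_cell_area = NULL,
                          far_cell_area = NULL) {
  build_grid(scenario$domain, scenario$patches,
             near_cell_area %||% scenario$near_cell_area,
             far_cell_area %||% scenario$far_cell_area,
             margin = scenario$grid_margin, grading = scenario$grading)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a scenario configuration as structured text (JSON)
#'
#' Patches are serialized as root tables (x, y, diameter); everything else
#' round-trips as plain values.
#'
#' @param scenario `flood_scenario`.
#' @param path file path.
#' @export
write_scenario_config <- function(scenario, path) {
  s <- unclass(scenario)
  s$bc <- unclass(s$bc)
  s$patches <- lapply(s$patches, function(p)
    data.frame(x = p$centers[, 1], y = p$centers[, 2], diameter = p$diameter,
               spacing = p$spacing))
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  s$patches <- lapply(
    if (is.data.frame(s$patches)) list(s$patches) else s$patches,
    function(df) root_patch(cbind(df$x, df$y), df$diameter,
                            spacing = df$spacing[1]))
  s$bc <- boundary_conditions(Q = s$bc$Q, stage = s$bc$stage)
  s$domain <- as.numeric(s$domain)
  s$patch_center <- as.numeric(s$patch_center)
  s$thresholds <- as.numeric(s$thresholds)
  structure(s, class = "flood_scenario")
}
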