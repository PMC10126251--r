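# Experiment orchestration: coupled flood runs and parameter sweeps.

# smallest circle-ish patch enclosing all patches (for multi-patch metrics)
enclosing_patch <- function(patches) {
  if (length(patches) == 1L) return(patches[[1]])
  centers <- do.call(rbind, lapply(patches, `[[`, "centers"))
  dvec <- unlist(lapply(patches, `[[`, "diameter"))
  root_patch(centers, dvec, spacing = patches[[1]]$spacing)
}

#' Run one coupled flood simulation
#'
#' Hydrodynamic spin-up with the morphology frozen, followed by the coupled
#' flow + sediment + bed-evolution flood. Bed-elevation probes are recorded
#' on the centerline at the given distances downstream of the patch trailing
#' edge. Metrics (viable area at each threshold, percent velocity change,
#' bar-peak distance) are computed from the final fields.
#'
#' @param scenario `flood_scenario` from [scenario_preset()].
#' @param settings `numerical_settings`.
#' @param params `sediment_parameters`.
#' @param probes_PL probe distances downstream of the trailing edge, in
#'   patch lengths (1 PL = 5 m).
#' @param PL patch length unit (m).
#' @param seed RNG seed recorded in the manifest (layouts are deterministic;
#'   kept for jittered extensions).
#' @param out_dir optional directory for rasters, series, metrics, manifest.
#' @return list of class `flood_run`: `grid`, `flow`, `sed`, `z_initial`,
#'   `metrics` (tidy data.frame, one row per threshold), `probes`,
#'   `diagnostics` (budgets, residuals, step counts), `manifest`.
#' @export
run_flood <- function(scenario, settings = numerical_settings("coarse"),
                      params = sediment_parameters(), probes_PL = c(1, 4, 8),
                      PL = 5, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(scenario, "flood_scenario"))
  set.seed(seed)
  grid <- scenario_grid(scenario)
  mix <- do.call(build_grain_mixture, scenario$mixture)
  flow <- init_flow_state(grid, scenario$depth, scenario$bed, settings)
  sed <- init_sediment_state(grid, mix)
  patch <- enclosing_patch(scenario$patches)
  xe <- patch$center[1] + patch$patch_diameter / 2
  pi_ <- vapply(probes_PL, function(p)
    which.min(abs(grid$xc - (xe + p * PL))), integer(1))
  pj <- rep(which.min(abs(grid$yc - patch$center[2])), length(pi_))

  ph <- phys_list(settings, scenario$bc, "flood")
  sl <- sed_list(params)
  ctl <- function(duration, morpho_on) list(
    duration = duration, dt = settings$dt, cfl = settings$cfl,
    morpho_every = as.integer(settings$morpho_every), morpho_on = morpho_on,
    max_vel = settings$max_vel, probe_i = as.integer(pi_ - 1L),
    probe_j = as.integer(pj - 1L), record_dt = settings$record_dt,
    dt_min = settings$dt_min,
    q_ramp = if (morpho_on) 0 else settings$q_ramp)

  z0 <- flow$z
  run1 <- cpp_run(flow$h, flow$u, flow$v, flow$z, flow$nu, sed$Ch, sed$p,
                  grid$mask, grid$xc, grid$yc, grid$dx, grid$dy, ph, sl,
                  mix$class_diameters, mix$settling_velocities,
                  ctl(scenario$spin_up, FALSE))
  run2 <- cpp_run(run1$h, run1$u, run1$v, run1$z, run1$nu, run1$Ch, run1$p,
                  grid$mask, grid$xc, grid$yc, grid$dx, grid$dy, ph, sl,
                  mix$class_diameters, mix$settling_velocities,
                  ctl(scenario$flood_duration, TRUE))
  flow$h <- run2$h; flow$u <- run2$u; flow$v <- run2$v
  flow$z <- run2$z; flow$nu <- run2$nu
  sed$Ch <- run2$Ch; sed$p <- run2$p

  region <- downstream_region(grid, patch, PL = PL)
  pvc <- tryCatch(
    percent_velocity_change(flow$u, flow$v, grid, patch),
    error = function(e) NA_real_)
  bpd <- bar_peak_distance(flow$z, grid, patch, PL = PL)
  metrics <- do.call(rbind, lapply(scenario$thresholds, function(th)
    data.frame(scenario = scenario$name,
               density = patch$density, spacing = patch$spacing,
               n_roots = patch$n_roots, phi = patch$phi,
               root_d = max(patch$diameter), threshold = th,
               viable_area_m2 = viable_area(flow$z, grid, th, region),
               pct_velocity_change = pvc, bar_peak_PL = bpd)))

  probes <- NULL
  if (length(run2$probes)) {
    zm <- run2$probes$z
    probes <- data.frame(
      time_s = rep(run2$probes$time, length(probes_PL)),
      distance_PL = rep(probes_PL, each = length(run2$probes$time)),
      elevation_m = as.vector(zm))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("rootmorph")),
    scenario = scenario$name, seed = seed,
    bundle = settings$bundle, settings = unclass(settings),
    sediment_parameters = unclass(params),
    mixture = scenario$mixture, Q = scenario$Q,
    domain = scenario$domain, spin_up = scenario$spin_up,
    flood_duration = scenario$flood_duration,
    grid = list(nx = grid$nx, ny = grid$ny,
                near_cell_area = grid$near_cell_area,
                far_cell_area = grid$far_cell_area),
    closures = list(shelter_mode = params$shelter_mode,
                    tau_prime_mode = params$tau_prime_mode,
                    kdev_sqrt = params$kdev_sqrt))
  out <- structure(list(
    scenario = scenario, grid = grid, flow = flow, sed = sed, z_initial = z0,
    metrics = metrics, probes = probes,
    diagnostics = list(
      spin_up = run1[c("n_steps", "max_residual", "water")],
      flood = run2[c("n_steps", "max_residual", "water", "sediment")]),
    manifest = manifest), class = "flood_run")
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

#' @export
print.flood_run <- function(x, ...) {
  cat("<flood_run>", x$scenario$name, "|",
      x$diagnostics$flood$n_steps, "flood steps | bar peak =",
      signif(x$metrics$bar_peak_PL[1], 3), "PL\n")
  print(x$metrics[, c("threshold", "viable_area_m2", "pct_velocity_change")])
  invisible(x)
}

#' Define an experiment plan (a 1-D parameter sweep over a preset)
#'
#' @param preset scenario preset name.
#' @param parameter name of the swept override (e.g. `"density"`, `"gap"`,
#'   `"spacing"`, `"n_roots"`).
#' @param values vector of parameter values, one run each.
#' @param overrides shared overrides applied to every run.
#' @param settings,params numerical settings and sediment parameters.
#' @param seed base seed; run i uses seed + i - 1.
#' @export
experiment_plan <- function(preset, parameter, values, overrides = list(),
                            settings = numerical_settings("coarse"),
                            params = sediment_parameters(), seed = 1L) {
  structure(list(preset = preset, parameter = parameter, values = values,
                 overrides = overrides, settings = settings, params = params,
                 seed = seed), class = "experiment_plan")
}

#' Execute an experiment plan
#'
#' Runs are independent and executed in order; a failed run is recorded in
#' the `failures` element and the sweep continues. The concatenated tidy
#' metrics table gains a `value` column holding the swept parameter.
#'
#' @param plan `experiment_plan`.
#' @param out_dir optional directory; each run writes to a subdirectory.
#' @param keep_runs keep the full `flood_run` objects (memory-heavy).
#' @return list of class `sweep_result`: `metrics`, `plan`, `failures`,
#'   optionally `runs`.
#' @export
run_sweep <- function(plan, out_dir = NULL, keep_runs = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  rows <- list(); runs <- list(); failures <- list()
  for (i in seq_along(plan$values)) {
    ov <- plan$overrides
    ov[[plan$parameter]] <- plan$values[i]
    dir_i <- if (is.null(out_dir)) NULL else
      file.path(out_dir, sprintf("run_%03d", i))
    res <- tryCatch({
      sc <- scenario_preset(plan$preset, ov)
      run_flood(sc, settings = plan$settings, params = plan$params,
                seed = plan$seed + i - 1L, out_dir = dir_i)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        list(index = i, value = plan$values[i], message = conditionMessage(res))
    } else {
      m <- res$metrics
      m$value <- plan$values[i]
      rows[[length(rows) + 1]] <- m
      if (keep_runs) runs[[length(runs) + 1]] <- res
    }
  }
  structure(list(metrics = do.call(rbind, rows), plan = plan,
                 failures = failures, runs = if (keep_runs) runs),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>", x$plan$preset, "sweeping", x$plan$parameter, "over",
      length(x$plan$values), "values;", length(x$failures), "failures\n")
  invisible(x)
}

#' Run hydrodynamics only (morphology frozen)
#'
#' Useful for spin-up studies and wake characterization. Probe points record
#' depth and velocity time series.
#'
#' @param scenario `flood_scenario`.
#' @param settings `numerical_settings`.
#' @param duration simulated time (s); defaults to the scenario spin-up.
#' @param probe_xy optional matrix of probe coordinates (m), one row each.
#' @return list: final `flow` state, `grid`, `probes` (time, h, u, v),
#'   `diagnostics`.
#' @export
simulate_flow <- function(scenario, settings = numerical_settings("coarse"),
                          duration = NULL, probe_xy = NULL) {
  grid <- scenario_grid(scenario)
  mix <- do.call(build_grain_mixture, scenario$mixture)
  flow <- init_flow_state(grid, scenario$depth, scenario$bed, settings)
  sed <- init_sediment_state(grid, mix)
  if (is.null(probe_xy)) probe_xy <- matrix(numeric(0), 0, 2)
  pi_ <- vapply(seq_len(nrow(probe_xy)), function(r)
    which.min(abs(grid$xc - probe_xy[r, 1])), integer(1))
  pj <- vapply(seq_len(nrow(probe_xy)), function(r)
    which.min(abs(grid$yc - probe_xy[r, 2])), integer(1))
  ctl <- list(duration = duration %||% scenario$spin_up, dt = settings$dt,
              cfl = settings$cfl,
              morpho_every = as.integer(settings$morpho_every),
              morpho_on = FALSE, max_vel = settings$max_vel,
              probe_i = as.integer(pi_ - 1L), probe_j = as.integer(pj - 1L),
              record_dt = settings$record_dt, dt_min = settings$dt_min,
              q_ramp = settings$q_ramp)
  out <- cpp_run(flow$h, flow$u, flow$v, flow$z, flow$nu, sed$Ch, sed$p,
                 grid$mask, grid$xc, grid$yc, grid$dx, grid$dy,
                 phys_list(settings, scenario$bc, "flood"), sed_list(
                   sediment_parameters()), mix$class_diameters,
                 mix$settling_velocities, ctl)
  flow$h <- out$h; flow$u <- out$u; flow$v <- out$v; flow$nu <- out$nu
  list(flow = flow, grid = grid, probes = out$probes,
       diagnostics = out[c("n_steps", "max_residual", "water")])
}
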