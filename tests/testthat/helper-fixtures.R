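# Shared fixtures: small grids, spun-up uniform flow fields, tiny scenarios.

# uniform rectangular grid without patches (far resolution everywhere)
tiny_grid <- function(Lx = 10, Ly = 4, cell = 0.5) {
  build_grid(c(Lx, Ly), list(), near_cell_area = cell^2 * 0.99,
             far_cell_area = cell^2)
}

# uniform flow state on a grid: depth h0, velocity (u0, v0), flat bed
uniform_flow <- function(grid, h0 = 1, u0 = 0, v0 = 0, bed = 10,
                         settings = numerical_settings()) {
  st <- init_flow_state(grid, depth = h0, bed = bed, settings = settings)
  st$u[grid$mask == 0L] <- u0
  st$v[grid$mask == 0L] <- v0
  st
}

# small fast scenario: one patch in a short flume, coarse resolution
test_scenario <- function(name = "density_sweep_fixed_area", ...) {
  ov <- utils::modifyList(list(
    domain = c(30, 12), patch_center = c(9, 6), Q = 12 / 30 * 40,
    patch_diameter = 2.4, density = 3.5,
    spin_up = 120, flood_duration = 300,
    near_cell_area = 0.01, far_cell_area = 1.0), list(...))
  scenario_preset(name, ov)
}

fast_settings <- function(...) {
  numerical_settings("coarse", q_ramp = 30, ...)
}
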