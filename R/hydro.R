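# Hydrodynamics: Manning friction, algebraic turbulence closure, boundary
# handling and the finite-volume flow step.

#' Bottom shear stress (kinematic) from Manning friction
#'
#' `tau_bx/rho = Cf u sqrt(u^2+v^2)`, `tau_by/rho = Cf v sqrt(u^2+v^2)` with
#' `Cf = g n^2 / h^(1/3)`. Cells at or below the dry threshold carry zero
#' stress.
#'
#' @param u,v depth-averaged velocity components (m/s).
#' @param h water depth (m).
#' @param n Manning roughness (s/m^(1/3)).
#' @param h_dry dry-cell threshold (m).
#' @return list with `taubx`, `tauby` (m^2/s^2) and `Cf`.
#' @export
bottom_friction <- function(u, v, h, n = 0.03, h_dry = 1e-4) {
  wet <- h > h_dry
  Cf <- ifelse(wet, GRAV * n^2 / pmax(h, h_dry)^(1 / 3), 0)
  Vm <- sqrt(u^2 + v^2)
  list(taubx = Cf * u * Vm, tauby = Cf * v * Vm, Cf = Cf)
}

#' Algebraic turbulence closure quantities
#'
#' From the friction velocity `u* = sqrt(Cf) |V|`: turbulent kinetic energy
#' `kappa = 2.07 u*^2`, dissipation `epsilon = Ce kappa^(3/2) / l`, and eddy
#' viscosity `nu = C_mu kappa^2 / epsilon = (C_mu/Ce) sqrt(kappa) l` (the
#' dimensionally consistent form), floored at `nu_background`. The
#' turbulence length scale l is the local depth.
#'
#' @param u_star friction velocity (m/s).
#' @param l turbulence length scale (m), typically the depth.
#' @param c_mu,c_e closure constants (0.09 and 1.0).
#' @param nu_background floor viscosity (m^2/s).
#' @return list with `kappa` (m^2/s^2), `epsilon` (m^2/s^3), `nu` (m^2/s).
#' @export
turbulence_quantities <- function(u_star, l = 1, c_mu = 0.09, c_e = 1.0,
                                  nu_background = 0) {
  kappa <- 2.07 * u_star^2
  epsilon <- ifelse(l > 0, c_e * kappa^(3 / 2) / l, 0)
  nu <- ifelse(kappa > 0, c_mu * kappa^2 / pmax(epsilon, 1e-300), 0) +
    nu_background
  list(kappa = kappa, epsilon = epsilon, nu = nu)
}

#' Eddy viscosity field from the flow
#'
#' @inheritParams bottom_friction
#' @param c_mu,c_e closure constants.
#' @param nu_background floor viscosity (m^2/s).
#' @return eddy viscosity (m^2/s), same shape as `u`.
#' @export
eddy_viscosity <- function(u, v, h, n = 0.03, c_mu = 0.09, c_e = 1.0,
                           nu_background = 1e-4, h_dry = 1e-4) {
  fr <- bottom_friction(u, v, h, n, h_dry)
  u_star <- sqrt(fr$Cf) * sqrt(u^2 + v^2)
  turbulence_quantities(u_star, l = pmax(h, 0), c_mu = c_mu, c_e = c_e,
                        nu_background = nu_background)$nu
}

#' Apply flood boundary conditions
#'
#' Distributes the inflow discharge across wetted upstream-edge cells in
#' proportion to their conveyance `dy * h^(5/3)`, and clamps the water height
#' on the other three edges to the boundary stage (ghost values; the solver
#' applies them as fluxes). Returns the inflow distribution for inspection.
#'
#' @param state `flow_state`.
#' @param bc `boundary_conditions`.
#' @param grid `flood_grid`.
#' @return list: `state` (unchanged fields), `inflow` per-cell discharge
#'   (m^3/s, length ny), `inflow_velocity` (m/s).
#' @export
apply_boundaries <- function(state, bc, grid) {
  h0 <- state$h[1, ]
  open <- grid$mask[1, ] == 0L & h0 > 1e-4
  if (bc$Q > 0 && !any(open))
    stop("inflow edge fully dry: cannot impose discharge")
  K <- ifelse(open, grid$dy * h0^(5 / 3), 0)
  qin <- if (bc$Q > 0) bc$Q * K / sum(K) else rep(0, grid$ny)
  uin <- ifelse(open, qin / (grid$dy * pmax(h0, 1e-4)), 0)
  list(state = state, inflow = qin, inflow_velocity = uin)
}

#' Advance the flow one time step
#'
#' Explicit flux-form finite-volume update of (h, uh, vh): upwinded
#' advection (first order, or minmod-limited second order), centered
#' pressure gradient on the surface H = h + z, turbulent diffusion, and
#' semi-implicit Manning friction. Obstacle faces carry zero flux; the water
#' volume budget closes to the boundary fluxes at machine precision.
#'
#' @param state `flow_state`.
#' @param grid `flood_grid`.
#' @param bc `boundary_conditions` (or NULL for a closed basin).
#' @param settings `numerical_settings`.
#' @param dt time step (s); must satisfy the CFL condition for the celerity
#'   `sqrt(g h) + |V|`.
#' @return updated `flow_state`; diagnostics (volume-budget residual,
#'   boundary fluxes, max velocity) in attribute `"diagnostics"`.
#' @export
step_flow <- function(state, grid, bc, settings, dt) {
  bctype <- if (is.null(bc)) "closed" else "flood"
  ph <- phys_list(settings, bc, bctype)
  out <- cpp_flow_step(state$h, state$u, state$v, state$z, state$nu,
                       grid$mask, grid$xc, grid$yc, grid$dx, grid$dy, ph, dt)
  if (!is.finite(out$max_vel) || out$max_vel > settings$max_vel)
    stop("flow solver blow-up: max |V| = ", out$max_vel, " m/s")
  ns <- state
  ns$h <- out$h; ns$u <- out$u; ns$v <- out$v; ns$nu <- out$nu
  attr(ns, "diagnostics") <- list(residual = out$residual,
                                  vol_in = out$vol_in, vol_out = out$vol_out,
                                  clamp = out$clamp, max_vel = out$max_vel)
  ns
}
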