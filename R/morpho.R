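# Morphodynamics closures and per-step operations (bedload, suspended load,
# bed evolution). The vectorized closures are backed by the same C++ code
# used inside the coupled solver.

#' Shields (dimensionless shear) stress
#'
#' `tau* = u*^2 / (s_g g d)`.
#'
#' @param u_star friction velocity (m/s).
#' @param s_g relative submerged weight (sigma/rho - 1).
#' @param d grain diameter (m).
#' @export
shields_stress <- function(u_star, s_g, d) {
  stopifnot(all(d > 0))
  u_star^2 / (s_g * GRAV * d)
}

#' Critical Shields stress (Iwagaki)
#'
#' Piecewise empirical relation for the critical friction velocity squared
#' as a function of grain diameter (five ranges), returned as a Shields
#' number. The coarse-gravel limit approaches a constant value near 0.05.
#' `mode = "constant"` gives the configurable constant-Shields fallback.
#'
#' @param d grain diameter (m).
#' @param s_g relative submerged weight.
#' @param mode `"iwagaki"` or `"constant"`.
#' @param tau_const the constant fallback value.
#' @export
critical_shields_iwagaki <- function(d, s_g = 1.65,
                                     mode = c("iwagaki", "constant"),
                                     tau_const = 0.05) {
  mode <- match.arg(mode)
  stopifnot(all(d > 0))
  if (mode == "constant") return(rep(tau_const, length(d)))
  cpp_iwagaki(as.numeric(d), s_g)
}

#' Meyer-Peter-Mueller bedload transport
#'
#' `qb = 8 sqrt(s_g g d^3) (tau*' - tau*c)^(3/2)` for positive excess
#' stress, else 0. Volumetric solid transport per unit width (m^2/s).
#'
#' @param tau_eff effective Shields stress tau*'.
#' @param tau_c critical Shields stress tau*c.
#' @param d grain diameter (m).
#' @param s_g relative submerged weight.
#' @param coef the dimensionless coefficient (8).
#' @export
bedload_mpm <- function(tau_eff, tau_c, d, s_g = 1.65, coef = 8) {
  n <- max(length(tau_eff), length(tau_c), length(d))
  cpp_mpm(rep_len(tau_eff - tau_c, n), rep_len(d, n), s_g, coef)
}

#' Rubey settling velocity
#'
#' `w0 = [sqrt(2/3 + A) - sqrt(A)] sqrt(s_g g d)` with
#' `A = 36 nu_w^2/(s_g g d^3)`. Recovers Stokes scaling (w0 ~ d^2) for fine
#' grains and w0 ~ sqrt(d) for coarse grains.
#'
#' @param d grain diameter (m).
#' @param s_g relative submerged weight.
#' @param nu_w kinematic viscosity of water (m^2/s), 1e-6 at 20 C.
#' @export
settling_rubey <- function(d, s_g = 1.65, nu_w = 1e-6) {
  stopifnot(all(d > 0))
  cpp_rubey(as.numeric(d), s_g, nu_w)
}

#' Itakura-Kishi suspended-sediment entrainment
#'
#' `Es = K [ alpha* (rho/sigma) (u*/w0) (Omega/tau*) - 1 ]`, floored at 0,
#' with `Omega = (tau*/B*) exp(-a^2)/(sqrt(pi) erfc(a)) + tau*/(B* eta0) - 1`
#' and `a = B*/tau* - 1/eta0`. `mode = "simplified"` drops Omega
#' (configurable pickup-law fallback `Es = K [alpha* (rho/sigma) u*/w0 - 1]`).
#'
#' @param u_star friction velocity (m/s).
#' @param tau_star Shields stress.
#' @param w0 settling velocity (m/s).
#' @param s_g relative submerged weight (sigma/rho = 1 + s_g).
#' @param K,alpha_star Itakura-Kishi constants (0.008, 0.14).
#' @param B_star,eta0 constants of the Omega function (0.143, 0.5).
#' @param mode `"itakura_kishi"` or `"simplified"`.
#' @return dimensionless entrainment concentration Es.
#' @export
entrainment_itakura_kishi <- function(u_star, tau_star, w0, s_g = 1.65,
                                      K = 0.008, alpha_star = 0.14,
                                      B_star = 0.143, eta0 = 0.5,
                                      mode = c("itakura_kishi",
                                               "simplified")) {
  mode <- match.arg(mode)
  n <- max(length(u_star), length(tau_star), length(w0))
  u_star <- rep_len(u_star, n); tau_star <- rep_len(tau_star, n)
  w0 <- rep_len(w0, n)
  if (mode == "simplified") {
    es <- K * (alpha_star / (1 + s_g) * u_star / w0 - 1)
    return(pmax(es, 0))
  }
  cpp_ik_es(u_star, tau_star, w0, s_g, K, alpha_star, B_star, eta0)
}

#' Itakura-Kishi Omega function
#' @param tau_star Shields stress.
#' @param B_star,eta0 constants (0.143, 0.5).
#' @export
ik_omega <- function(tau_star, B_star = 0.143, eta0 = 0.5) {
  cpp_ik_omega(as.numeric(tau_star), B_star, eta0)
}

#' Suspended-sediment vertical profile (Lane-Kalinske)
#'
#' `C/C_alpha = exp(-(6 w0/(kappa_vK u*)) (z - z_alpha)/h)` with the
#' reference height `z_alpha = 0.05 h` and von Karman constant 0.4.
#'
#' @param z height above the bed (m).
#' @param h water depth (m).
#' @param w0 settling velocity (m/s).
#' @param u_star friction velocity (m/s), > 0.
#' @param kappa_vk von Karman constant.
#' @param z_alpha_coef reference height as a fraction of depth.
#' @return the concentration ratio C/C_alpha.
#' @export
reference_concentration_profile <- function(z, h, w0, u_star,
                                            kappa_vk = 0.4,
                                            z_alpha_coef = 0.05) {
  stopifnot(all(u_star > 0))
  za <- z_alpha_coef * h
  exp(-(6 * w0 / (kappa_vk * u_star)) * (z - za) / h)
}

#' Mixed-grain sheltering correction
#'
#' Ratio of the critical tractive force of grain class `d_k` to that of the
#' mean diameter `d_m`. `mode = "paper"` uses the printed piecewise rule: a
#' constant 0.85 for `d_k/d_m <= 0.4` and the Egiazaroff-type
#' `[1 + 0.34 ln(d_k/d_m)]^-2` above; `mode = "ashida_michiue"` replaces the
#' lower branch by `0.85/(d_k/d_m)` (the two branches then agree within 1%
#' at the 0.4 junction).
#'
#' @param d_k grain class diameter (m).
#' @param d_m mean diameter of the mixture (m).
#' @param mode `"paper"` or `"ashida_michiue"`.
#' @export
sheltering_correction <- function(d_k, d_m, mode = c("paper",
                                                     "ashida_michiue")) {
  mode <- match.arg(mode)
  stopifnot(all(d_k > 0), all(d_m > 0))
  n <- max(length(d_k), length(d_m))
  cpp_shelter(rep_len(d_k, n) / rep_len(d_m, n),
              match(mode, c("paper", "ashida_michiue")) - 1L)
}

#' Streamline curvature of the depth-averaged flow
#'
#' `1/r = [u(u v_x - v u_x) + v(u v_y - v u_y)] / |V|^3` by centered finite
#' differences (one-sided against obstacles and domain edges); zero where
#' `|V|` is below `v_floor`.
#'
#' @param u,v velocity component matrices (m/s).
#' @param grid `flood_grid`.
#' @param v_floor velocity floor (m/s).
#' @return matrix of signed curvature (1/m).
#' @export
streamline_curvature <- function(u, v, grid, v_floor = 1e-6) {
  cpp_curvature(u, v, grid$xc, grid$yc, grid$mask, v_floor)
}

#' Directional splitting of bedload along and across the streamline
#'
#' Near-bed streamwise speed `vb = 8.5 u*`, transverse near-bed speed
#' `ubn = -7 vb h / r` (secondary-flow closure), slope-deviation coefficient
#' `kdev = sqrt(tau*c/(mu_s mu_k tau*))`:
#' `q_s = qb (vb/Vb - kdev dz/ds)`, `q_n = qb (ubn/Vb - kdev dz/dn)`, then
#' rotated into Cartesian components by the flow angle
#' `theta = atan2(v, u)`: `q_x = q_s cos(theta) - q_n sin(theta)`,
#' `q_y = q_s sin(theta) + q_n cos(theta)`.
#'
#' @param qb scalar bedload magnitude (m^2/s), >= 0.
#' @param u,v depth-averaged velocity (m/s).
#' @param u_star friction velocity (m/s).
#' @param h depth (m).
#' @param inv_r signed streamline curvature (1/m).
#' @param dzdx,dzdy bed-elevation gradients.
#' @param tau_star,tau_c Shields and critical Shields stress.
#' @param mu_s,mu_k static and kinetic friction factors.
#' @param sqrt_form use the square-root form of the deviation coefficient.
#' @return list with `q_s`, `q_n`, `q_x`, `q_y` (m^2/s).
#' @export
directional_split <- function(qb, u, v, u_star, h, inv_r, dzdx, dzdy,
                              tau_star, tau_c, mu_s = 1.0, mu_k = 0.45,
                              sqrt_form = TRUE) {
  stopifnot(all(qb >= 0))
  Vm <- sqrt(u^2 + v^2)
  cth <- ifelse(Vm > 0, u / Vm, 1)
  sth <- ifelse(Vm > 0, v / Vm, 0)
  dzds <- cth * dzdx + sth * dzdy
  dzdn <- -sth * dzdx + cth * dzdy
  vb <- 8.5 * u_star
  ubn <- -7 * vb * h * inv_r
  Vb <- sqrt(vb^2 + ubn^2)
  kdev <- ifelse(tau_star > 0, tau_c / (mu_s * mu_k * tau_star), 0)
  if (sqrt_form) kdev <- sqrt(kdev)
  q_s <- ifelse(Vb > 0, qb * (vb / Vb - kdev * dzds), 0)
  q_n <- ifelse(Vb > 0, qb * (ubn / Vb - kdev * dzdn), 0)
  list(q_s = q_s, q_n = q_n,
       q_x = q_s * cth - q_n * sth,
       q_y = q_s * sth + q_n * cth)
}

#' Per-class transport fields from the current flow
#'
#' Computes availability-weighted bedload vectors (with curvature-driven
#' directional splitting and sheltering), the Itakura-Kishi entrainment and
#' the Lane-Kalinske profile factors for every cell and grain class.
#'
#' @param flow `flow_state`.
#' @param sed `sediment_state`.
#' @param grid `flood_grid`.
#' @param settings `numerical_settings`.
#' @param params `sediment_parameters`.
#' @return list of nx x ny x nk arrays `qxk`, `qyk`, `Esk`, `pfk`.
#' @export
transport_fields <- function(flow, sed, grid, settings = numerical_settings(),
                             params = sediment_parameters()) {
  mix <- sed$mixture
  cpp_transport_fields(flow$h, flow$u, flow$v, flow$z, sed$p, grid$mask,
                       grid$xc, grid$yc, grid$dx, grid$dy,
                       phys_list(settings, NULL, "closed"), sed_list(params),
                       mix$class_diameters, mix$settling_velocities)
}

#' Advance the suspended load one morphodynamic step
#'
#' Upwinded advection and turbulent diffusion of the depth-integrated
#' concentration `C h` per class, with explicit (availability-weighted)
#' entrainment and implicit deposition through the near-bed reference
#' concentration `C_alpha = pf * C`. Returns the per-class deposited and
#' entrained solid volumes for the subsequent bed update.
#'
#' @param sed `sediment_state`.
#' @param flow `flow_state`.
#' @param tf transport fields from [transport_fields()].
#' @param grid `flood_grid`.
#' @param settings,params solver settings and sediment parameters.
#' @param bc `boundary_conditions` (NULL = closed box).
#' @param dt morphodynamic time step (s).
#' @return updated `sediment_state`; arrays `dep`/`ent` and the boundary
#'   ledger in attribute `"exchange"`.
#' @export
suspended_step <- function(sed, flow, tf, grid, settings, params, bc, dt) {
  mix <- sed$mixture
  bctype <- if (is.null(bc)) "closed" else "flood"
  out <- cpp_suspended_step(sed$Ch, flow$h, flow$u, flow$v, flow$nu,
                            tf$Esk, tf$pfk, grid$mask, grid$xc, grid$yc,
                            grid$dx, grid$dy, phys_list(settings, bc, bctype),
                            sed_list(params), mix$class_diameters,
                            mix$settling_velocities, dt)
  ns <- sed
  ns$Ch <- out$Ch
  attr(ns, "exchange") <- out[c("dep", "ent", "susp_in", "susp_out",
                                "dep_total", "ent_total", "clip")]
  ns
}

#' Exner bed-evolution update with mixed-grain exchange layer
#'
#' `dz/dt = [-(div q) - (Es - C_alpha) w0] / (1 - lambda)` summed over
#' classes (void-ratio scaling of the printed transport divergence), with
#' surface-layer fractions advanced by the active-layer conservation
#' equation over the 0.5 m exchange layer and renormalized to sum to 1. A
#' class cannot erode more than its share of the exchange layer.
#'
#' @param flow `flow_state` (supplies and receives `z`).
#' @param sed `sediment_state` (supplies and receives `p`).
#' @param tf transport fields ([transport_fields()]).
#' @param dep,ent per-class deposited/entrained solid volume per area (m),
#'   e.g. from the `"exchange"` attribute of [suspended_step()].
#' @param grid,settings,params,bc as elsewhere.
#' @param dt morphodynamic time step (s).
#' @return list `flow` (updated z), `sed` (updated p), `ledger` (boundary
#'   bedload fluxes, solid m^3).
#' @export
bed_update <- function(flow, sed, tf, dep, ent, grid, settings, params, bc,
                       dt) {
  mix <- sed$mixture
  bctype <- if (is.null(bc)) "closed" else "flood"
  out <- cpp_bed_update(flow$z, sed$p, tf$qxk, tf$qyk, dep, ent, grid$mask,
                        grid$xc, grid$yc, grid$dx, grid$dy,
                        phys_list(settings, bc, bctype), sed_list(params),
                        mix$class_diameters, mix$settling_velocities, dt)
  flow$z <- out$z
  sed$p <- out$p
  list(flow = flow, sed = sed,
       ledger = out[c("bed_in", "bed_out", "clip")])
}
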