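# Numerical settings bundles and sediment parameter sets.

#' Numerical settings for the flow/morphodynamics solver
#'
#' Two documented bundles: `"coarse"` (desk-scale: CFL-adaptive time step,
#' first-order upwind advection, morphodynamics sub-cycled every 10 flow
#' steps) and `"paper"` (fixed dt = 0.04 s within the 0.01-0.08 s range,
#' second-order minmod advection, morphodynamics every 5 steps). Every run
#' records its bundle in the manifest.
#'
#' @param bundle `"coarse"` or `"paper"`.
#' @param ... overrides for any field below.
#' @return list of class `numerical_settings` with fields `dt` (s; <= 0
#'   means CFL-adaptive), `cfl`, `manning_n` (s/m^(1/3)), `c_mu`, `c_e`,
#'   `turbulence_length` (`"depth"`), `nu_background` (m^2/s), `h_dry` (m),
#'   `coriolis_f` (1/s), `order` (1 or 2), `morpho_every`, `max_vel` (m/s),
#'   `record_dt` (s), `dt_min` (s), `q_ramp` (s; inflow discharge ramp-up
#'   during spin-up to avoid an impulsive flood-wave start). A fixed `dt`
#'   is clamped per step to the explicit scheme's 2-D stability bound
#'   whenever the grid requires a smaller step; runs stay deterministic.
#' @export
numerical_settings <- function(bundle = c("coarse", "paper"), ...) {
  bundle <- match.arg(bundle)
  s <- list(
    bundle = bundle,
    dt = if (bundle == "paper") 0.04 else 0,
    cfl = 0.7,
    manning_n = 0.03,
    c_mu = 0.09,
    c_e = 1.0,
    turbulence_length = "depth",
    nu_background = 1e-4,
    h_dry = 1e-4,
    coriolis_f = 0,
    order = if (bundle == "paper") 2L else 1L,
    morpho_every = if (bundle == "paper") 5L else 10L,
    max_vel = 50,
    record_dt = 50,
    dt_min = 1e-4,
    q_ramp = 60)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(s))
    if (length(bad)) stop("unknown numerical settings: ",
                          paste(bad, collapse = ", "))
    s <- utils::modifyList(s, ov)
  }
  structure(s, class = "numerical_settings")
}

#' Sediment-transport parameter set
#'
#' Defaults follow the flood-simulation configuration: submerged relative
#' weight 1.65, bed void ratio 0.30, 0.5 m exchange (active) layer,
#' morphological factor 1, Meyer-Peter-Mueller coefficient 8,
#' Itakura-Kishi constants K = 0.008, alpha* = 0.14 (B* = 0.143,
#' eta0 = 0.5), von Karman constant 0.4, reference height 0.05 h, static and
#' kinetic friction factors 1.0 and 0.45.
#'
#' `supply_ratio` scales the sediment flux entering through open
#' boundaries relative to the local equilibrium load: 1 (default) is an
#' equilibrium feed, under which the downstream bar forms by deposition of
#' material routed around the patch; 0 is a clear-water flood whose
#' degradation front erodes the bed from the inflow — physically the
#' regime of progressive flood erosion, but its front speed (set by the
#' bedload flux at the stated discharge) is far too slow to cross a
#' desk-scale domain within affordable morphological time.
#'
#' `shelter_mode` selects the printed piecewise sheltering rule (`"paper"`:
#' constant 0.85 lower branch) or the Ashida-Michiue variant
#' (`"ashida_michiue"`: 0.85/(dk/dm)). `tau_prime_mode` selects the
#' grain-roughness partition for the effective Shields stress
#' (`"partition"`: tau*' = (n'/n)^{3/2} tau*, n' = dm^{1/6}/(7.66 sqrt(g)))
#' or `"identity"` (tau*' = tau*). `kdev_sqrt` toggles the square root in
#' the bed-slope deviation coefficient sqrt(tau*c/(mu_s mu_k tau*)).
#'
#' @param ... overrides for any field.
#' @return list of class `sediment_parameters`.
#' @export
sediment_parameters <- function(...) {
  s <- list(
    s_g = 1.65,
    void_ratio = 0.30,
    exchange_thickness = 0.5,
    mu_s = 1.0,
    mu_k = 0.45,
    morph_factor = 1,
    ik_K = 0.008,
    ik_alpha = 0.14,
    ik_Bstar = 0.143,
    ik_eta0 = 0.5,
    kappa_vk = 0.4,
    z_alpha_coef = 0.05,
    profile_factor_cap = 100,
    mpm_coef = 8,
    schmidt_inv = 1,
    velocity_floor = 1e-6,
    supply_ratio = 1,
    shelter_mode = "paper",
    tau_prime_mode = "partition",
    kdev_sqrt = TRUE,
    nu_w = 1e-6)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(s))
    if (length(bad)) stop("unknown sediment parameters: ",
                          paste(bad, collapse = ", "))
    s <- utils::modifyList(s, ov)
  }
  structure(s, class = "sediment_parameters")
}

# internal: flatten settings + bc into the list the kernels expect
phys_list <- function(settings, bc = NULL, bctype = c("flood", "closed",
                                                      "periodic"),
                      slope = 0) {
  bctype <- match.arg(bctype)
  list(manning_n = settings$manning_n, c_mu = settings$c_mu,
       c_e = settings$c_e, nu_background = settings$nu_background,
       h_dry = settings$h_dry, coriolis_f = settings$coriolis_f,
       slope = slope,
       Q = if (is.null(bc)) 0 else bc$Q,
       stage = if (is.null(bc)) 1 else bc$stage,
       bctype = match(bctype, c("flood", "closed", "periodic")) - 1L,
       order = as.integer(settings$order))
}

sed_list <- function(sp) {
  list(s_g = sp$s_g, void_ratio = sp$void_ratio,
       exchange_thickness = sp$exchange_thickness, mu_s = sp$mu_s,
       mu_k = sp$mu_k, morph_factor = sp$morph_factor, ik_K = sp$ik_K,
       ik_alpha = sp$ik_alpha, ik_Bstar = sp$ik_Bstar, ik_eta0 = sp$ik_eta0,
       kappa_vk = sp$kappa_vk, z_alpha_coef = sp$z_alpha_coef,
       profile_factor_cap = sp$profile_factor_cap, mpm_coef = sp$mpm_coef,
       schmidt_inv = sp$schmidt_inv, velocity_floor = sp$velocity_floor,
       supply_ratio = sp$supply_ratio,
       shelter_mode = match(sp$shelter_mode,
                            c("paper", "ashida_michiue")) - 1L,
       tau_prime_mode = match(sp$tau_prime_mode,
                              c("identity", "partition")) - 1L,
       kdev_sqrt = as.integer(isTRUE(sp$kdev_sqrt)))
}
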