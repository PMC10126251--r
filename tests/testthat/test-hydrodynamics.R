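# Friction, turbulence closure, boundaries, and the finite-volume flow step.

test_that("bottom friction follows Cf = g n^2 / h^(1/3)", {
  fr <- bottom_friction(0, 0, 1)
  expect_equal(fr$taubx, 0)
  expect_equal(fr$tauby, 0)
  # hand oracle: n = 0.03, h = 1, u = 1, v = 0
  fr <- bottom_friction(1, 0, 1, n = 0.03)
  expect_equal(fr$Cf, 9.81 * 0.0009)
  expect_equal(fr$taubx, 0.008829, tolerance = 1e-12)
  expect_equal(fr$tauby, 0)
  # swapping (u, v) swaps the components exactly
  a <- bottom_friction(0.7, -0.3, 0.8)
  b <- bottom_friction(-0.3, 0.7, 0.8)
  expect_equal(a$taubx, b$tauby)
  expect_equal(a$tauby, b$taubx)
  # dry cells carry zero stress
  expect_equal(bottom_friction(1, 1, 0)$taubx, 0)
})

test_that("turbulence closure: kappa = 2.07 u*^2 and nu = (Cmu/Ce) sqrt(kappa) l", {
  tq <- turbulence_quantities(1)
  expect_equal(tq$kappa, 2.07)
  # doubling the speed quadruples kappa exactly
  expect_equal(turbulence_quantities(2)$kappa, 4 * tq$kappa)
  # dimensional identity nu = Cmu kappa^2 / eps with eps = Ce kappa^(3/2)/l
  tq2 <- turbulence_quantities(0.5, l = 2, c_mu = 0.09, c_e = 1)
  expect_equal(tq2$nu, 0.09 / 1 * sqrt(tq2$kappa) * 2)
  # still water floors at the background value
  expect_equal(turbulence_quantities(0, nu_background = 1e-4)$nu, 1e-4)
  nu <- eddy_viscosity(u = 0 * diag(2), v = 0 * diag(2), h = diag(2) * 0 + 1)
  expect_true(all(nu == 1e-4))
})

test_that("inflow discharge distributes by conveyance h^(5/3)", {
  g <- tiny_grid(10, 6, 0.5)
  st <- uniform_flow(g, h0 = 1)
  bc <- boundary_conditions(Q = 0)
  expect_equal(apply_boundaries(st, bc, g)$inflow, rep(0, g$ny))
  # uniform depth -> equal per-cell discharge; bulk speed Q/(W h)
  bc <- boundary_conditions(Q = 8)
  ab <- apply_boundaries(st, bc, g)
  expect_equal(ab$inflow, rep(8 / g$ny, g$ny))
  expect_equal(sum(ab$inflow), 8)
  expect_equal(mean(ab$inflow_velocity), 8 / 6 / 1)
  # deeper cells take proportionally more
  st$h[1, ] <- seq(0.5, 1.5, length.out = g$ny)
  ab <- apply_boundaries(st, bc, g)
  expect_equal(ab$inflow / (g$dy * st$h[1, ]^(5 / 3)),
               rep(ab$inflow[1] / (g$dy[1] * st$h[1, 1]^(5 / 3)), g$ny),
               tolerance = 1e-12)
  # fully dry inflow edge is an error
  st$h[1, ] <- 0
  expect_error(apply_boundaries(st, bc, g), "dry")
})

test_that("still water over a flat bed is an exact fixed point", {
  g <- tiny_grid(8, 4, 0.5)
  st <- uniform_flow(g, h0 = 1)
  s2 <- step_flow(st, g, boundary_conditions(Q = 0), fast_settings(), 0.05)
  expect_equal(s2$h, st$h)
  expect_equal(s2$u, st$u)
  expect_equal(s2$v, st$v)
})

test_that("water volume budget closes to boundary fluxes each step", {
  sc <- test_scenario()
  g <- scenario_grid(sc)
  st <- uniform_flow(g, h0 = 1)
  set <- fast_settings()
  A <- cell_areas(g)
  s <- st
  for (i in 1:50) {
    s2 <- step_flow(s, g, sc$bc, set, 0.01)
    d <- attr(s2, "diagnostics")
    expect_lt(d$residual, 1e-8)
    dV <- sum((s2$h - s$h) * A)
    expect_equal(dV, d$vol_in - d$vol_out + d$clamp,
                 tolerance = 1e-8 * max(1, abs(dV)))
    s <- s2
  }
})

test_that("sloped periodic channel converges to the Manning normal depth", {
  S <- 1e-3; n <- 0.03; q <- 1.0
  hn <- (q * n / sqrt(S))^(3 / 5)
  g <- build_grid(c(20, 3), list(), 0.249, 0.25)
  st <- init_flow_state(g, depth = hn, bed = 0)
  st$u[] <- q / hn
  ph <- rootmorph:::phys_list(numerical_settings("coarse", manning_n = n),
                              NULL, "periodic", slope = S)
  h <- st$h; u <- st$u; v <- st$v; nu <- st$nu
  for (i in 1:6000) {
    o <- rootmorph:::cpp_flow_step(h, u, v, st$z, nu, g$mask, g$xc, g$yc,
                                   g$dx, g$dy, ph, 0.02)
    h <- o$h; u <- o$u; v <- o$v; nu <- o$nu
  }
  # periodic mass is fixed at the normal depth; equilibrium discharge
  # recovers q = h^(5/3) sqrt(S)/n within 1%
  expect_equal(mean(h), hn, tolerance = 1e-6)
  expect_equal(mean(u * h), q, tolerance = 0.01)
})

test_that("increasing Manning n decreases the equilibrium channel velocity", {
  g <- build_grid(c(10, 2), list(), 0.249, 0.25)
  speeds <- vapply(c(0.02, 0.04), function(n) {
    st <- init_flow_state(g, depth = 1, bed = 0)
    st$u[] <- 1
    ph <- rootmorph:::phys_list(numerical_settings("coarse", manning_n = n),
                                NULL, "periodic", slope = 1e-3)
    h <- st$h; u <- st$u; v <- st$v; nu <- st$nu
    for (i in 1:3000) {
      o <- rootmorph:::cpp_flow_step(h, u, v, st$z, nu, g$mask, g$xc, g$yc,
                                     g$dx, g$dy, ph, 0.02)
      h <- o$h; u <- o$u; v <- o$v; nu <- o$nu
    }
    mean(u)
  }, numeric(1))
  expect_gt(speeds[1], speeds[2])
})

test_that("mirror-symmetric scenario stays mirror-symmetric early on", {
  # 19 roots = two complete hexagonal rings, a y-symmetric layout
  sc <- test_scenario("spacing_sweep_fixed_N",
                      patch_center = c(9, 4), domain = c(18, 8),
                      Q = 8 / 30 * 40, n_roots = 19, spacing = 0.45,
                      patch_diameter = NULL,
                      near_cell_area = 0.0099, far_cell_area = 0.01)
  g <- scenario_grid(sc)
  # the (uniform) grid is symmetric about the centerline
  expect_equal(g$dy, rev(g$dy), tolerance = 1e-9)
  r <- simulate_flow(sc, fast_settings(), duration = 30)
  u <- r$flow$u; v <- r$flow$v; h <- r$flow$h
  flip <- function(m) m[, rev(seq_len(ncol(m)))]
  expect_equal(u, flip(u), tolerance = 1e-6)
  expect_equal(h, flip(h), tolerance = 1e-6)
  expect_equal(v, -flip(v), tolerance = 1e-6)
})

test_that("wake transitions from steady deceleration to oscillation with phi", {
  base <- list(domain = c(26, 12), patch_center = c(8, 6), Q = 12 / 30 * 40,
               patch_diameter = 2.4, near_cell_area = 0.01,
               far_cell_area = 1.0, spin_up = 400)
  probe <- function(dens) {
    sc <- scenario_preset("density_sweep_fixed_area",
                          utils::modifyList(base, list(density = dens)))
    D <- sc$patches[[1]]$patch_diameter
    xe <- sc$patch_center[1] + D / 2
    r <- simulate_flow(sc, fast_settings(record_dt = 2),
                       probe_xy = rbind(c(xe + 1.5 * D, 6)))
    late <- r$probes$time > 250
    c(osc = sd(r$probes$v[late, 1]),
      slow = mean(r$probes$u[late, 1]),
      pvc = percent_velocity_change(r$flow$u, r$flow$v, r$grid,
                                    sc$patches[[1]]))
  }
  lo <- probe(0.8)   # sparse: steady decelerated wake
  hi <- probe(6.0)   # dense: patch-scale turbulence
  expect_lt(lo["osc"], 0.15)           # no periodic oscillation
  expect_gt(hi["osc"], 2 * lo["osc"])  # transverse oscillation above onset
  expect_lt(lo["slow"], 12 / 30 * 40 / 12)  # wake slower than the bulk flow
  expect_gt(hi["pvc"], lo["pvc"])      # velocity change grows with phi
})

test_that("curvature: parallel flow, solid-body rotation, mirror antisymmetry", {
  g <- tiny_grid(10, 10, 0.25)
  u0 <- matrix(0.8, g$nx, g$ny); v0 <- matrix(0.3, g$nx, g$ny)
  expect_true(all(streamline_curvature(u0, v0, g) == 0))
  # solid-body rotation about the domain center: 1/r = 1/R
  om <- 0.5
  xc <- outer(g$xc - 5, rep(1, g$ny)); yc <- outer(rep(1, g$nx), g$yc - 5)
  u <- -om * yc; v <- om * xc
  invr <- streamline_curvature(u, v, g)
  R <- sqrt(xc^2 + yc^2)
  interior <- R > 1 & abs(xc) < 4 & abs(yc) < 4
  expect_equal(invr[interior], 1 / R[interior], tolerance = 0.005)
  # mirror reflection flips the sign
  invr_m <- streamline_curvature(u[, ncol(u):1], -v[, ncol(v):1], g)
  expect_equal(invr_m, -invr[, ncol(invr):1], tolerance = 1e-12)
})
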