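# Sediment closures, directional splitting, suspended load and bed evolution.

test_that("Shields stress: trivial and hand-arithmetic oracles", {
  expect_equal(shields_stress(0, 1.65, 0.01), 0)
  expect_equal(shields_stress(0.1, 1.65, 0.0032),
               0.01 / (1.65 * 9.81 * 0.0032), tolerance = 1e-12)
  # scales as 1/d at fixed u*
  expect_equal(shields_stress(0.2, 1.65, 0.002),
               2 * shields_stress(0.2, 1.65, 0.004))
})

test_that("Iwagaki critical Shields: continuity, coarse limit, fallback", {
  expect_equal(critical_shields_iwagaki(0.01, mode = "constant"), 0.05)
  expect_equal(critical_shields_iwagaki(1e-5, mode = "constant"), 0.05)
  # piecewise boundaries (cm): 0.303, 0.118, 0.0565, 0.0065; the largest
  # jump of the standard published constants is ~2.1% (at d = 0.303 cm)
  for (db in c(0.303, 0.118, 0.0565, 0.0065) * 1e-2) {
    lo <- critical_shields_iwagaki(db * (1 - 1e-9))
    hi <- critical_shields_iwagaki(db * (1 + 1e-9))
    expect_lt(abs(hi - lo) / lo, 0.022)
  }
  # coarse-gravel limit approaches a constant Shields number near 0.05
  expect_equal(critical_shields_iwagaki(0.02), 0.05, tolerance = 0.002)
  expect_equal(critical_shields_iwagaki(0.034), 0.05, tolerance = 0.002)
})

test_that("Meyer-Peter-Mueller bedload: threshold and coefficient", {
  expect_equal(bedload_mpm(0.03, 0.05, 0.003), 0)   # below threshold
  d <- 0.0032; sg <- 1.65
  # unit excess stress recovers the dimensionless coefficient 8
  expect_equal(bedload_mpm(1.05, 0.05, d, sg) / sqrt(sg * 9.81 * d^3), 8)
  # direct evaluation at excess 0.04
  expect_equal(bedload_mpm(0.09, 0.05, d, sg),
               8 * sqrt(sg * 9.81 * d^3) * 0.04^1.5, tolerance = 1e-12)
})

test_that("Rubey settling: monotone, Stokes and sqrt(d) limits", {
  d <- exp(seq(log(1e-6), log(0.034), length.out = 40))
  w <- settling_rubey(d)
  expect_true(all(diff(w) > 0))
  # fine limit: log-log slope -> 2 (Stokes)
  sl_fine <- diff(log(settling_rubey(c(1e-6, 2e-6)))) / log(2)
  expect_equal(sl_fine, 2, tolerance = 0.01)
  # coarse limit: slope -> 0.5
  sl_coarse <- diff(log(settling_rubey(c(0.017, 0.034)))) / log(2)
  expect_equal(sl_coarse, 0.5, tolerance = 0.01)
})

test_that("Itakura-Kishi entrainment: floor, monotonicity, threshold root", {
  expect_equal(entrainment_itakura_kishi(0, 0, 0.01), 0)
  # non-decreasing in u* at fixed w0 (tau* follows u*)
  us <- seq(0.01, 0.4, length.out = 60)
  es <- entrainment_itakura_kishi(us, shields_stress(us, 1.65, 0.0002), 0.02)
  expect_true(all(diff(es) >= -1e-15))
  # exact zero at the bracket root: alpha* (rho/sigma) u* Omega = tau* w0
  tau <- 0.2; u_star <- 0.1
  om <- ik_omega(tau)
  w0_root <- 0.14 / (1 + 1.65) * u_star * om / tau
  expect_equal(entrainment_itakura_kishi(u_star, tau, w0_root), 0)
  expect_gt(entrainment_itakura_kishi(u_star, tau, w0_root * 0.99), 0)
  # simplified pickup-law fallback stays available
  expect_gte(entrainment_itakura_kishi(0.3, 0.2, 0.01, mode = "simplified"), 0)
})

test_that("suspended-sediment profile: reference height and e-folding", {
  expect_equal(reference_concentration_profile(0.05, 1, 0.01, 0.1), 1)
  # h = 1 m puts the reference height at 0.05 m
  expect_equal(0.05 * 1, 0.05)
  # ratio e^-1 at (z - za) = h kappa u*/(6 w0)
  h <- 2; w0 <- 0.02; us <- 0.1
  zstar <- 0.05 * h + h * 0.4 * us / (6 * w0)
  expect_equal(reference_concentration_profile(zstar, h, w0, us), exp(-1),
               tolerance = 1e-12)
})

test_that("sheltering: printed branches, identity at dm, mode agreement", {
  # printed lower branch is the constant 0.85
  expect_equal(sheltering_correction(0.2, 1), 0.85)
  expect_equal(sheltering_correction(0.4, 1), 0.85)
  # dk = dm gives exactly 1 (ln 1 = 0)
  expect_equal(sheltering_correction(0.01, 0.01), 1)
  # Ashida-Michiue lower branch 0.85/(dk/dm) meets the upper branch at 0.4
  am <- sheltering_correction(0.4, 1, mode = "ashida_michiue")
  up <- 1 / (1 + 0.34 * log(0.40001))^2
  expect_equal(am, 0.85 / 0.4)
  expect_lt(abs(am - up) / up, 0.01)
})

test_that("directional split: straight flow, slope deviation, rotation", {
  # straight flow over a flat bed: all transport streamwise
  ds <- directional_split(qb = 1e-4, u = 1, v = 0, u_star = 0.08, h = 1,
                          inv_r = 0, dzdx = 0, dzdy = 0,
                          tau_star = 0.2, tau_c = 0.04)
  expect_equal(ds$q_n, 0)
  expect_equal(ds$q_s, 1e-4)
  expect_equal(ds$q_x, 1e-4)
  expect_equal(ds$q_y, 0)
  # pure transverse slope on straight flow: q_n = -qb kdev dz/dn
  ds <- directional_split(1e-4, 1, 0, 0.08, 1, 0, dzdx = 0, dzdy = 0.02,
                          tau_star = 0.2, tau_c = 0.04, mu_s = 1, mu_k = 0.45)
  kdev <- sqrt(0.04 / (1 * 0.45 * 0.2))
  expect_equal(ds$q_n, -1e-4 * kdev * 0.02, tolerance = 1e-12)
  # rotation preserves magnitude for any flow angle
  ds <- directional_split(2e-4, 0.6, -0.8, 0.08, 1, 0.05, 0.01, -0.02,
                          0.2, 0.04)
  expect_equal(ds$q_x^2 + ds$q_y^2, ds$q_s^2 + ds$q_n^2, tolerance = 1e-15)
})

test_that("kernel transport fields match the R closure pipeline (dual route)", {
  g <- tiny_grid(8, 6, 0.25)
  sc_set <- numerical_settings("coarse")
  pp <- sediment_parameters()
  mix <- build_grain_mixture(2e-3, 6e-3, 3.2e-3, n_classes = 1)
  st <- init_flow_state(g, depth = 1, bed = 10)
  # smooth spatially varying flow and bed
  X <- outer(g$xc, rep(1, g$ny)); Y <- outer(rep(1, g$nx), g$yc)
  st$u <- 0.9 + 0.2 * sin(X / 2) * cos(Y / 3)
  st$v <- 0.15 * sin(Y / 2 + 0.3)
  st$z <- 10 + 0.05 * sin(X / 3) * sin(Y / 2)
  sed <- init_sediment_state(g, mix)
  tf <- transport_fields(st, sed, g, sc_set, pp)

  # independent R route on interior cells
  d <- mix$class_diameters
  fr <- bottom_friction(st$u, st$v, st$h, sc_set$manning_n)
  us <- sqrt(fr$Cf) * sqrt(st$u^2 + st$v^2)
  tau <- shields_stress(us, pp$s_g, d)
  nprime <- d^(1 / 6) / (7.66 * sqrt(9.81))
  tau_eff <- pmin(1, (nprime / sc_set$manning_n)^1.5) * tau
  tau_c <- critical_shields_iwagaki(d, pp$s_g) * sheltering_correction(d, d)
  qb <- matrix(bedload_mpm(tau_eff, tau_c, d, pp$s_g), g$nx, g$ny)
  invr <- streamline_curvature(st$u, st$v, g)
  dzdx <- matrix(0, g$nx, g$ny); dzdy <- dzdx
  dzdx[2:(g$nx - 1), ] <- (st$z[3:g$nx, ] - st$z[1:(g$nx - 2), ]) /
    (g$xc[3] - g$xc[1])
  dzdy[, 2:(g$ny - 1)] <- (st$z[, 3:g$ny] - st$z[, 1:(g$ny - 2)]) /
    (g$yc[3] - g$yc[1])
  ds <- directional_split(qb, st$u, st$v, us, st$h, invr, dzdx, dzdy,
                          tau, tau_c, pp$mu_s, pp$mu_k)
  interior <- cbind(rep(2:(g$nx - 1), g$ny - 2),
                    rep(2:(g$ny - 1), each = g$nx - 2))
  expect_equal(tf$qxk[, , 1][interior], ds$q_x[interior], tolerance = 1e-10)
  expect_equal(tf$qyk[, , 1][interior], ds$q_y[interior], tolerance = 1e-10)
})

test_that("suspended load: equilibrium box, settling decay, blob advection", {
  g <- tiny_grid(10, 4, 0.5)
  set <- numerical_settings("coarse")
  pp <- sediment_parameters()
  mix <- build_grain_mixture(1e-4, 1e-3, 3e-4, n_classes = 1)
  w0 <- mix$settling_velocities
  st <- init_flow_state(g, depth = 1, bed = 10)
  sed <- init_sediment_state(g, mix)
  nk <- 1

  # (a) exchange equilibrium: Es = C_alpha leaves C unchanged in a no-flux box
  sed$Ch[] <- 0.01
  pf <- 3
  tf <- list(Esk = array(pf * 0.01 / 1, c(g$nx, g$ny, nk)),
             pfk = array(pf, c(g$nx, g$ny, nk)))
  s2 <- suspended_step(sed, st, tf, g, set, pp, NULL, dt = 0.5)
  expect_equal(s2$Ch, sed$Ch, tolerance = 1e-12)

  # (b) pure settling: exponential decay at rate pf w0 / h
  tf0 <- list(Esk = array(0, c(g$nx, g$ny, nk)),
              pfk = array(pf, c(g$nx, g$ny, nk)))
  s <- sed; s$Ch[] <- 0.02
  dt <- 0.05; nstep <- 200
  for (i in seq_len(nstep)) s <- suspended_step(s, st, tf0, g, set, pp, NULL, dt)
  rate <- pf * w0 / 1
  expect_equal(mean(s$Ch), 0.02 * exp(-rate * dt * nstep), tolerance = 0.02)

  # (c) blob advection: centroid moves with the flow within 5%
  g2 <- tiny_grid(20, 4, 0.25)
  st2 <- uniform_flow(g2, h0 = 1, u0 = 0.8)
  sed2 <- init_sediment_state(g2, mix)
  X <- outer(g2$xc, rep(1, g2$ny))
  sed2$Ch[, , 1] <- 0.01 * exp(-(X - 5)^2 / 0.5)
  tfz <- list(Esk = array(0, c(g2$nx, g2$ny, nk)),
              pfk = array(0, c(g2$nx, g2$ny, nk)))
  ppz <- sediment_parameters(profile_factor_cap = 0)  # no settling loss
  s2 <- sed2
  for (i in 1:40) s2 <- suspended_step(s2, st2, tfz, g2, set, ppz,
                                       boundary_conditions(Q = 0), dt = 0.25)
  centroid <- function(Ch) sum(X * Ch[, , 1]) / sum(Ch[, , 1])
  moved <- centroid(s2$Ch) - centroid(sed2$Ch)
  expect_equal(moved, 0.8 * 10, tolerance = 0.05 * 8)
})

test_that("bed update: zero transport and divergence-free bedload fix z", {
  g <- tiny_grid(10, 4, 0.5)
  set <- numerical_settings("coarse"); pp <- sediment_parameters()
  mix <- build_grain_mixture(2e-3, 6e-3, 3.2e-3, n_classes = 1)
  st <- init_flow_state(g, depth = 1, bed = 10)
  sed <- init_sediment_state(g, mix)
  dims <- c(g$nx, g$ny, 1)
  zero <- array(0, dims)
  tf <- list(qxk = zero, qyk = zero)
  bu <- bed_update(st, sed, tf, zero, zero, g, set, pp, NULL, dt = 10)
  expect_equal(bu$flow$z, st$z)
  expect_equal(bu$sed$p, sed$p)
  # uniform (divergence-free) bedload also leaves z unchanged in the interior
  tf2 <- list(qxk = zero + 5e-4, qyk = zero)
  bu2 <- bed_update(st, sed, tf2, zero, zero, g, set, pp,
                    boundary_conditions(Q = 0), dt = 10)
  expect_equal(bu2$flow$z[2:(g$nx - 1), ], st$z[2:(g$nx - 1), ])
})

test_that("1-D linear bedload ramp erodes uniformly at the Exner rate", {
  g <- tiny_grid(10, 4, 0.5)
  set <- numerical_settings("coarse"); pp <- sediment_parameters()
  mix <- build_grain_mixture(2e-3, 6e-3, 3.2e-3, n_classes = 1)
  st <- init_flow_state(g, depth = 1, bed = 10)
  sed <- init_sediment_state(g, mix)
  a <- 1e-4  # dqx/dx (m^2/s per m)
  qx <- array(a * outer(g$xc, rep(1, g$ny)), c(g$nx, g$ny, 1))
  zero <- array(0, c(g$nx, g$ny, 1))
  dt <- 5
  bu <- bed_update(st, sed, list(qxk = qx, qyk = zero), zero, zero,
                   g, set, pp, boundary_conditions(Q = 0), dt)
  dz <- bu$flow$z - st$z
  expected <- -a * dt / (1 - pp$void_ratio)
  # interior cells erode at exactly -(1/(1-lambda)) dqx/dx
  expect_equal(dz[2:(g$nx - 1), ], matrix(expected, g$nx - 2, g$ny),
               tolerance = 1e-12)
})

test_that("no morphodynamic change below the threshold stress", {
  g <- tiny_grid(10, 4, 0.5)
  set <- numerical_settings("coarse"); pp <- sediment_parameters()
  mix <- build_grain_mixture(0.001e-3, 34e-3, 3.2e-3, n_classes = 5)
  st <- uniform_flow(g, h0 = 1, u0 = 0.001)   # far below any threshold
  sed <- init_sediment_state(g, mix)
  tf <- transport_fields(st, sed, g, set, pp)
  expect_true(all(tf$qxk == 0))
  expect_true(all(tf$qyk == 0))
  expect_true(all(tf$Esk == 0))
  s2 <- suspended_step(sed, st, tf, g, set, pp, NULL, 1)
  ex <- attr(s2, "exchange")
  bu <- bed_update(st, s2, tf, ex$dep, ex$ent, g, set, pp, NULL, 1)
  expect_equal(bu$flow$z, st$z)
})

test_that("single-class mixture keeps surface fractions at exactly 1", {
  sc <- test_scenario(flood_duration = 60)
  sc$mixture <- list(d_min = 2e-3, d_max = 6e-3, target_d50 = 3.2e-3,
                     n_classes = 1)
  r <- run_flood(sc, fast_settings())
  expect_true(all(r$sed$p == 1))
})

test_that("global sediment budget closes over a coupled run", {
  sc <- test_scenario(flood_duration = 200)
  r <- run_flood(sc, fast_settings())
  lam <- sediment_parameters()$void_ratio
  A <- cell_areas(r$grid)
  d_bed <- sum((r$flow$z - r$z_initial) * A) * (1 - lam)
  d_susp <- sum(apply(r$sed$Ch, 3, function(m) sum(m * A)))
  led <- r$diagnostics$flood$sediment
  net_in <- (led$susp_in + led$bed_in) - (led$susp_out + led$bed_out)
  moved <- led$entrained + led$deposited +
    led$susp_in + led$susp_out + led$bed_in + led$bed_out
  expect_lt(abs(d_bed + d_susp - net_in - led$clip) / max(moved, 1e-12), 1e-6)
})
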