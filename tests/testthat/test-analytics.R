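# Closed-form oracles and the post-processing diagnostics.

test_that("Poiseuille oracle: no-slip, peak value, flow-rate quadrature", {
  expect_equal(analytic_poiseuille(1, G = 4, mu = 1, R = 1), 0)
  expect_equal(analytic_poiseuille(0, G = 4, mu = 1, R = 1), 1)
  # quadrature of the profile recovers Q = pi G R^4 / (8 mu)
  G <- 7; mu <- 0.03; R <- 0.01
  Q <- stats::integrate(function(r)
    2 * pi * r * analytic_poiseuille(r, G, mu, R), 0, R)$value
  expect_equal(Q, pi * G * R^4 / (8 * mu), tolerance = 1e-8)
})

test_that("Hartmann pipe oracle: no-slip, Bessel value, Poiseuille limit", {
  expect_equal(analytic_mhd_pipe_profile(1, 1, 1, 1, Ha = 10), 0)
  # centerline at Ha = 10: (1/100)(1 - 1/I0(10))
  expect_equal(analytic_mhd_pipe_profile(0, 1, 1, 1, Ha = 10),
               (1 - 1 / besselI(10, 0)) / 100)
  expect_equal(analytic_mhd_pipe_profile(0, 1, 1, 1, Ha = 10), 9.99645e-3,
               tolerance = 1e-5)
  # small-Ha limit recovers Poiseuille pointwise within 0.1%
  r <- seq(0, 0.99, by = 0.11)
  u0 <- analytic_poiseuille(r, 1, 1, 1)
  u_small <- analytic_mhd_pipe_profile(r, 1, 1, 1, Ha = 0.01)
  expect_lt(max(abs(u_small - u0) / u0), 1e-3)
  expect_equal(analytic_mhd_pipe_profile(r, 1, 1, 1, Ha = 0), u0)
})

test_that("wall shear stress: zero flow, Poiseuille value, throat peak", {
  fx <- make_fixture("straight_tube")
  mesh <- fx$mesh
  cfg <- solver_config()
  st0 <- init_state(mesh, fx$props, pulsatile_pressure(0, 0), cfg,
                    warm_start = FALSE)
  w0 <- wall_shear_stress(st0, mesh)
  expect_equal(w0$tau_w, rep(0, mesh$nz))

  mesh2 <- build_mesh(straight_geom(), 12, 32)
  props <- fluid_props(carreau = newtonian_params(0.036))
  pp <- pulsatile_pressure(34.5, 0)
  st <- solve_steady(mesh2, props, magnetic_config(B0 = 0, z_on = 0.02,
                                                   z_off = 0.07),
                     pp, solver_config(max_outer = 500), quiet = TRUE)
  w <- wall_shear_stress(st, mesh2)
  tau_ex <- (pp$Pm / 0.07) * 0.01 / 2
  expect_lt(max(abs(w$tau_w - tau_ex)) / tau_ex, 0.02)
})

test_that("stenosed wall stress peaks near the throat and drops after it", {
  geom <- base_geom(0.6)
  mesh <- build_mesh(geom, 48, 16)
  pp <- pulsatile_pressure(34.5, 0)
  st <- solve_steady(mesh, fluid_props(),
                     magnetic_config(B0 = 0, z_on = 0.02, z_off = 0.07),
                     pp, solver_config(max_outer = 600), quiet = TRUE)
  w <- wall_shear_stress(st, mesh)
  z_throat <- geom$d + geom$L0 / 2
  ipk <- which.max(abs(w$tau_w))
  # peak at/near the throat (within two cells)
  expect_lt(abs(w$z[ipk] - z_throat), 2.5 * diff(mesh$z_f)[1])
  # sharp drop after the stenosis: far-downstream stress is a small
  # fraction of the peak
  post <- w$z > geom$d + geom$L0 + 0.005
  expect_lt(max(abs(w$tau_w[post])), 0.2 * abs(w$tau_w[ipk]))
})

test_that("flow resistance matches the Poiseuille law and is cumulative", {
  mesh <- build_mesh(straight_geom(), 16, 32)
  props <- fluid_props(carreau = newtonian_params(0.036))
  pp <- pulsatile_pressure(34.5, 0)
  st <- solve_steady(mesh, props, magnetic_config(B0 = 0, z_on = 0.02,
                                                  z_off = 0.07),
                     pp, solver_config(max_outer = 500), quiet = TRUE)
  fr <- flow_resistance(st, mesh, p_in = pp$Pm)
  lam_ex <- 8 * 0.036 * 0.07 / (pi * 0.01^4)
  expect_lt(abs(fr$total - lam_ex) / lam_ex, 0.02)
  # attached steady flow: Lambda(z) non-decreasing downstream
  expect_true(all(diff(fr$profile$Lambda) > -1e-9 * abs(fr$total)))
})

test_that("resistance is undefined at vanishing flow", {
  fx <- make_fixture("straight_tube")
  st0 <- init_state(fx$mesh, fx$props, pulsatile_pressure(0, 0),
                    solver_config(), warm_start = FALSE)
  expect_error(flow_resistance(st0, fx$mesh), "undefined")
})

test_that("recirculation detector is definitionally empty for attached flow", {
  mesh <- build_mesh(straight_geom(), 16, 16)
  props <- fluid_props(carreau = newtonian_params(0.036))
  st <- solve_steady(mesh, props, magnetic_config(B0 = 0, z_on = 0.02,
                                                  z_off = 0.07),
                     pulsatile_pressure(34.5, 0),
                     solver_config(max_outer = 500), quiet = TRUE)
  expect_true(all(st$u_z >= -1e-12))
  rec <- detect_recirculation(st, mesh)
  expect_false(rec$present)
  expect_equal(rec$extent, 0)
  expect_equal(rec$n_cells, 0L)
})

test_that("probe traces run from the axis to the wall", {
  fx <- make_fixture("tiny_stenosis")
  st <- init_state(fx$mesh, fx$props, pulsatile_pressure(34.5, 0.2),
                   solver_config())
  pr <- extract_probe(st, fx$mesh, 0.02)
  expect_true(all(diff(pr$r) > 0))
  icol <- which.min(abs(fx$mesh$z_c - 0.02))
  expect_lt(max(pr$r), stenosis_radius(fx$mesh$z_c[icol], fx$mesh$geom))
  expect_equal(unique(pr$z_station), 0.02)
  expect_equal(nrow(pr), fx$mesh$nr)
})

test_that("observed order exceeds one on a smooth (double-cosine) wall", {
  # the as-printed asymmetric profile has a slope break at the throat that
  # limits peak-stress convergence; the smooth variant shows the scheme's
  # nominal order
  scn <- preset("paper_case_50pct")
  g <- scn$geometry
  gs <- stenosis_geometry(g$R0, g$L_vessel, g$d, g$L0, g$delta,
                          profile = "cosine")
  study <- grid_convergence_study(gs, scn$fluid, scn$magnetics,
                                  pulsatile_pressure(scn$pressure$Pm, 0),
                                  scn$solver, nz0 = 24, nr0 = 8,
                                  levels = 3)
  expect_true(all(diff(study$rel_err) < 0))
  expect_gt(attr(study, "observed_order"), 1)
})

test_that("constricted-geometry energy audit gap shrinks under refinement", {
  # at a strong constriction the audit gap measures the upwind scheme's
  # artificial dissipation in the throat jet; it must decrease with
  # resolution even though it does not vanish at study resolutions
  scn <- scenario(geometry = list(blockage_fraction = 0.5))
  pp0 <- pulsatile_pressure(scn$pressure$Pm, 0)
  closure <- sapply(list(c(32, 12), c(64, 24)), function(nm) {
    mesh <- build_mesh(scn$geometry, nm[1], nm[2])
    st <- solve_steady(mesh, scn$fluid, scn$magnetics, pp0, scn$solver,
                       quiet = TRUE)
    mechanical_energy_audit(st, mesh, scn$fluid, scn$magnetics,
                            pp0$Pm)$closure_rel
  })
  expect_lt(closure[2], closure[1])
  expect_lt(closure[2], 0.12)
})
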