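# SIMPLE solver: closed-form oracles, conservation, determinism, and the
# qualitative physics the damping model must reproduce.

newt_props <- function(mu = 0.036) fluid_props(carreau = newtonian_params(mu))
no_field <- function() magnetic_config(B0 = 0, z_on = 0.02, z_off = 0.07)
uniform_field <- function(Ha) magnetic_config(
  Ha = Ha, z_on = -1, z_off = 1, ramp_len = 0, sigma = 0.8,
  R0 = 0.01, mu_ref = 0.036)

test_that("straight-tube solve reproduces Poiseuille within 1%", {
  geom <- straight_geom()
  mesh <- build_mesh(geom, 16, 32)
  pp <- pulsatile_pressure(Pm = 34.5, eps = 0)
  st <- solve_steady(mesh, newt_props(), no_field(), pp,
                     solver_config(max_outer = 500), quiet = TRUE)
  expect_true(attr(st, "converged"))
  G <- pp$Pm / geom$L_vessel
  i <- mesh$nz %/% 2
  uex <- analytic_poiseuille(mesh$rc_cell[i, ], G, 0.036, geom$R0)
  expect_lt(max(abs(st$u_z[i, ] - uex)) / max(uex), 0.01)
  # flow rate against the classic quadrature Q = pi G R^4 / (8 mu)
  Qex <- pi * G * geom$R0^4 / (8 * 0.036)
  expect_lt(abs(flow_rate(st, mesh) - Qex) / Qex, 0.01)
})

test_that("uniform transverse damping matches the Bessel-form profile", {
  geom <- straight_geom()
  mesh <- build_mesh(geom, 16, 32)
  pp <- pulsatile_pressure(Pm = 34.5, eps = 0)
  G <- pp$Pm / geom$L_vessel
  for (Ha in c(1, 10)) {
    st <- solve_steady(mesh, newt_props(), uniform_field(Ha), pp,
                       solver_config(max_outer = 600), quiet = TRUE)
    i <- mesh$nz %/% 2
    uex <- analytic_mhd_pipe_profile(mesh$rc_cell[i, ], G, 0.036,
                                     geom$R0, Ha)
    expect_lt(max(abs(st$u_z[i, ] - uex)) / max(uex), 0.02)
  }
})

test_that("converged states conserve mass per cell and globally", {
  geom <- base_geom(0.5)
  mesh <- build_mesh(geom, 32, 12)
  pp <- pulsatile_pressure(Pm = 34.5, eps = 0)
  st <- solve_steady(mesh, fluid_props(), no_field(), pp,
                     solver_config(max_outer = 600), quiet = TRUE)
  expect_true(attr(st, "converged"))
  inlet_flux <- sum(abs(st$Fz[1, ]))
  imb <- stenoflow:::cell_imbalance(mesh, st$Fz, st$Fe)
  expect_lt(max(abs(imb)), 1e-6 * inlet_flux)
  expect_lt(abs(sum(st$Fz[1, ]) - sum(st$Fz[mesh$nz + 1, ])),
            1e-6 * inlet_flux)
})

test_that("a converged state is a fixed point of the outer iteration", {
  geom <- straight_geom()
  mesh <- build_mesh(geom, 12, 16)
  pp <- pulsatile_pressure(Pm = 34.5, eps = 0)
  cfg <- solver_config(max_outer = 500)
  st <- solve_steady(mesh, newt_props(), no_field(), pp, cfg, quiet = TRUE)
  st2 <- simple_iterate(st, mesh, newt_props(), no_field(), pp, cfg,
                        quiet = TRUE)
  expect_lte(length(attr(st2, "residuals")), 3)
  expect_lt(max(abs(st2$u_z - st$u_z)), 1e-4 * max(abs(st$u_z)))
})

test_that("centerline velocity is non-increasing in Hartmann number", {
  geom <- base_geom(0.5)
  mesh <- build_mesh(geom, 32, 12)
  pp <- pulsatile_pressure(Pm = 34.5, eps = 0)
  cfg <- solver_config(max_outer = 600)
  ucl <- sapply(c(0, 0.1, 1, 3), function(Ha) {
    mag <- if (Ha == 0) no_field() else
      magnetic_config(Ha = Ha, z_on = geom$d + geom$L0 / 2,
                      z_off = geom$L_vessel, ramp_len = 0.1 * geom$L0,
                      sigma = 0.8, R0 = geom$R0, mu_ref = 0.036)
    st <- solve_steady(mesh, fluid_props(), mag, pp, cfg, quiet = TRUE)
    st$u_z[mesh$nz %/% 2, 1]
  })
  expect_true(all(diff(ucl) <= 1e-12))
})

test_that("with zero applied field the magnetic terms change nothing", {
  geom <- base_geom(0.5)
  mesh <- build_mesh(geom, 24, 8)
  pp <- pulsatile_pressure(Pm = 34.5, eps = 0)
  cfg <- solver_config(max_outer = 400)
  st0 <- solve_steady(mesh, fluid_props(), no_field(), pp, cfg, quiet = TRUE)
  stB <- solve_steady(mesh, fluid_props(),
                      magnetic_config(B0 = 0, z_on = 0.01, z_off = 0.05,
                                      ramp_len = 0.001),
                      pp, cfg, quiet = TRUE)
  expect_identical(st0$u_z, stB$u_z)
  expect_identical(st0$p, stB$p)
})

test_that("shear-thinning flattens the profile against Newtonian at equal flow", {
  geom <- straight_geom()
  mesh <- build_mesh(geom, 12, 24)
  # slow flow so the shear rates sit on the thinning branch of the Carreau
  # curve rather than the high-shear plateau
  pp <- pulsatile_pressure(Pm = 3.45, eps = 0)
  cfg <- solver_config(max_outer = 500)
  stC <- solve_steady(mesh, fluid_props(), no_field(), pp, cfg, quiet = TRUE)
  stN <- solve_steady(mesh, newt_props(), no_field(), pp, cfg, quiet = TRUE)
  i <- mesh$nz %/% 2
  ratio <- function(st) {
    u <- st$u_z[i, ]
    w <- mesh$Az_zface[i, ]     # annular weights
    u[1] / (sum(u * w) / sum(w))
  }
  # center-to-mean velocity ratio: 2 for a parabola, smaller when the
  # core is blunted by shear thinning
  expect_lt(ratio(stC), ratio(stN) - 0.01)
})

test_that("transient stepping is deterministic and first-order in dt", {
  geom <- base_geom(0.5)
  mesh <- build_mesh(geom, 24, 8)
  props <- fluid_props()
  mag <- magnetic_config(B0 = 0, z_on = 0.02, z_off = 0.07)
  pp <- pulsatile_pressure(Pm = 34.5, eps = 0.2)
  run_to <- function(dt, t_stop) {
    cfg <- solver_config(dt = dt, t_end = t_stop, max_outer = 600,
                         outer_tol = 1e-8, du_tol = 1e-8)
    st <- init_state(mesh, props, pp, cfg)
    for (k in seq_len(round(t_stop / dt)))
      st <- advance(st, mesh, props, mag, pp, cfg, quiet = TRUE)
    st
  }
  a <- run_to(0.02, 0.2)
  b <- run_to(0.02, 0.2)
  expect_identical(a$u_z, b$u_z)     # bit-for-bit reproducible
  expect_identical(a$T, b$T)
  # Richardson: halving dt should roughly halve the time-stepping error
  c2 <- run_to(0.01, 0.2)
  c4 <- run_to(0.005, 0.2)
  i <- mesh$nz %/% 2
  e1 <- abs(a$u_z[i, 1] - c2$u_z[i, 1])
  e2 <- abs(c2$u_z[i, 1] - c4$u_z[i, 1])
  expect_gt(e1 / e2, 1.4)
  expect_lt(e1 / e2, 3.5)
})

test_that("zero driving pressure yields a quiescent state", {
  geom <- base_geom(0.5)
  mesh <- build_mesh(geom, 24, 8)
  pp <- pulsatile_pressure(Pm = 0, eps = 0)
  st <- solve_steady(mesh, fluid_props(), no_field(), pp,
                     solver_config(), quiet = TRUE)
  expect_true(attr(st, "converged"))
  expect_equal(max(abs(st$u_z)), 0)
  expect_equal(max(abs(st$u_r)), 0)
})
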