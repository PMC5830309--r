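# Operator-level checks of the transport discretization and the
# metric-based gradient reconstruction.

test_that("uniform field is an exact solution with zero sources", {
  fx <- make_fixture("tiny_stenosis")
  mesh <- fx$mesh
  nz <- mesh$nz; nr <- mesh$nr
  # arbitrary divergence-free-ish face fluxes: any fluxes work because the
  # flux-sum compensation keeps constants in the kernel
  set.seed(1)
  Fz <- matrix(rnorm(prod(dim(mesh$Az_zface))), nz + 1, nr) * 1e-4
  Fe <- matrix(rnorm(nz * (nr + 1)), nz, nr + 1) * 1e-4
  Fe[, 1] <- 0; Fe[, nr + 1] <- 0
  phi0 <- 7.3
  bc <- bc_spec(inlet = list(type = "dirichlet", value = phi0),
                outlet = list(type = "neumann"),
                wall = list(type = "dirichlet", value = phi0), parity = 1)
  sys <- discretize_transport(mesh, Fz, Fe, matrix(0.5, nz, nr), bc)
  resid <- sys$A %*% rep(phi0, nz * nr) - sys$b
  expect_lt(max(abs(resid)), 1e-10 * max(abs(sys$b)))
})

test_that("steady axial advection-diffusion matches a 1D upwind oracle", {
  fx <- make_fixture("straight_tube")
  mesh <- fx$mesh
  nz <- mesh$nz; nr <- mesh$nr
  rho <- 1000; u <- 0.02; Gam <- 0.5
  Fz <- matrix(0, nz + 1, nr)
  for (i in 1:(nz + 1)) Fz[i, ] <- rho * u * mesh$Az_zface[i, ]
  Fe <- matrix(0, nz, nr + 1)
  bc <- bc_spec(inlet = list(type = "dirichlet", value = 0),
                outlet = list(type = "dirichlet", value = 1),
                wall = list(type = "neumann"), parity = 1)
  sys <- discretize_transport(mesh, Fz, Fe, matrix(Gam, nz, nr), bc)
  phi <- matrix(as.numeric(Matrix::solve(sys$A, sys$b)), nz, nr)
  # uniform-in-r solution: every radial level identical
  expect_lt(max(abs(phi - phi[, 1])), 1e-9)

  # independent 1D oracle: tridiagonal first-order upwind chain with the
  # same half-cell Dirichlet closures, unit cross-section
  A1 <- mesh$Az_zface[1, 1]
  dz <- diff(mesh$z_c)[1]
  F1 <- rho * u * A1
  D1 <- Gam * A1 / dz
  Db <- Gam * A1 / (dz / 2)
  M <- matrix(0, nz, nz); b1 <- numeric(nz)
  for (i in 1:nz) {
    # west face (upwind from i-1): neighbor coefficient D + F
    if (i > 1) { M[i, i] <- M[i, i] + D1; M[i, i - 1] <- -(D1 + F1) }
    # east face (upwind from i): diagonal D + F
    if (i < nz) { M[i, i] <- M[i, i] + D1 + F1; M[i, i + 1] <- -D1 }
  }
  M[1, 1] <- M[1, 1] + Db               # inlet Dirichlet 0: inflow at phi_b
  M[nz, nz] <- M[nz, nz] + Db + F1      # outlet Dirichlet, outflow convects
  b1[nz] <- Db * 1
  # flux-sum compensation used by the assembler: net outflow is 0 here
  phi1 <- solve(M, b1)
  expect_equal(phi[, 1], phi1, tolerance = 1e-9)

  # and the upwind solution brackets the exact exponential profile
  Pe <- rho * u * mesh$geom$L_vessel / Gam
  exact <- (exp(Pe * mesh$z_c / mesh$geom$L_vessel) - 1) / (exp(Pe) - 1)
  pe_cell <- rho * u * dz / Gam
  expect_lt(max(abs(phi[, 1] - exact)), pe_cell)
})

test_that("pure transient decay follows the backward-Euler closed form", {
  fx <- make_fixture("straight_tube")
  mesh <- fx$mesh
  nz <- mesh$nz; nr <- mesh$nr
  rho <- 1050; dt <- 0.01; cc <- 37
  phi_old <- matrix(runif(nz * nr, 1, 2), nz, nr)
  bc <- bc_spec()   # all Neumann, no diffusion anyway
  sys <- discretize_transport(
    mesh, matrix(0, nz + 1, nr), matrix(0, nz, nr + 1),
    matrix(0, nz, nr), bc,
    trans_coef = rho * mesh$vol / dt, phi_old = phi_old,
    aP_extra = cc * mesh$vol)
  phi <- matrix(as.numeric(Matrix::solve(sys$A, sys$b)), nz, nr)
  expect_equal(phi, phi_old / (1 + cc * dt / rho), tolerance = 1e-12)
})

test_that("negative diffusivity is rejected", {
  fx <- make_fixture("straight_tube")
  mesh <- fx$mesh
  expect_error(
    discretize_transport(mesh, matrix(0, mesh$nz + 1, mesh$nr),
                         matrix(0, mesh$nz, mesh$nr + 1),
                         matrix(-1, mesh$nz, mesh$nr), bc_spec()),
    "negative diffusivity")
})

test_that("cell gradients converge to manufactured derivatives", {
  errs <- sapply(c(1, 2, 4), function(f) {
    fx <- make_fixture("manufactured_field", seed = 11)
    mesh <- if (f == 1) fx$mesh else refine_mesh(fx$mesh, f)
    z <- mesh$zc_cell; r <- mesh$rc_cell
    uz <- fx$fu(z, r)
    g <- cell_gradients(uz, mesh, bc_spec(wall = list(type = "dirichlet",
                                                      value = 0)))
    ex <- fx$grad_exact(z, r)
    max(abs(g$dz - ex$duz_dz) / max(abs(ex$duz_dz)),
        abs(g$dr - ex$duz_dr) / max(abs(ex$duz_dr)))
  })
  expect_lt(errs[1], 0.15)
  # second order in the interior, first order at the one-sided boundary
  # closures: the max error at least halves per refinement level
  expect_lt(errs[2], 0.6 * errs[1])
  expect_lt(errs[3], 0.6 * errs[2])
})

test_that("shear-rate invariant from discrete gradients matches analytics", {
  fx <- make_fixture("manufactured_field", seed = 5)
  mesh <- refine_mesh(fx$mesh, 2)
  z <- mesh$zc_cell; r <- mesh$rc_cell
  uz <- fx$fu(z, r); ur <- fx$fv(z, r)
  guz <- cell_gradients(uz, mesh, bc_spec(wall = list(type = "dirichlet",
                                                      value = 0)))
  gur <- cell_gradients(ur, mesh, bc_spec(wall = list(type = "dirichlet",
                                                      value = 0),
                                          parity = -1))
  gam <- shear_rate_invariant(guz$dz, guz$dr, gur$dz, gur$dr, ur, r)
  ex <- fx$grad_exact(z, r)
  hoop <- ifelse(r > 0, ur / r, ex$dur_dr)
  gam_ex <- sqrt(2 * (ex$dur_dr^2 + hoop^2 + ex$duz_dz^2) +
                   (ex$dur_dz + ex$duz_dr)^2)
  expect_lt(max(abs(gam - gam_ex)) / max(gam_ex), 0.08)
})

test_that("inlet pressure waveform follows the sinusoidal law", {
  pp <- pulsatile_pressure(Pm = 100, eps = 0.2, omega0 = 2 * pi)
  expect_equal(inlet_pressure(0, pp), 100)
  expect_equal(inlet_pressure(0.25, pp), 120)        # systolic peak
  expect_equal(inlet_pressure(0.75, pp), 80)
  expect_equal(inlet_pressure(1, pp), 100, tolerance = 1e-12)
  expect_error(pulsatile_pressure(Pm = 100, eps = 1.2), "eps")
})
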