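# Energy transport: rho cp DT/Dt = div(k grad T) + sigma B^2 u_z^2 + mu Phi
# (+ the magnetocaloric hook, identically zero for the temperature-
# independent magnetization law).

#' Viscous dissipation function
#'
#' Axisymmetric, swirl-free dissipation
#' \deqn{\Phi = 2\left[(\partial_r u_r)^2 + (u_r/r)^2 + (\partial_z u_z)^2\right]
#'   + (\partial_z u_r + \partial_r u_z)^2 - \tfrac{2}{3}(\nabla\cdot V)^2}
#' evaluated from cell-centered gradients; the result is clamped at zero
#' (the continuum expression is non-negative for incompressible flow, but
#' the discrete divergence is not exactly zero).
#'
#' @param state A `sim_state`.
#' @param mesh The mesh.
#' @return `nz x nr` matrix of Phi (1/s^2); multiply by viscosity for the
#'   volumetric heating rate W/m^3.
#' @export
viscous_dissipation <- function(state, mesh) {
  guz <- cell_gradients(state$u_z, mesh, .bc_uz())
  gur <- cell_gradients(state$u_r, mesh, .bc_ur())
  hoop <- ifelse(mesh$rc_cell > 0, state$u_r / mesh$rc_cell, gur$dr)
  div <- guz$dz + gur$dr + hoop
  phi <- 2 * (gur$dr^2 + hoop^2 + guz$dz^2) +
    (gur$dz + guz$dr)^2 - (2 / 3) * div^2
  pmax(phi, 0)
}

# wall Dirichlet mask for the cooled distal-stenosis patch
cooled_wall_mask <- function(mesh) {
  g <- mesh$geom
  mesh$z_c > g$d + g$L0 / 2 & mesh$z_c <= g$d + g$L0
}

#' Advance the temperature field
#'
#' Solves the energy equation for the temperature at the current velocity
#' level: upwind convection by the stored (continuity-satisfying) face
#' fluxes, conduction, Joule heating `sigma B^2 u_z^2`, viscous dissipation
#' `mu Phi`, and the magnetocaloric hook.  Thermal boundary conditions:
#' Dirichlet `cfg$T_inlet` at the inlet, zero-gradient outlet and axis
#' symmetry; the wall is adiabatic unless `cfg$cooled_wall` holds the
#' distal stenosis half at `cfg$T_wall`.
#'
#' @param state A `sim_state` with converged velocity/flux fields.
#' @param mesh,props,mag,cfg Simulation setup objects.
#' @param dt Time step, s, or `NULL` for the steady energy balance.
#' @param state_old Previous time level (required with `dt`).
#' @return The state with an updated temperature field.
#' @export
solve_energy <- function(state, mesh, props, mag, cfg,
                         dt = NULL, state_old = NULL) {
  nz <- mesh$nz; nr <- mesh$nr
  wall_bc <- if (isTRUE(cfg$cooled_wall))
    list(type = "mixed", value = cfg$T_wall, mask = cooled_wall_mask(mesh))
  else list(type = "neumann")
  bc_T <- bc_spec(inlet = list(type = "dirichlet", value = cfg$T_inlet),
                  outlet = list(type = "neumann"),
                  wall = wall_bc, parity = 1)

  Bc <- field_envelope(mesh$z_c, mag)
  joule <- sweep(state$u_z^2, 1, props$sigma * Bc^2, "*")
  phi <- viscous_dissipation(state, mesh)
  Hc <- Bc / mag$mu0_mag
  src <- (joule + state$mu * phi +
            magnetocaloric_source(state$T, 0 * Hc, mag)) * mesh$vol

  trans <- if (!is.null(dt)) {
    if (is.null(state_old)) stop("state_old is required for a transient step")
    props$rho * props$cp * mesh$vol / dt
  } else NULL

  gT <- cell_gradients(state$T, mesh, bc_T)
  sys <- discretize_transport(
    mesh, props$cp * state$Fz, props$cp * state$Fe,
    matrix(props$k, nz, nr), bc_T, grad = gT,
    trans_coef = trans,
    phi_old = if (!is.null(trans)) state_old$T else NULL,
    src = src)
  if (cfg$relax_T < 1) {
    rsys <- relax_system(sys, state$T, cfg$relax_T)
    state$T <- solve_field(rsys, nz, nr)
  } else {
    state$T <- solve_field(sys, nz, nr)
  }
  state
}

#' One backward-Euler time step
#'
#' Advances the coupled system by `cfg$dt`: evaluates the pulsatile inlet
#' pressure at the new time level, runs the SIMPLE loop for the implicit
#' momentum/continuity solve, then advances the energy equation.  Warns
#' (does not fail) when the advective CFL number is large, since the
#' implicit scheme remains stable but accuracy degrades.
#'
#' @inheritParams simple_iterate
#' @return The state at `t + dt`.
#' @export
advance <- function(state, mesh, props, mag, pp, cfg, quiet = FALSE) {
  dt <- cfg$dt
  dz <- diff(mesh$z_f)[1]
  cfl <- max(abs(state$u_z)) * dt / dz
  if (cfl > 20)
    warning(sprintf("advective CFL = %.1f is large; consider a smaller dt",
                    cfl))
  new <- simple_iterate(state, mesh, props, mag, pp, cfg,
                        t = state$t + dt, dt = dt, state_old = state,
                        quiet = quiet)
  solve_energy(new, mesh, props, mag, cfg, dt = dt, state_old = state)
}
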