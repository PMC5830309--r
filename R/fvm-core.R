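#' Fluid properties
#'
#' Material constants of the working fluid.  Defaults are whole blood:
#' density 1050 kg/m^3, specific heat 3490 J/(kg K), thermal conductivity
#' 0.5 W/(m K), electrical conductivity 0.8 S/m, and the Carreau
#' shear-thinning law of [carreau_params()].
#'
#' @param rho Density, kg/m^3.
#' @param cp Specific heat at constant pressure, J/(kg K).
#' @param k Thermal conductivity, W/(m K).
#' @param sigma Electrical conductivity, S/m.
#' @param carreau A [carreau_params()] viscosity law.
#' @return An object of class `fluid_props`.
#' @export
fluid_props <- function(rho = 1050, cp = 3490, k = 0.5, sigma = 0.8,
                        carreau = carreau_params()) {
  stopifnot(rho > 0, cp > 0, k > 0, sigma >= 0,
            inherits(carreau, "carreau_params"))
  structure(list(rho = rho, cp = cp, k = k, sigma = sigma,
                 carreau = carreau), class = "fluid_props")
}

#' Pulsatile driving pressure
#'
#' Sinusoidal inlet gauge pressure mimicking the cardiac cycle,
#' `P(t) = Pm (1 + eps sin(omega0 t))` with amplitude ratio
#' `eps = Ps / Pm < 1` so the driving pressure never reverses sign.
#'
#' @param Pm Mean inlet gauge pressure, Pa.
#' @param eps Amplitude ratio (0 <= eps < 1).
#' @param omega0 Angular frequency, rad/s (default `2*pi`: a 1 Hz beat).
#' @return An object of class `pulsatile_pressure`.
#' @export
pulsatile_pressure <- function(Pm, eps = 0.2, omega0 = 2 * pi) {
  stopifnot(eps >= 0, eps < 1, omega0 > 0)
  structure(list(Pm = Pm, eps = eps, omega0 = omega0),
            class = "pulsatile_pressure")
}

#' Instantaneous inlet pressure
#'
#' @param t Time, s (non-negative).
#' @param pp A [pulsatile_pressure()].
#' @return Inlet gauge pressure `Pm (1 + eps sin(omega0 t))`, Pa.
#' @examples
#' pp <- pulsatile_pressure(Pm = 100, eps = 0.2, omega0 = 2 * pi)
#' inlet_pressure(0, pp)      # 100
#' inlet_pressure(0.25, pp)   # 120, the systolic peak
#' @export
inlet_pressure <- function(t, pp) {
  stopifnot(inherits(pp, "pulsatile_pressure"), all(t >= 0))
  pp$Pm * (1 + pp$eps * sin(pp$omega0 * t))
}

#' Solver controls
#'
#' Numerical parameters of the SIMPLE/backward-Euler solver.  The defaults
#' (velocity relaxation 0.7, pressure 0.3, temperature 1.0, normalized mass
#' residual tolerance 1e-6) are the customary robust choices for collocated
#' SIMPLE.
#'
#' @param dt Time step, s.
#' @param t_end End time, s.
#' @param outer_tol Convergence tolerance on the normalized mass residual.
#' @param du_tol Additional convergence requirement on the relative
#'   velocity change per outer iteration (guards against declaring
#'   convergence while the momentum iteration is still creeping).
#' @param max_outer Cap on SIMPLE outer iterations (per step or steady run).
#' @param relax_u,relax_p,relax_T Under-relaxation factors in (0, 1].
#' @param relax_mu Relaxation of the viscosity update in (0, 1].
#' @param viscous_form `"full"` solves the divergence of the complete
#'   variable-viscosity stress; `"laplacian"` restores the constant-mu
#'   `mu * laplacian(V)` form for comparison.
#' @param T_inlet Inlet blood temperature, K (default 310; the literal
#'   300 K variant is available by configuration).
#' @param cooled_wall Logical: hold the distal-stenosis-half wall patch at
#'   `T_wall` (otherwise the whole wall is adiabatic).
#' @param T_wall Cooled-patch wall temperature, K (defaults to `T_inlet`).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = 0.01, t_end = 1, outer_tol = 1e-6,
                          du_tol = 1e-6, max_outer = 200L,
                          relax_u = 0.7, relax_p = 0.3, relax_T = 1.0,
                          relax_mu = 0.7,
                          viscous_form = c("full", "laplacian"),
                          T_inlet = 310, cooled_wall = FALSE,
                          T_wall = T_inlet) {
  viscous_form <- match.arg(viscous_form)
  stopifnot(dt > 0, t_end > 0, outer_tol > 0, du_tol > 0, max_outer >= 1,
            relax_u > 0, relax_u <= 1, relax_p > 0, relax_p <= 1,
            relax_T > 0, relax_T <= 1, relax_mu > 0, relax_mu <= 1,
            T_inlet > 0)
  structure(list(dt = dt, t_end = t_end, outer_tol = outer_tol,
                 du_tol = du_tol, max_outer = as.integer(max_outer),
                 relax_u = relax_u, relax_p = relax_p, relax_T = relax_T,
                 relax_mu = relax_mu, viscous_form = viscous_form,
                 T_inlet = T_inlet, cooled_wall = cooled_wall,
                 T_wall = T_wall),
            class = "solver_config")
}

#' Initialize a simulation state
#'
#' By default the state is warm-started from lubrication theory: a
#' quasi-Poiseuille axial profile whose flow rate balances the
#' instantaneous driving pressure against the series resistance
#' `(8 mu / pi) * integral(dz / R(z)^4)`, the corresponding nonlinear
#' pressure distribution along the vessel, and the Carreau viscosity at
#' the local shear estimate.  This places the slowly converging global
#' flow mode close to its solution before SIMPLE starts.  With
#' `warm_start = FALSE` the state is quiescent (zero velocity, linear
#' pressure ramp).
#'
#' @param mesh An [build_mesh()] mesh.
#' @param props A [fluid_props()].
#' @param pp A [pulsatile_pressure()] (evaluated at `t0`).
#' @param cfg A [solver_config()].
#' @param t0 Initial time, s.
#' @param warm_start Use the lubrication-theory initial guess.
#' @return An object of class `sim_state` with fields `u_z`, `u_r`, `p`,
#'   `T`, `mu` (nz x nr matrices), face mass fluxes `Fz`, `Fe`, and time
#'   `t`.
#' @export
init_state <- function(mesh, props, pp, cfg, t0 = 0, warm_start = TRUE) {
  nz <- mesh$nz; nr <- mesh$nr
  p_in <- inlet_pressure(t0, pp)
  u_z <- matrix(0, nz, nr)
  mu <- matrix(carreau_viscosity(0, props$carreau), nz, nr)
  p <- matrix(p_in * (1 - mesh$z_c / mesh$geom$L_vessel), nz, nr)
  if (warm_start && p_in > 0) {
    dz <- diff(mesh$z_f)
    # series lumen resistance per unit (8 mu / pi); iterate the effective
    # viscosity through the Carreau law at the wall-shear estimate
    mu_eff <- props$carreau$mu1
    for (k in 1:4) {
      Lam <- (8 * mu_eff / pi) * sum(dz / mesh$Rc^4)
      Q <- p_in / Lam
      gam_w <- 4 * Q / (pi * min(mesh$Rc)^3)
      mu_eff <- carreau_viscosity(gam_w, props$carreau)
    }
    u_z <- outer(2 * Q / (pi * mesh$Rc^2), 1 - mesh$eta_c^2)
    gam <- outer(4 * Q / (pi * mesh$Rc^3), mesh$eta_c)
    mu <- carreau_viscosity(gam, props$carreau)
    cum <- cumsum(dz / mesh$Rc^4) - 0.5 * dz / mesh$Rc^4
    p <- matrix(p_in * (1 - cum / sum(dz / mesh$Rc^4)), nz, nr)
  }
  structure(list(
    u_z = u_z, u_r = matrix(0, nz, nr),
    p = p, T = matrix(cfg$T_inlet, nz, nr),
    mu = mu,
    Fz = matrix(0, nz + 1, nr), Fe = matrix(0, nz, nr + 1),
    t = t0), class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf(
    "sim_state at t = %.4g s: max |u_z| = %.4g m/s, p in [%.4g, %.4g] Pa, T in [%.4g, %.4g] K\n",
    x$t, max(abs(x$u_z)), min(x$p), max(x$p), min(x$T), max(x$T)))
  invisible(x)
}
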