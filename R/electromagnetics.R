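#' Applied magnetic field configuration
#'
#' Describes a transverse magnetic field of induction `B0` applied over an
#' axial window `[z_on, z_off]` with C1-smooth cosine ramps of length
#' `ramp_len` at both edges.  Under the low-magnetic-Reynolds, azimuthally
#' averaged axisymmetric reduction used throughout this package, the field
#' enters the momentum equation as the damping body force
#' `-sigma B(z)^2 u_z` and the energy equation as the Joule source
#' `sigma B(z)^2 u_z^2`.
#'
#' Exactly one of `B0` (Tesla) or `Ha` (Hartmann number) must be supplied;
#' the other is derived through `Ha = B0 R0 sqrt(sigma / mu_ref)` where
#' `mu_ref` is the high-shear viscosity plateau governing the near-wall
#' layers.
#'
#' @param B0 Applied induction magnitude, T (mutually exclusive with `Ha`).
#' @param Ha Hartmann number (mutually exclusive with `B0`).
#' @param z_on,z_off Axial extent of the magnetized region, m.
#' @param ramp_len Smoothing length of the field envelope edges, m.
#' @param sigma Electrical conductivity of blood, S/m (default 0.8).
#' @param chi Magnetic susceptibility for the linear magnetization law
#'   M = chi H.  Defaults to 0: at the tesla-scale inductions implied by
#'   Hartmann numbers of order one in blood, even a weak-paramagnetic
#'   susceptibility makes the Kelvin force on the field-entry ramp dwarf
#'   the physiological driving pressure, which is not the damping-dominated
#'   regime this model targets; supply a positive chi to switch the force
#'   on.
#' @param mu0_mag Vacuum permeability, T m/A.
#' @param R0 Reference length for the Hartmann number, m.
#' @param mu_ref Reference viscosity for the Hartmann number, Pa s.
#' @return An object of class `magnetic_config` with both `B0` and `Ha`
#'   populated consistently.
#' @export
magnetic_config <- function(B0 = NULL, Ha = NULL, z_on, z_off,
                            ramp_len = 0.1 * (z_off - z_on),
                            sigma = 0.8, chi = 0,
                            mu0_mag = 4e-7 * pi,
                            R0 = 0.01, mu_ref = 0.036) {
  if (is.null(B0) == is.null(Ha))
    stop("exactly one of B0 or Ha must be given")
  stopifnot(z_on < z_off, sigma >= 0, ramp_len >= 0,
            R0 > 0, mu_ref > 0)
  if (is.null(B0)) {
    stopifnot(Ha >= 0)
    B0 <- if (sigma > 0) Ha / (R0 * sqrt(sigma / mu_ref)) else 0
  } else {
    stopifnot(B0 >= 0)
    Ha <- hartmann_number(B0, R0, sigma, mu_ref)
  }
  structure(list(B0 = B0, Ha = Ha, z_on = z_on, z_off = z_off,
                 ramp_len = ramp_len, sigma = sigma, chi = chi,
                 mu0_mag = mu0_mag, R0 = R0, mu_ref = mu_ref),
            class = "magnetic_config")
}

#' @export
print.magnetic_config <- function(x, ...) {
  cat(sprintf(
    "magnetic_config: B0 = %.4g T (Ha = %.4g), region [%g, %g] m, ramp %g m, sigma = %g S/m\n",
    x$B0, x$Ha, x$z_on, x$z_off, x$ramp_len, x$sigma))
  invisible(x)
}

#' Hartmann number
#'
#' Ratio of electromagnetic to viscous body forces,
#' `Ha = B0 R0 sqrt(sigma / mu_ref)`.
#'
#' @param B0 Applied induction, T (non-negative).
#' @param R0 Reference length (vessel radius), m.
#' @param sigma Electrical conductivity, S/m.
#' @param mu_ref Reference dynamic viscosity, Pa s; must be positive.
#' @return Dimensionless Hartmann number.
#' @export
hartmann_number <- function(B0, R0, sigma, mu_ref) {
  if (mu_ref <= 0) stop("reference viscosity must be positive")
  stopifnot(B0 >= 0, R0 > 0, sigma >= 0)
  B0 * R0 * sqrt(sigma / mu_ref)
}

#' Local magnetic-field envelope
#'
#' Axial profile of the applied induction: zero outside
#' `[z_on - ramp_len, z_off + ramp_len]`, the plateau `B0` well inside, and
#' C1-smooth half-cosine ramps across the edges (value `B0/2` at the ramp
#' midpoints `z_on - ramp_len/2` and `z_off + ramp_len/2`).
#'
#' @param z Axial position(s), m.
#' @param cfg A [magnetic_config()].
#' @return Induction magnitude(s), T.
#' @export
field_envelope <- function(z, cfg) {
  stopifnot(inherits(cfg, "magnetic_config"))
  B0 <- cfg$B0; rl <- cfg$ramp_len
  b <- numeric(length(z))
  if (B0 == 0) return(b)
  if (rl == 0) {
    b[z >= cfg$z_on & z <= cfg$z_off] <- B0
    return(b)
  }
  plateau <- z >= cfg$z_on & z <= cfg$z_off
  up <- z > cfg$z_on - rl & z < cfg$z_on
  dn <- z > cfg$z_off & z < cfg$z_off + rl
  b[plateau] <- B0
  b[up] <- 0.5 * B0 * (1 + cos(pi * (cfg$z_on - z[up]) / rl))
  b[dn] <- 0.5 * B0 * (1 + cos(pi * (z[dn] - cfg$z_off) / rl))
  b
}

#' Axial derivative of the field envelope
#'
#' Analytic dB/dz of [field_envelope()]; nonzero only on the ramps.
#'
#' @inheritParams field_envelope
#' @return dB/dz, T/m.
#' @export
field_envelope_deriv <- function(z, cfg) {
  stopifnot(inherits(cfg, "magnetic_config"))
  B0 <- cfg$B0; rl <- cfg$ramp_len
  db <- numeric(length(z))
  if (B0 == 0 || rl == 0) return(db)
  up <- z > cfg$z_on - rl & z < cfg$z_on
  dn <- z > cfg$z_off & z < cfg$z_off + rl
  db[up] <- 0.5 * B0 * (pi / rl) * sin(pi * (cfg$z_on - z[up]) / rl)
  db[dn] <- -0.5 * B0 * (pi / rl) * sin(pi * (z[dn] - cfg$z_off) / rl)
  db
}

#' Axial Lorentz (MHD damping) body force
#'
#' Azimuthally averaged axisymmetric reduction of `J x B` with
#' `J = sigma (V x B)` for a transverse field: the force opposes the axial
#' motion, `f_z = -sigma B^2 u_z` (N/m^3).
#'
#' @param u_z Axial velocity, m/s.
#' @param B_local Local induction, T.
#' @param sigma Electrical conductivity, S/m.
#' @return Axial body force, N/m^3 (sign opposite to `u_z`).
#' @export
lorentz_force_axial <- function(u_z, B_local, sigma) {
  -sigma * B_local^2 * u_z
}

#' Joule heating source
#'
#' Volumetric dissipation `J . J / sigma = sigma B^2 u_z^2` (W/m^3) of the
#' induced currents; always non-negative, and exactly the negative of the
#' mechanical power `u_z f_z` extracted by [lorentz_force_axial()].
#'
#' @inheritParams lorentz_force_axial
#' @return Volumetric heat source, W/m^3.
#' @export
joule_heating <- function(u_z, B_local, sigma) {
  sigma * B_local^2 * u_z^2
}

#' Magnetization (Kelvin) body force
#'
#' Ferrohydrodynamic force `mu0 M grad(H)` with the linear, temperature-
#' independent law `M = chi H`: `f = mu0_mag chi H dH/dz` along the axis.
#' Vanishes wherever the field is uniform or `chi = 0`.
#'
#' @param H_local Magnetic field intensity, A/m.
#' @param grad_H Axial gradient of `H`, A/m^2.
#' @param cfg A [magnetic_config()].
#' @return Axial body force, N/m^3.
#' @export
magnetization_force <- function(H_local, grad_H, cfg) {
  stopifnot(inherits(cfg, "magnetic_config"))
  cfg$mu0_mag * cfg$chi * H_local * grad_H
}

#' Magnetocaloric energy-equation hook
#'
#' The energy equation formally carries the term
#' `mu0 T (dM/dT) DH/Dt`; with the linear magnetization law used here,
#' `M = chi H` independent of temperature, `dM/dT = 0` and the term is
#' identically zero.  The hook is kept so a temperature-dependent law can be
#' plugged in without touching the solver.
#'
#' @param T_field Temperature, K.
#' @param DH_Dt Material derivative of `H`, A/(m s).
#' @param cfg A [magnetic_config()].
#' @return Volumetric source, W/m^3 (zero for the default law).
#' @export
magnetocaloric_source <- function(T_field, DH_Dt, cfg) {
  0 * T_field
}
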