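# Closed-form validation oracles and post-processing diagnostics.

#' Poiseuille pipe-flow profile
#'
#' Steady fully developed laminar profile `u(r) = G (R^2 - r^2) / (4 mu)`
#' driven by a constant pressure gradient `G = -dp/dz`; flow rate
#' `Q = pi G R^4 / (8 mu)`.
#'
#' @param r Radial position(s), m, in `[0, R]`.
#' @param G Driving pressure gradient, Pa/m.
#' @param mu Dynamic viscosity, Pa s.
#' @param R Pipe radius, m.
#' @return Axial velocity, m/s.
#' @export
analytic_poiseuille <- function(r, G, mu, R) {
  G * (R^2 - r^2) / (4 * mu)
}

#' Hartmann-damped pipe-flow profile
#'
#' Exact steady solution of the axisymmetric momentum equation with the
#' azimuthally averaged MHD damping force `-sigma B^2 u`:
#' \deqn{u(r) = \frac{G R^2}{\mu Ha^2}
#'   \left[1 - \frac{I_0(Ha\, r/R)}{I_0(Ha)}\right]}
#' with `I_0` the modified Bessel function and
#' `Ha = B R sqrt(sigma/mu)`.  For `Ha = 0` it reduces to
#' [analytic_poiseuille()].
#'
#' @inheritParams analytic_poiseuille
#' @param Ha Hartmann number (>= 0).
#' @return Axial velocity, m/s.
#' @export
analytic_mhd_pipe_profile <- function(r, G, mu, R, Ha) {
  stopifnot(Ha >= 0)
  if (Ha == 0) return(analytic_poiseuille(r, G, mu, R))
  (G * R^2 / (mu * Ha^2)) *
    (1 - besselI(Ha * r / R, 0) / besselI(Ha, 0))
}

#' Wall shear stress profile
#'
#' Tangential viscous traction on the stenosed wall,
#' `tau_w = mu_w du_t/dn`, from the one-sided gradient between the
#' wall-adjacent cell and the no-slip wall along the local wall normal.
#' The wall viscosity is the Carreau value at the one-sided shear rate.
#'
#' @param state A converged `sim_state`.
#' @param mesh The mesh.
#' @param carreau A [carreau_params()] for the wall viscosity (defaults to
#'   the viscosity field stored in the state at the wall cells).
#' @return A data frame of class `wall_profile` with columns `z` (axial
#'   face position, m), `s` (arc length along the wall, m), `tau_w` (Pa)
#'   and `p_wall` (Pa).
#' @export
wall_shear_stress <- function(state, mesh, carreau = NULL) {
  nr <- mesh$nr
  tvec <- mesh$wall_tangent
  u1 <- state$u_z[, nr] * tvec[, 1] + state$u_r[, nr] * tvec[, 2]
  # two-point one-sided (quadratic) wall-normal gradient through the
  # no-slip wall and the two nearest cell rows
  d1 <- mesh$wall_dist
  d2 <- d1 * (1 - mesh$eta_c[nr - 1]) / (1 - mesh$eta_c[nr])
  u2 <- state$u_z[, nr - 1] * tvec[, 1] + state$u_r[, nr - 1] * tvec[, 2]
  dudn <- (d2^2 * u1 - d1^2 * u2) / (d1 * d2 * (d2 - d1))
  mu_w <- if (is.null(carreau)) state$mu[, nr]
  else carreau_viscosity(abs(dudn), carreau)
  # arc length along the wall
  dz <- diff(mesh$z_f)
  ds <- dz * sqrt(1 + mesh$Rpc^2)
  s <- cumsum(ds) - ds / 2
  structure(data.frame(z = mesh$z_c, s = s, tau_w = mu_w * dudn,
                       p_wall = state$p[, nr]),
            class = c("wall_profile", "data.frame"))
}

#' Volumetric flow rate through a constant-z station
#'
#' Integrates the stored face mass fluxes over the inlet (default) or any
#' z-face index, returning the physical flow rate (the per-radian fluxes
#' are multiplied by 2 pi).
#'
#' @param state A `sim_state`.
#' @param mesh The mesh.
#' @param iface z-face index in `1..nz+1` (1 = inlet).
#' @param rho Fluid density used to convert mass to volume flux.
#' @return Volumetric flow rate, m^3/s.
#' @export
flow_rate <- function(state, mesh, iface = 1, rho = 1050) {
  2 * pi * sum(state$Fz[iface, ]) / rho
}

#' Cumulative flow resistance along the vessel
#'
#' Hemodynamic resistance profile `Lambda(z) = (p_in - p(z, r_mid)) / Q`
#' sampled at a fixed midline radius, plus the total `delta p / Q` of the
#' whole vessel.  `Q` is the instantaneous inlet volumetric flow rate.
#'
#' @param state A converged `sim_state`.
#' @param mesh The mesh.
#' @param rho Fluid density, kg/m^3.
#' @param p_in Inlet gauge pressure, Pa (defaults to the pressure
#'   extrapolated to the inlet midline cell).
#' @param r_mid Midline sampling radius, m (default 2.5 mm).
#' @param q_min Smallest |Q| (m^3/s) for which resistance is defined.
#' @return A list with `profile` (data frame `z`, `Lambda`), `total`
#'   (Pa s/m^3), and `Q` (m^3/s).
#' @export
flow_resistance <- function(state, mesh, rho = 1050, p_in = NULL,
                            r_mid = 2.5e-3, q_min = 1e-15) {
  Q <- flow_rate(state, mesh, 1, rho)
  if (abs(Q) < q_min)
    stop("flow rate below threshold: resistance undefined")
  # pressure along the midline: per column, interpolate p over r to r_mid
  nz <- mesh$nz
  pmid <- vapply(seq_len(nz), function(i) {
    r <- mesh$rc_cell[i, ]
    stats::approx(r, state$p[i, ], xout = min(r_mid, max(r)), rule = 2)$y
  }, 0)
  # extrapolate the half cell to the inlet/outlet faces
  z <- mesh$z_c
  p_end <- pmid[nz] + (pmid[nz] - pmid[nz - 1]) /
    (z[nz] - z[nz - 1]) * (mesh$z_f[nz + 1] - z[nz])
  p0 <- pmid[1] + (pmid[2] - pmid[1]) / (z[2] - z[1]) * (mesh$z_f[1] - z[1])
  if (is.null(p_in)) p_in <- p0
  list(profile = data.frame(z = c(z, mesh$z_f[nz + 1]),
                            Lambda = (p_in - c(pmid, p_end)) / Q),
       total = (p_in - p_end) / Q,
       Q = Q)
}

#' Detect a post-throat recirculation zone
#'
#' Scans the cells downstream of the stenosis throat for reversed axial
#' flow (`u_z < -u_tol`), returning the axial extent and strength of the
#' largest contiguous region, or an empty descriptor when the flow is
#' attached.
#'
#' @param state A converged `sim_state`.
#' @param mesh The mesh.
#' @param u_tol Reverse-velocity threshold, m/s (a small fraction of the
#'   peak speed by default).
#' @return A list with `present` (logical), `z_start`, `z_end`, `extent`
#'   (m), `max_reverse` (most negative u_z, m/s) and `n_cells`.
#' @export
detect_recirculation <- function(state, mesh, u_tol = NULL) {
  if (is.null(u_tol)) u_tol <- 1e-6 * max(abs(state$u_z), 1e-300)
  g <- mesh$geom
  z_throat <- g$d + g$L0 / 2
  post <- mesh$z_c > z_throat
  rev_col <- apply(state$u_z < -u_tol, 1, any) & post
  if (!any(rev_col))
    return(list(present = FALSE, z_start = NA_real_, z_end = NA_real_,
                extent = 0, max_reverse = 0, n_cells = 0L))
  # largest contiguous run of columns with reversed flow
  r <- rle(rev_col)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i0 <- starts[best]; i1 <- ends[best]
  sel <- state$u_z[i0:i1, , drop = FALSE]
  list(present = TRUE,
       z_start = mesh$z_f[i0], z_end = mesh$z_f[i1 + 1],
       extent = mesh$z_f[i1 + 1] - mesh$z_f[i0],
       max_reverse = min(sel),
       n_cells = sum(sel < -u_tol))
}

#' Radial probe trace at an axial station
#'
#' @param state A `sim_state`.
#' @param mesh The mesh.
#' @param z_station Axial position, m.
#' @return Data frame with `t`, `z_station`, `r` (strictly increasing from
#'   the axis to the wall), `u_z` and `T`.
#' @export
extract_probe <- function(state, mesh, z_station) {
  i <- which.min(abs(mesh$z_c - z_station))
  data.frame(t = state$t, z_station = z_station,
             r = mesh$rc_cell[i, ], u_z = state$u_z[i, ], T = state$T[i, ])
}

#' Grid-convergence study for the peak wall shear stress
#'
#' Solves the same steady scenario on a sequence of nested meshes (cell
#' counts doubling per level) and reports the relative difference of the
#' maximum wall shear stress against the finest level, the classical
#' mesh-independence protocol.  The error sequence should decrease
#' monotonically, and its decay rate estimates the observed spatial order.
#'
#' @param geom A [stenosis_geometry()].
#' @param props,mag,pp,cfg Simulation setup objects.
#' @param nz0,nr0 Coarsest-level cell counts.
#' @param levels Number of nested levels (>= 3).
#' @return A data frame with `level`, `nz`, `nr`, `tau_max` and `rel_err`
#'   (relative to the finest level; 0 at the finest by construction), with
#'   attribute `"observed_order"` from the last three levels.
#' @export
grid_convergence_study <- function(geom, props, mag, pp, cfg,
                                   nz0 = 24, nr0 = 8, levels = 3) {
  if (levels < 3) stop("need at least 3 levels")
  tau_max <- numeric(levels)
  nzv <- nz0 * 2^(0:(levels - 1)); nrv <- nr0 * 2^(0:(levels - 1))
  for (l in seq_len(levels)) {
    mesh <- build_mesh(geom, nzv[l], nrv[l])
    st <- solve_steady(mesh, props, mag, pp, cfg, quiet = TRUE)
    if (!isTRUE(attr(st, "converged")))
      stop("level ", l, " did not converge")
    tau_max[l] <- max(abs(wall_shear_stress(st, mesh)$tau_w))
  }
  rel_err <- abs(tau_max - tau_max[levels]) / tau_max[levels]
  # observed order from the three finest levels (Richardson)
  e <- abs(diff(tau_max[(levels - 2):levels]))
  order_obs <- if (all(e > 0)) log2(e[1] / e[2]) else NA_real_
  out <- data.frame(level = seq_len(levels), nz = nzv, nr = nrv,
                    tau_max = tau_max, rel_err = rel_err)
  attr(out, "observed_order") <- order_obs
  out
}

#' Global mechanical-energy audit
#'
#' At steady state the pressure power delivered to the vessel balances the
#' dissipation channels:
#' `(p_in - p_out) Q = integral(mu Phi) dV + integral(sigma B^2 u_z^2) dV
#'  + net kinetic-energy outflow`.
#' All terms are returned per unit radian (the common factor cancels in the
#' relative closure).
#'
#' @param state A converged `sim_state`.
#' @param mesh The mesh.
#' @param props A [fluid_props()].
#' @param mag A [magnetic_config()].
#' @param p_in Inlet gauge pressure, Pa (outlet gauge is 0).
#' @return List with `pressure_power`, `viscous`, `joule`, `ke_net` (W/rad)
#'   and `closure_rel`, the relative imbalance
#'   `|power - viscous - joule - ke_net| / power`.
#' @export
mechanical_energy_audit <- function(state, mesh, props, mag, p_in) {
  rho <- props$rho
  Qin <- sum(state$Fz[1, ]) / rho          # volumetric, per radian
  power <- p_in * Qin
  phi <- viscous_dissipation(state, mesh)
  viscous <- sum(state$mu * phi * mesh$vol)
  Bc <- field_envelope(mesh$z_c, mag)
  joule <- sum(sweep(state$u_z^2, 1, props$sigma * Bc^2, "*") * mesh$vol)
  nz <- mesh$nz
  ke_out <- sum(state$Fz[nz + 1, ] * 0.5 *
                  (state$u_z[nz, ]^2 + state$u_r[nz, ]^2))
  ke_in <- sum(state$Fz[1, ] * 0.5 * (state$u_z[1, ]^2 + state$u_r[1, ]^2))
  ke_net <- ke_out - ke_in
  list(pressure_power = power, viscous = viscous, joule = joule,
       ke_net = ke_net,
       closure_rel = abs(power - viscous - joule - ke_net) /
         max(abs(power), 1e-300))
}

#' Global thermal-energy audit
#'
#' At a converged steady state the enthalpy carried out of the vessel minus
#' the enthalpy carried in, plus the heat removed through the cooled wall
#' patch, must equal the volumetric heat sources (Joule + viscous
#' dissipation).  Terms per unit radian.
#'
#' @inheritParams mechanical_energy_audit
#' @param cfg The [solver_config()] used for the energy solve (supplies the
#'   inlet temperature and cooled-wall settings).
#' @return List with `enthalpy_net`, `wall_cooling`, `joule`, `viscous`
#'   (W/rad) and `closure_rel` relative to the total source.
#' @export
thermal_energy_audit <- function(state, mesh, props, mag, cfg) {
  nz <- mesh$nz; nr <- mesh$nr
  cp <- props$cp
  # upwind enthalpy fluxes at the pressure boundaries (matching assembly)
  h_in <- sum(cp * (pmax(state$Fz[1, ], 0) * cfg$T_inlet -
                      pmax(-state$Fz[1, ], 0) * state$T[1, ]))
  h_out <- sum(cp * (pmax(state$Fz[nz + 1, ], 0) * state$T[nz, ] -
                       pmax(-state$Fz[nz + 1, ], 0) * state$T[nz, ]))
  # conductive wall extraction on the cooled patch (one-sided, as assembled)
  cooling <- 0
  if (isTRUE(cfg$cooled_wall)) {
    mask <- cooled_wall_mask(mesh)
    Dw <- props$k * mesh$gdiff_eta[, nr + 1]
    cooling <- sum((Dw * (state$T[, nr] - cfg$T_wall))[mask])
  }
  Bc <- field_envelope(mesh$z_c, mag)
  joule <- sum(sweep(state$u_z^2, 1, props$sigma * Bc^2, "*") * mesh$vol)
  viscous <- sum(state$mu * viscous_dissipation(state, mesh) * mesh$vol)
  src <- joule + viscous
  list(enthalpy_net = h_out - h_in, wall_cooling = cooling,
       joule = joule, viscous = viscous,
       closure_rel = abs(h_out - h_in + cooling - src) /
         max(abs(src), abs(h_out - h_in), 1e-300))
}
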