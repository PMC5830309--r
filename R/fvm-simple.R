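# SIMPLE pressure-velocity coupling on the collocated grid.
#
# Face mass fluxes are built by momentum-weighted (Rhie-Chow) interpolation
# to suppress checkerboard pressure modes; the pressure-correction Poisson
# equation then restores discrete continuity cell by cell.  The inlet and
# outlet are pressure boundaries (inlet gauge from the pulsatile waveform,
# outlet gauge 0), which drive the flow.

.bc_uz <- function() bc_spec(inlet = list(type = "neumann"),
                             outlet = list(type = "neumann"),
                             wall = list(type = "dirichlet", value = 0),
                             parity = 1)
.bc_ur <- function() bc_spec(inlet = list(type = "dirichlet", value = 0),
                             outlet = list(type = "neumann"),
                             wall = list(type = "dirichlet", value = 0),
                             parity = -1)
.bc_p <- function(p_in, p_out = 0)
  bc_spec(inlet = list(type = "dirichlet", value = p_in),
          outlet = list(type = "dirichlet", value = p_out),
          wall = list(type = "neumann"), parity = 1)

# Rhie-Chow face mass fluxes; Dc = vol / a_P from the momentum solve.
# With a transient term, the Choi correction carries the previous level's
# face-minus-interpolated flux difference, scaled by the transient fraction
# of the momentum diagonal; without it the pressure-velocity coupling (and
# the converged step itself) degrades as dt shrinks.
face_fluxes <- function(mesh, uz, ur, p, gp, Dc, rho, p_in, p_out = 0,
                        trans = NULL, state_old = NULL,
                        alpha_u = 1, prev = NULL) {
  nz <- mesh$nz; nr <- mesh$nr
  idx <- function(i, j) i + (j - 1L) * nz
  Fz <- matrix(0, nz + 1, nr)
  Fe <- matrix(0, nz, nr + 1)
  Dzf <- zface_interp(Dc)
  gam_z <- gam_e <- NULL
  if (!is.null(trans) && !is.null(state_old)) {
    gam <- trans * Dc / mesh$vol     # rho/dt * vol/aP, dimensionless
    gam_z <- zface_interp(gam)
    gam_e <- etaface_interp(gam)
  }

  ## interior constant-z faces
  ii <- rep(2:nz, times = nr); jj <- rep(1:nr, each = nz - 1)
  fz <- cbind(ii, jj)
  P <- idx(ii - 1L, jj); Nn <- idx(ii, jj)
  ubar <- 0.5 * (uz[P] + uz[Nn])
  dzv <- mesh$z_c[ii] - mesh$z_c[ii - 1]
  drv <- mesh$eta_c[jj] * (mesh$Rc[ii] - mesh$Rc[ii - 1])
  gpz <- 0.5 * (gp$dz[P] + gp$dz[Nn])
  gpr <- 0.5 * (gp$dr[P] + gp$dr[Nn])
  corr <- mesh$gdiff_z[fz] * ((p[Nn] - p[P]) - (gpz * dzv + gpr * drv))
  Fz[fz] <- rho * (ubar * mesh$Az_zface[fz] - Dzf[fz] * corr)
  if (!is.null(gam_z)) {
    ubar_o <- 0.5 * (state_old$u_z[P] + state_old$u_z[Nn])
    Fz[fz] <- Fz[fz] + gam_z[fz] *
      (state_old$Fz[fz] - rho * ubar_o * mesh$Az_zface[fz])
  }
  if (!is.null(prev) && alpha_u < 1) {
    # Majumdar correction: removes the under-relaxation dependence of the
    # converged face fluxes
    ubar_k <- 0.5 * (prev$u_z[P] + prev$u_z[Nn])
    Fz[fz] <- Fz[fz] + (1 - alpha_u) *
      (prev$Fz[fz] - rho * ubar_k * mesh$Az_zface[fz])
  }

  ## interior constant-eta faces
  ii <- rep(1:nz, times = nr - 1); jj <- rep(2:nr, each = nz)
  fe <- cbind(ii, jj)
  P <- idx(ii, jj - 1L); Nn <- idx(ii, jj)
  Def <- etaface_interp(Dc)
  uzb <- 0.5 * (uz[P] + uz[Nn]); urb <- 0.5 * (ur[P] + ur[Nn])
  drv <- (mesh$eta_c[jj] - mesh$eta_c[jj - 1]) * mesh$Rc[ii]
  gpr <- 0.5 * (gp$dr[P] + gp$dr[Nn])
  corr <- mesh$gdiff_eta[fe] * ((p[Nn] - p[P]) - gpr * drv)
  Fe[fe] <- rho * (uzb * mesh$Az_eta[fe] + urb * mesh$Ar_eta[fe] -
                     Def[fe] * corr)
  if (!is.null(gam_e)) {
    uzb_o <- 0.5 * (state_old$u_z[P] + state_old$u_z[Nn])
    urb_o <- 0.5 * (state_old$u_r[P] + state_old$u_r[Nn])
    Fe[fe] <- Fe[fe] + gam_e[fe] *
      (state_old$Fe[fe] - rho * (uzb_o * mesh$Az_eta[fe] +
                                   urb_o * mesh$Ar_eta[fe]))
  }
  if (!is.null(prev) && alpha_u < 1) {
    uzb_k <- 0.5 * (prev$u_z[P] + prev$u_z[Nn])
    urb_k <- 0.5 * (prev$u_r[P] + prev$u_r[Nn])
    Fe[fe] <- Fe[fe] + (1 - alpha_u) *
      (prev$Fe[fe] - rho * (uzb_k * mesh$Az_eta[fe] +
                              urb_k * mesh$Ar_eta[fe]))
  }

  ## inlet / outlet pressure boundaries
  pf <- p[1, ] + gp$dz[1, ] * (mesh$z_f[1] - mesh$z_c[1]) +
    gp$dr[1, ] * mesh$eta_c * (mesh$Rf[1] - mesh$Rc[1])
  Fz[1, ] <- rho * (uz[1, ] * mesh$Az_zface[1, ] +
                      Dc[1, ] * mesh$gdiff_z[1, ] * (p_in - pf))
  pf <- p[nz, ] + gp$dz[nz, ] * (mesh$z_f[nz + 1] - mesh$z_c[nz]) +
    gp$dr[nz, ] * mesh$eta_c * (mesh$Rf[nz + 1] - mesh$Rc[nz])
  Fz[nz + 1, ] <- rho * (uz[nz, ] * mesh$Az_zface[nz + 1, ] +
                           Dc[nz, ] * mesh$gdiff_z[nz + 1, ] * (pf - p_out))
  ## wall and axis faces carry no mass flux (already zero)
  list(Fz = Fz, Fe = Fe)
}

# net outflow per cell
cell_imbalance <- function(mesh, Fz, Fe) {
  nz <- mesh$nz; nr <- mesh$nr
  (Fz[2:(nz + 1), , drop = FALSE] - Fz[1:nz, , drop = FALSE]) +
    (Fe[, 2:(nr + 1), drop = FALSE] - Fe[, 1:nr, drop = FALSE])
}

# pressure-correction solve + corrections; returns updated p, u, fluxes
pressure_correction <- function(mesh, state, Fz, Fe, Dc, rho, relax_p) {
  nz <- mesh$nz; nr <- mesh$nr; N <- nz * nr
  idx <- function(i, j) i + (j - 1L) * nz

  Ti <- list(); Tj <- list(); Tx <- list(); ng <- 0L
  push <- function(I, J, X) {
    ng <<- ng + 1L
    Ti[[ng]] <<- I; Tj[[ng]] <<- J; Tx[[ng]] <<- X
  }

  Dzf <- zface_interp(Dc); Def <- etaface_interp(Dc)
  ## interior z faces
  ii <- rep(2:nz, times = nr); jj <- rep(1:nr, each = nz - 1)
  fz <- cbind(ii, jj)
  P <- idx(ii - 1L, jj); Nn <- idx(ii, jj)
  cz <- rho * Dzf[fz] * mesh$gdiff_z[fz]
  push(c(P, P, Nn, Nn), c(P, Nn, Nn, P), c(cz, -cz, cz, -cz))
  ## interior eta faces
  ii <- rep(1:nz, times = nr - 1); jj <- rep(2:nr, each = nz)
  fe <- cbind(ii, jj)
  Pe <- idx(ii, jj - 1L); Ne <- idx(ii, jj)
  ce <- rho * Def[fe] * mesh$gdiff_eta[fe]
  push(c(Pe, Pe, Ne, Ne), c(Pe, Ne, Ne, Pe), c(ce, -ce, ce, -ce))
  ## pressure boundaries: p' = 0 at inlet and outlet faces
  cin <- rho * Dc[1, ] * mesh$gdiff_z[1, ]
  cout <- rho * Dc[nz, ] * mesh$gdiff_z[nz + 1, ]
  push(idx(1L, 1:nr), idx(1L, 1:nr), cin)
  push(idx(nz, 1:nr), idx(nz, 1:nr), cout)

  A <- Matrix::sparseMatrix(i = unlist(Ti[1:ng]), j = unlist(Tj[1:ng]),
                            x = unlist(Tx[1:ng]), dims = c(N, N))
  b <- -as.vector(cell_imbalance(mesh, Fz, Fe))
  pc <- matrix(as.numeric(Matrix::solve(A, b)), nz, nr)
  if (!all(is.finite(pc))) stop("pressure correction solve failed")

  ## correct face fluxes (restores discrete continuity exactly)
  Fz[fz] <- Fz[fz] - cz * (pc[Nn] - pc[P])
  Fe[fe] <- Fe[fe] - ce * (pc[Ne] - pc[Pe])
  Fz[1, ] <- Fz[1, ] - cin * pc[1, ]
  Fz[nz + 1, ] <- Fz[nz + 1, ] + cout * pc[nz, ]

  ## correct cell velocities and pressure
  gpc <- cell_gradients(pc, mesh, .bc_p(0, 0))
  state$u_z <- state$u_z - Dc * gpc$dz
  state$u_r <- state$u_r - Dc * gpc$dr
  state$p <- state$p + relax_p * pc
  state$Fz <- Fz; state$Fe <- Fe
  state
}

#' One SIMPLE solve to convergence
#'
#' Runs the SIMPLE outer loop (momentum predictor with the current Carreau
#' viscosity and magnetic sources, Rhie-Chow face fluxes, pressure
#' correction, viscosity update) until the normalized mass residual falls
#' below `cfg$outer_tol` or `cfg$max_outer` iterations are reached.  With
#' `dt = NULL` the transient term is dropped and the call iterates towards
#' the steady solution at frozen boundary pressure; with a time step it
#' performs the implicit solve of one backward-Euler level against
#' `state_old`.
#'
#' @param state Current [init_state()] state (initial iterate).
#' @param mesh An [build_mesh()] mesh.
#' @param props A [fluid_props()].
#' @param mag A [magnetic_config()] (use `B0 = 0` for non-magnetic runs).
#' @param pp A [pulsatile_pressure()] supplying the inlet gauge pressure.
#' @param cfg A [solver_config()].
#' @param t Time at which the inlet pressure is evaluated, s.
#' @param dt Time step, s, or `NULL` for a steady solve.
#' @param state_old Previous time level (required when `dt` is given).
#' @param quiet Suppress the non-convergence warning.
#' @return The updated state with attribute `"residuals"` (per-iteration
#'   normalized mass residual) and `"converged"`.
#' @export
simple_iterate <- function(state, mesh, props, mag, pp, cfg,
                           t = state$t, dt = NULL, state_old = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(state, "sim_state"), inherits(mesh, "axi_mesh"),
            inherits(props, "fluid_props"), inherits(mag, "magnetic_config"),
            inherits(pp, "pulsatile_pressure"), inherits(cfg, "solver_config"))
  nz <- mesh$nz; nr <- mesh$nr
  rho <- props$rho
  p_in <- inlet_pressure(t, pp)
  full_stress <- cfg$viscous_form == "full"

  ## magnetic source geometry (per z-column)
  Bc <- field_envelope(mesh$z_c, mag)
  sigB2_vol <- sweep(mesh$vol, 1, props$sigma * Bc^2, "*")
  Hc <- Bc / mag$mu0_mag
  dHc <- field_envelope_deriv(mesh$z_c, mag) / mag$mu0_mag
  fmag_vol <- sweep(mesh$vol, 1, magnetization_force(Hc, dHc, mag), "*")

  trans <- if (!is.null(dt)) rho * mesh$vol / dt else NULL
  if (!is.null(trans) && is.null(state_old))
    stop("state_old is required for a transient step")

  ## reference flux for residual normalization: Poiseuille scale
  mu_ref <- props$carreau$mu_inf
  u_ref <- pp$Pm * mesh$geom$R0^2 / (8 * mu_ref * mesh$geom$L_vessel)
  ref_flux <- max(rho * u_ref * mesh$geom$R0^2 / 2, 1e-300)

  bc_uz <- .bc_uz(); bc_ur <- .bc_ur(); bc_p <- .bc_p(p_in)
  residuals <- numeric(0)
  converged <- FALSE
  best <- Inf

  ## Aitken extrapolation bookkeeping: the under-relaxed fixed-point
  ## iteration converges geometrically in a single smooth mode on
  ## high-aspect meshes; periodically boosting along the last increment by
  ## rho/(1-rho) removes that mode without disturbing stability.
  hist1 <- NULL; hist2 <- NULL
  aitken <- function(cur, prev, prev2) {
    for (f in c("u_z", "u_r", "p")) {
      d1 <- prev[[f]] - prev2[[f]]
      d2 <- cur[[f]] - prev[[f]]
      den <- sum(d1 * d1)
      if (den <= 0) next
      num <- sum(d2 * d1)
      rho <- num / den
      css <- num^2 / (den * sum(d2 * d2) + 1e-300)
      if (rho > 0.5 && rho < 0.995 && css > 0.9)
        cur[[f]] <- cur[[f]] + min(rho / (1 - rho), 100) * d2
    }
    cur
  }

  for (it in seq_len(cfg$max_outer)) {
    gp <- cell_gradients(state$p, mesh, bc_p)
    guz <- cell_gradients(state$u_z, mesh, bc_uz)
    gur <- cell_gradients(state$u_r, mesh, bc_ur)

    ## viscosity update from the shear-rate invariant
    gam <- shear_rate_invariant(guz$dz, guz$dr, gur$dz, gur$dr,
                                state$u_r, mesh$rc_cell)
    mu_new <- carreau_viscosity(gam, props$carreau)
    state$mu <- state$mu + cfg$relax_mu * (mu_new - state$mu)
    mu <- state$mu
    mu_zf <- zface_interp(mu); mu_ef <- etaface_interp(mu)

    ## pressure force on cells (face-pressure summation; the r-component
    ## balances the azimuthal-face projection p * A_cs)
    p_zf <- zface_interp(state$p)
    p_zf[1, ] <- p_in; p_zf[nz + 1, ] <- 0
    p_ef <- etaface_interp(state$p)
    Pz <- -((p_zf[2:(nz + 1), ] * mesh$Az_zface[2:(nz + 1), ] -
               p_zf[1:nz, ] * mesh$Az_zface[1:nz, ]) +
              (p_ef[, 2:(nr + 1)] * mesh$Az_eta[, 2:(nr + 1)] -
                 p_ef[, 1:nr] * mesh$Az_eta[, 1:nr]))
    Pr <- -((p_ef[, 2:(nr + 1)] * mesh$Ar_eta[, 2:(nr + 1)] -
               p_ef[, 1:nr] * mesh$Ar_eta[, 1:nr]) -
              state$p * mesh$Acs)

    ## deferred full-stress (transpose-gradient) fluxes
    if (full_stress) {
      gdz_zf <- zface_interp(guz$dz); gdr_zf <- zface_interp(guz$dr)
      rdz_zf <- zface_interp(gur$dz)
      gdz_ef <- etaface_interp(guz$dz); gdr_ef <- etaface_interp(guz$dr)
      rdz_ef <- etaface_interp(gur$dz); rdr_ef <- etaface_interp(gur$dr)
      Gzf_z <- mu_zf * gdz_zf * mesh$Az_zface
      Gef_z <- mu_ef * (gdz_ef * mesh$Az_eta + rdz_ef * mesh$Ar_eta)
      Tz <- (Gzf_z[2:(nz + 1), ] - Gzf_z[1:nz, ]) +
        (Gef_z[, 2:(nr + 1)] - Gef_z[, 1:nr])
      rdr_zf <- zface_interp(gur$dr)
      Gzf_r <- mu_zf * gdr_zf * mesh$Az_zface
      Gef_r <- mu_ef * (gdr_ef * mesh$Az_eta + rdr_ef * mesh$Ar_eta)
      Tr <- (Gzf_r[2:(nz + 1), ] - Gzf_r[1:nz, ]) +
        (Gef_r[, 2:(nr + 1)] - Gef_r[, 1:nr])
      hoop_coef <- 2
    } else {
      Tz <- 0; Tr <- 0
      hoop_coef <- 1
    }

    ## z-momentum: implicit (Patankar) under-relaxation -- the stable
    ## pairing with the under-relaxed pressure correction
    sys <- discretize_transport(
      mesh, state$Fz, state$Fe, mu, bc_uz, grad = guz,
      trans_coef = trans,
      phi_old = if (!is.null(trans)) state_old$u_z else NULL,
      aP_extra = sigB2_vol,
      src = Pz + fmag_vol + Tz)
    rsys <- relax_system(sys, state$u_z, cfg$relax_u)
    uz_new <- solve_field(rsys, nz, nr)
    Dc <- mesh$vol / matrix(rsys$diag, nz, nr)

    ## r-momentum (hoop stress implicit on the diagonal)
    hoop <- hoop_coef * mu * mesh$vol / mesh$r_hoop^2
    sys <- discretize_transport(
      mesh, state$Fz, state$Fe, mu, bc_ur, grad = gur,
      trans_coef = trans,
      phi_old = if (!is.null(trans)) state_old$u_r else NULL,
      aP_extra = hoop,
      src = Pr + Tr)
    rsys <- relax_system(sys, state$u_r, cfg$relax_u)
    ur_new <- solve_field(rsys, nz, nr)

    du <- max(abs(uz_new - state$u_z), abs(ur_new - state$u_r)) /
      max(abs(uz_new), u_ref, 1e-300)
    u_prev_z <- state$u_z; u_prev_r <- state$u_r
    state$u_z <- uz_new; state$u_r <- ur_new

    ## Rhie-Chow fluxes and mass residual
    fl <- face_fluxes(mesh, uz_new, ur_new, state$p, gp, Dc, rho, p_in,
                      trans = trans, state_old = state_old,
                      alpha_u = cfg$relax_u,
                      prev = list(u_z = u_prev_z, u_r = u_prev_r,
                                  Fz = state$Fz, Fe = state$Fe))
    res <- sum(abs(cell_imbalance(mesh, fl$Fz, fl$Fe))) / ref_flux
    residuals <- c(residuals, res)
    if (!is.finite(res) || (it > 20 && res > 1e4 * max(best, 1)))
      stop(sprintf(
        "SIMPLE diverged at iteration %d (residual %.3g, best %.3g)",
        it, res, best))
    best <- min(best, res)

    state <- pressure_correction(mesh, state, fl$Fz, fl$Fe, Dc, rho,
                                 cfg$relax_p)
    if (res < cfg$outer_tol && du < cfg$du_tol) { converged <- TRUE; break }

    if (!is.null(hist2) && it %% 5 == 0 && !isFALSE(cfg$accel)) {
      state2 <- aitken(state, hist1, hist2)
      hist1 <- NULL; hist2 <- NULL
      state <- state2
    } else {
      hist2 <- hist1
      hist1 <- list(u_z = state$u_z, u_r = state$u_r, p = state$p)
    }
  }
  if (!converged && !quiet)
    warning(sprintf("SIMPLE stopped at max_outer = %d (residual %.3g)",
                    cfg$max_outer, residuals[length(residuals)]))
  state$t <- t
  attr(state, "residuals") <- residuals
  attr(state, "converged") <- converged
  state
}

#' Steady-state solve at frozen inlet pressure
#'
#' Convenience wrapper: initializes a lubrication-theory state (unless one
#' is given) and iterates SIMPLE without the transient term.  If the outer
#' iteration diverges -- which happens on strongly constricted geometries
#' at the default under-relaxation -- the solve restarts automatically with
#' progressively gentler relaxation factors and a larger iteration budget.
#'
#' @inheritParams simple_iterate
#' @param state Optional warm-start state.
#' @param max_retries Number of gentler-relaxation restarts allowed.
#' @return Converged `sim_state` (with `"residuals"`/`"converged"`
#'   attributes); the energy equation is not solved here.
#' @export
solve_steady <- function(mesh, props, mag, pp, cfg, t = 0, state = NULL,
                         quiet = FALSE, max_retries = 3) {
  state0 <- if (is.null(state)) init_state(mesh, props, pp, cfg, t0 = t)
  else state
  for (try in 0:max_retries) {
    out <- tryCatch(
      simple_iterate(state0, mesh, props, mag, pp, cfg, t = t, dt = NULL,
                     quiet = quiet),
      error = function(e) e)
    if (!inherits(out, "error")) return(out)
    if (try == max_retries) stop(out)
    cfg$relax_u <- 0.6 * cfg$relax_u
    cfg$relax_p <- 0.6 * cfg$relax_p
    cfg$max_outer <- as.integer(ceiling(1.6 * cfg$max_outer))
  }
}
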