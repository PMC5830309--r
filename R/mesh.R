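# Body-fitted axisymmetric finite-volume mesh.
#
# The grid is structured in (z, eta) with eta = r / R(z) in [0, 1], uniform
# in both directions; cell (i, j) spans z in [z_f[i], z_f[i+1]] and eta in
# [eta_f[j], eta_f[j+1]].  All areas and volumes are per unit radian (the
# 2*pi factor cancels in every balance).  Faces at constant z are flat
# annuli with a purely axial area vector; faces at constant eta are
# surfaces of revolution r = eta * R(z) with area vector
# (A_z, A_r) = (-eta^2 (R_e^2 - R_w^2) / 2, eta * int R dz).
# For a 1-radian wedge the closed-surface identity is: the axial area
# components sum to zero exactly, and the radial components sum to the
# cross-sectional (z-r plane) area of the cell, which is the projection of
# the two azimuthal faces.

# 10-point Gauss-Legendre nodes/weights on [-1, 1]
.gl10 <- list(
  x = c(-0.9739065285171717, -0.8650633666889845, -0.6794095682990244,
        -0.4333953941292472, -0.1488743389816312,  0.1488743389816312,
         0.4333953941292472,  0.6794095682990244,  0.8650633666889845,
         0.9739065285171717),
  w = c(0.0666713443086881, 0.1494513491505806, 0.2190863625159820,
        0.2692667193099963, 0.2955242247147529, 0.2955242247147529,
        0.2692667193099963, 0.2190863625159820, 0.1494513491505806,
        0.0666713443086881))

# integrate f(z) over [a, b], splitting at the wall-profile breakpoints so
# every Gauss panel sees a smooth integrand
.integrate_profile <- function(f, a, b, geom) {
  if (b <= a) return(0)
  brk <- c(geom$d, geom$d + geom$L0 / 2, geom$d + geom$L0)
  pts <- sort(unique(c(a, b, brk[brk > a & brk < b])))
  tot <- 0
  for (s in seq_len(length(pts) - 1)) {
    lo <- pts[s]; hi <- pts[s + 1]
    xm <- 0.5 * (hi + lo); xr <- 0.5 * (hi - lo)
    tot <- tot + xr * sum(.gl10$w * f(xm + xr * .gl10$x))
  }
  tot
}

#' Build a body-fitted axisymmetric finite-volume mesh
#'
#' Constructs a structured quadrilateral grid for the stenosed vessel in
#' mapped coordinates `(z, eta = r / R(z))`, uniform in both directions,
#' with all metric quantities (face area vectors, cell volumes,
#' cross-section areas, diffusion geometry) precomputed.  Areas and volumes
#' are per unit radian.
#'
#' @param geom A [stenosis_geometry()].
#' @param nz,nr Number of cells in the axial and radial direction (>= 4).
#' @return An object of class `axi_mesh`.
#' @export
build_mesh <- function(geom, nz, nr) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  if (nz < 4 || nr < 4) stop("need nz >= 4 and nr >= 4 cells")
  if (geom$delta >= geom$R0) stop("degenerate geometry: delta >= R0")
  nz <- as.integer(nz); nr <- as.integer(nr)

  z_f <- seq(0, geom$L_vessel, length.out = nz + 1)
  eta_f <- seq(0, 1, length.out = nr + 1)
  z_c <- 0.5 * (z_f[-1] + z_f[-(nz + 1)])
  eta_c <- 0.5 * (eta_f[-1] + eta_f[-(nr + 1)])

  Rf <- stenosis_radius(z_f, geom)
  Rc <- stenosis_radius(z_c, geom)
  Rpc <- stenosis_radius_deriv(z_c, geom)

  IR <- vapply(seq_len(nz), function(i)
    .integrate_profile(function(z) stenosis_radius(z, geom),
                       z_f[i], z_f[i + 1], geom), 0)
  IR2 <- vapply(seq_len(nz), function(i)
    .integrate_profile(function(z) stenosis_radius(z, geom)^2,
                       z_f[i], z_f[i + 1], geom), 0)

  deta2 <- eta_f[-1]^2 - eta_f[-(nr + 1)]^2   # length nr
  deta <- diff(eta_f)

  # constant-z faces: (nz+1) x nr, purely axial area
  Az_zface <- outer(Rf^2 / 2, deta2)
  # constant-eta faces: nz x (nr+1)
  Ar_eta <- outer(IR, eta_f)
  dR2 <- Rf[-1]^2 - Rf[-(nz + 1)]^2           # length nz
  Az_eta <- outer(-dR2 / 2, eta_f^2)

  vol <- outer(IR2, deta2 / 2)                # nz x nr
  Acs <- outer(IR, deta)                      # cross-section area per cell
  r_hoop <- vol / Acs                         # effective cell radius

  # cell centroids (z at column midpoint, r on the mapped ray)
  zc_cell <- matrix(z_c, nz, nr)
  rc_cell <- outer(Rc, eta_c)

  # diffusion geometry ------------------------------------------------
  # constant-z faces: gdiff = |A|^2/(A.d) and non-orthogonal remainder
  # T = A - gdiff * d (z-component of T is 0 for these faces)
  gdiff_z <- matrix(0, nz + 1, nr)
  Tz_r <- matrix(0, nz + 1, nr)
  dz_c <- diff(z_c)
  for (j in seq_len(nr)) {
    # interior faces i = 2..nz between cells (i-1, j) and (i, j)
    dzv <- dz_c
    drv <- eta_c[j] * diff(Rc)
    gdiff_z[2:nz, j] <- Az_zface[2:nz, j] / dzv
    Tz_r[2:nz, j] <- -Az_zface[2:nz, j] * drv / dzv
    # inlet face (i = 1): cell 1 centroid to face centroid
    dzb <- z_c[1] - z_f[1]
    drb <- eta_c[j] * (Rc[1] - Rf[1])
    gdiff_z[1, j] <- Az_zface[1, j] / dzb
    Tz_r[1, j] <- -Az_zface[1, j] * drb / dzb
    # outlet face (i = nz + 1)
    dzb <- z_f[nz + 1] - z_c[nz]
    drb <- eta_c[j] * (Rf[nz + 1] - Rc[nz])
    gdiff_z[nz + 1, j] <- Az_zface[nz + 1, j] / dzb
    Tz_r[nz + 1, j] <- -Az_zface[nz + 1, j] * drb / dzb
  }

  # constant-eta faces: d is radial between centroids in the same column
  gdiff_eta <- matrix(0, nz, nr + 1)
  Teta_z <- matrix(0, nz, nr + 1)
  Teta_r <- matrix(0, nz, nr + 1)
  for (j in 2:nr) {
    drv <- (eta_c[j] - eta_c[j - 1]) * Rc
    A2 <- Az_eta[, j]^2 + Ar_eta[, j]^2
    gdiff_eta[, j] <- A2 / (Ar_eta[, j] * drv)
    Teta_z[, j] <- Az_eta[, j]
    Teta_r[, j] <- Ar_eta[, j] - gdiff_eta[, j] * drv
  }
  # wall face j = nr + 1: cell centroid to wall face centroid
  drw <- (1 - eta_c[nr]) * Rc
  A2w <- Az_eta[, nr + 1]^2 + Ar_eta[, nr + 1]^2
  gdiff_eta[, nr + 1] <- A2w / (Ar_eta[, nr + 1] * drw)
  Teta_z[, nr + 1] <- Az_eta[, nr + 1]
  Teta_r[, nr + 1] <- Ar_eta[, nr + 1] - gdiff_eta[, nr + 1] * drw
  # axis face j = 1 has zero area: all metrics stay 0

  # wall geometry for shear-stress evaluation
  wall_norm <- sqrt(1 + Rpc^2)
  wall_tangent <- cbind(1 / wall_norm, Rpc / wall_norm)     # (t_z, t_r)
  wall_dist <- Rc * (1 - eta_c[nr]) / wall_norm             # centroid->wall
  wall_area <- sqrt(Az_eta[, nr + 1]^2 + Ar_eta[, nr + 1]^2)

  structure(list(
    geom = geom, nz = nz, nr = nr,
    z_f = z_f, eta_f = eta_f, z_c = z_c, eta_c = eta_c,
    Rf = Rf, Rc = Rc, Rpc = Rpc, IR = IR, IR2 = IR2,
    Az_zface = Az_zface, Ar_eta = Ar_eta, Az_eta = Az_eta,
    vol = vol, Acs = Acs, r_hoop = r_hoop,
    zc_cell = zc_cell, rc_cell = rc_cell,
    gdiff_z = gdiff_z, Tz_r = Tz_r,
    gdiff_eta = gdiff_eta, Teta_z = Teta_z, Teta_r = Teta_r,
    wall_tangent = wall_tangent, wall_dist = wall_dist,
    wall_area = wall_area),
    class = "axi_mesh")
}

#' @export
print.axi_mesh <- function(x, ...) {
  cat(sprintf(
    "axi_mesh: %d x %d cells (axial x radial), %d faces on the wall, lumen volume %.4g m^3/rad\n",
    x$nz, x$nr, x$nz, sum(x$vol)))
  invisible(x)
}

#' Nested mesh refinement
#'
#' Rebuilds the mesh with `factor` times as many cells in each direction.
#' Because the grid is uniform in the mapped coordinates the refined mesh is
#' exactly nested: every parent cell is the union of `factor^2` children,
#' and the wall geometry is unchanged.
#'
#' @param mesh An [build_mesh()] mesh.
#' @param factor Integer refinement factor (>= 2).
#' @return A refined `axi_mesh`.
#' @export
refine_mesh <- function(mesh, factor = 2) {
  stopifnot(inherits(mesh, "axi_mesh"))
  factor <- as.integer(factor)
  if (factor < 2) stop("refinement factor must be >= 2")
  build_mesh(mesh$geom, mesh$nz * factor, mesh$nr * factor)
}

# interior-face closure check used by tests and sanity asserts:
# returns max |sum of outward area vectors| over cells, where the radial
# component is balanced against the azimuthal projection A_cs
mesh_closure_residual <- function(mesh) {
  nz <- mesh$nz; nr <- mesh$nr
  sz <- mesh$Az_zface[2:(nz + 1), , drop = FALSE] -
    mesh$Az_zface[1:nz, , drop = FALSE] +
    mesh$Az_eta[, 2:(nr + 1), drop = FALSE] -
    mesh$Az_eta[, 1:nr, drop = FALSE]
  sr <- mesh$Ar_eta[, 2:(nr + 1), drop = FALSE] -
    mesh$Ar_eta[, 1:nr, drop = FALSE] - mesh$Acs
  scale <- max(mesh$wall_area, mesh$Az_zface)
  max(abs(sz), abs(sr)) / scale
}
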