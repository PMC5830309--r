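# Structured outputs: legacy-ASCII VTK unstructured-grid snapshots (with a
# minimal reader for round-trip checks), CSV probe traces, run logs, and
# deterministic test fixtures.

#' Write a solution snapshot as a VTK unstructured grid
#'
#' Emits a legacy-ASCII VTK file: mesh nodes at the face intersections
#' `(z, r = eta R(z), 0)`, one quad per cell, and the fields `u_z`, `u_r`,
#' `p`, `T`, `mu` plus the assembled `velocity` vector as cell data.  The
#' field names are part of the output contract and stay stable across
#' versions.
#'
#' @param state A `sim_state`.
#' @param mesh The mesh.
#' @param path Output file path (conventionally `.vtk`).
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, mesh, path) {
  nz <- mesh$nz; nr <- mesh$nr
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  npts <- (nz + 1) * (nr + 1)
  ncell <- nz * nr
  # nodes: index p(i, j) = i + j * (nz + 1), 0-based, i along z
  zs <- rep(mesh$z_f, nr + 1)
  rs <- as.vector(outer(mesh$Rf, mesh$eta_f))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("stenoflow snapshot t=%.9g", state$t),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", npts)), con)
  writeLines(sprintf("%.12g %.12g 0", zs, rs), con)
  ii <- rep(0:(nz - 1), nr); jj <- rep(0:(nr - 1), each = nz)
  p00 <- ii + jj * (nz + 1)
  writeLines(sprintf("CELLS %d %d", ncell, 5 * ncell), con)
  writeLines(sprintf("4 %d %d %d %d", p00, p00 + 1,
                     p00 + nz + 2, p00 + nz + 1), con)
  writeLines(sprintf("CELL_TYPES %d", ncell), con)
  writeLines(rep("9", ncell), con)   # VTK_QUAD
  writeLines(sprintf("CELL_DATA %d", ncell), con)
  scalar <- function(name, field) {
    writeLines(c(sprintf("SCALARS %s double 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.12g", as.vector(field)), con)
  }
  scalar("u_z", state$u_z); scalar("u_r", state$u_r)
  scalar("p", state$p); scalar("T", state$T); scalar("mu", state$mu)
  writeLines("VECTORS velocity double", con)
  writeLines(sprintf("%.12g %.12g 0",
                     as.vector(state$u_z), as.vector(state$u_r)), con)
  invisible(path)
}

#' Read back the node coordinates of a VTK snapshot
#'
#' Minimal legacy-ASCII reader used to verify write/read round trips.
#'
#' @param path A file written by [write_snapshot()].
#' @return Matrix with columns `z`, `r`.
#' @export
read_vtk_points <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  xyz <- do.call(rbind, lapply(lines[(ip + 1):(ip + n)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  colnames(xyz) <- c("z", "r", "y3")
  xyz[, c("z", "r")]
}

#' Write probe traces as CSV
#'
#' Fixed column order `t, z_station, r, u_z, T` with a header row.
#'
#' @param traces A data frame of probe rows (from [extract_probe()],
#'   possibly row-bound over stations and times).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_probes <- function(traces, path) {
  cols <- c("t", "z_station", "r", "u_z", "T")
  stopifnot(all(cols %in% names(traces)))
  utils::write.csv(traces[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Deterministic test fixtures
#'
#' Small meshes and manufactured fields for operator unit tests:
#' \describe{
#'   \item{`straight_tube`}{16 x 8 unobstructed vessel plus blood
#'     properties.}
#'   \item{`tiny_stenosis`}{24 x 8 vessel with a 50% stenosis.}
#'   \item{`manufactured_field`}{smooth velocity/temperature fields with
#'     analytically known derivatives on the straight-tube mesh; the seed
#'     deterministically perturbs the field amplitudes.}
#' }
#'
#' @param kind Fixture name.
#' @param seed Integer seed; the same seed yields a bit-identical fixture.
#' @return A list with `mesh`, `props`, and for `manufactured_field` the
#'   fields `u_z`, `u_r`, `T` and the exact gradient closures
#'   `grad_exact(z, r)`.
#' @export
make_fixture <- function(kind = c("straight_tube", "tiny_stenosis",
                                  "manufactured_field"), seed = 1) {
  kind <- match.arg(kind)
  props <- fluid_props()
  if (kind == "straight_tube") {
    geom <- stenosis_geometry(R0 = 0.01, L_vessel = 0.07, d = 0.02,
                              L0 = 0.02, delta = 0)
    return(list(mesh = build_mesh(geom, 16, 8), props = props))
  }
  if (kind == "tiny_stenosis") {
    L0 <- 0.02824
    geom <- stenosis_geometry(R0 = 0.01, L_vessel = 0.07, d = 0.02 - L0 / 2,
                              L0 = L0, delta = 0.005)
    return(list(mesh = build_mesh(geom, 24, 8), props = props))
  }
  ## manufactured smooth fields on a straight tube
  set.seed(seed)
  amp <- stats::runif(3, 0.5, 1.5)
  geom <- stenosis_geometry(R0 = 0.01, L_vessel = 0.07, d = 0.02,
                            L0 = 0.02, delta = 0)
  mesh <- build_mesh(geom, 16, 8)
  R0 <- geom$R0; L <- geom$L_vessel
  kz <- pi / L
  fu <- function(z, r) amp[1] * cos(kz * z) * (1 - (r / R0)^2)
  fv <- function(z, r) amp[2] * sin(kz * z) * (r / R0) * (1 - (r / R0)^2)
  fT <- function(z, r) 310 + amp[3] * cos(kz * z) * (r / R0)^2
  grad_exact <- function(z, r) list(
    duz_dz = -amp[1] * kz * sin(kz * z) * (1 - (r / R0)^2),
    duz_dr = -2 * amp[1] * cos(kz * z) * r / R0^2,
    dur_dz = amp[2] * kz * cos(kz * z) * (r / R0) * (1 - (r / R0)^2),
    dur_dr = amp[2] * sin(kz * z) * (1 - 3 * (r / R0)^2) / R0)
  z <- mesh$zc_cell; r <- mesh$rc_cell
  list(mesh = mesh, props = props,
       u_z = fu(z, r), u_r = fv(z, r), T = fT(z, r),
       fu = fu, fv = fv, fT = fT, grad_exact = grad_exact, amp = amp)
}

# hash of the fully resolved configuration, for the run log
scenario_hash <- function(scn) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  save_scenario(scn, tf)
  unname(tools::md5sum(tf))
}
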