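# Finite-volume discretization of the generic transport equation
#
#   d(rho phi)/dt + div(rho V phi) = div(Gamma grad phi) + S
#
# integrated over each cell: implicit backward-Euler transient, first-order
# upwind convection through the stored face mass fluxes, central diffusion
# with over-relaxed non-orthogonal deferred correction, and linearized
# sources.  Boundary conditions enter through the `bc` spec (Dirichlet /
# Neumann per side, mirror parity across the axis, optionally a mixed
# Dirichlet/Neumann wall via a mask).  The sum of the face mass fluxes is
# subtracted from the diagonal so that a uniform field remains an exact
# solution even before the pressure correction has driven the imbalance to
# zero.

#' Discretize a convection-diffusion transport equation
#'
#' Assembles the sparse linear system of one implicit transport step on an
#' axisymmetric mesh.  Used internally for both momentum components, the
#' pressure correction and the energy equation; exported because it is also
#' the natural hook for scalar transport add-ons.
#'
#' @param mesh An [build_mesh()] mesh.
#' @param Fz,Fe Face mass fluxes through constant-z faces (`(nz+1) x nr`)
#'   and constant-eta faces (`nz x (nr+1)`), kg/s per radian, oriented
#'   along +z / +r.
#' @param Gamma Cell diffusivity field (`nz x nr`), non-negative.
#' @param bc Boundary spec from [bc_spec()].  `wall$type` may additionally
#'   be `"mixed"` with `wall$value` and logical `wall$mask` (length `nz`,
#'   TRUE where Dirichlet).
#' @param grad Optional cell-gradient list (`dz`, `dr`) of the previous
#'   iterate, enabling the deferred non-orthogonal diffusion correction.
#' @param trans_coef Optional transient coefficient per cell
#'   (`rho * vol / dt`, times `cp` for the energy equation).
#' @param phi_old Previous-time field (required with `trans_coef`).
#' @param aP_extra Optional non-negative implicit source coefficient added
#'   to the diagonal (e.g. MHD damping `sigma B^2 vol`).
#' @param src Optional explicit source term per cell (already multiplied by
#'   the cell volume).
#' @return List with sparse matrix `A` (`Matrix::dgCMatrix`) and
#'   right-hand side `b`; solve `A x = b` for the new field.
#' @export
discretize_transport <- function(mesh, Fz, Fe, Gamma, bc, grad = NULL,
                                 trans_coef = NULL, phi_old = NULL,
                                 aP_extra = NULL, src = NULL) {
  nz <- mesh$nz; nr <- mesh$nr; N <- nz * nr
  if (any(Gamma < 0)) stop("negative diffusivity")
  Gzf <- zface_interp(Gamma)
  Gef <- etaface_interp(Gamma)
  idx <- function(i, j) i + (j - 1L) * nz

  Ti <- vector("list", 8); Tj <- vector("list", 8); Tx <- vector("list", 8)
  ng <- 0L
  bvec <- numeric(N)
  push <- function(I, J, X) {
    ng <<- ng + 1L
    Ti[[ng]] <<- I; Tj[[ng]] <<- J; Tx[[ng]] <<- X
  }

  ## interior constant-z faces ---------------------------------------
  ii <- rep(2:nz, times = nr); jj <- rep(1:nr, each = nz - 1)
  fz <- cbind(ii, jj)
  P <- idx(ii - 1L, jj); Nn <- idx(ii, jj)
  F <- Fz[fz]; D <- Gzf[fz] * mesh$gdiff_z[fz]
  push(c(P, P, Nn, Nn), c(P, Nn, Nn, P),
       c(D + pmax(F, 0), -(D + pmax(-F, 0)),
         D + pmax(-F, 0), -(D + pmax(F, 0))))
  if (!is.null(grad)) {
    corr <- Gzf[fz] * 0.5 * (grad$dr[P] + grad$dr[Nn]) * mesh$Tz_r[fz]
    bvec[P] <- bvec[P] + corr
    bvec[Nn] <- bvec[Nn] - corr
  }

  ## interior constant-eta faces -------------------------------------
  ii <- rep(1:nz, times = nr - 1); jj <- rep(2:nr, each = nz)
  fe <- cbind(ii, jj)
  P <- idx(ii, jj - 1L); Nn <- idx(ii, jj)
  F <- Fe[fe]; D <- Gef[fe] * mesh$gdiff_eta[fe]
  push(c(P, P, Nn, Nn), c(P, Nn, Nn, P),
       c(D + pmax(F, 0), -(D + pmax(-F, 0)),
         D + pmax(-F, 0), -(D + pmax(F, 0))))
  if (!is.null(grad)) {
    corr <- Gef[fe] *
      (0.5 * (grad$dz[P] + grad$dz[Nn]) * mesh$Teta_z[fe] +
         0.5 * (grad$dr[P] + grad$dr[Nn]) * mesh$Teta_r[fe])
    bvec[P] <- bvec[P] + corr
    bvec[Nn] <- bvec[Nn] - corr
  }

  ## inlet faces (outward normal -z) ----------------------------------
  Pb <- idx(1L, 1:nr)
  F <- Fz[1, ]
  if (bc$inlet$type == "dirichlet") {
    phib <- .bc_value(bc$inlet, nr)
    D <- Gzf[1, ] * mesh$gdiff_z[1, ]
    push(Pb, Pb, D + pmax(-F, 0))
    bvec[Pb] <- bvec[Pb] + (D + pmax(F, 0)) * phib
    if (!is.null(grad))
      bvec[Pb] <- bvec[Pb] + Gamma[Pb] * grad$dr[Pb] * mesh$Tz_r[1, ]
  } else {
    push(Pb, Pb, -F)
  }

  ## outlet faces (outward normal +z) ---------------------------------
  Pb <- idx(nz, 1:nr)
  F <- Fz[nz + 1, ]
  if (bc$outlet$type == "dirichlet") {
    phib <- .bc_value(bc$outlet, nr)
    D <- Gzf[nz + 1, ] * mesh$gdiff_z[nz + 1, ]
    push(Pb, Pb, D + pmax(F, 0))
    bvec[Pb] <- bvec[Pb] + (D + pmax(-F, 0)) * phib
    if (!is.null(grad))
      bvec[Pb] <- bvec[Pb] + Gamma[Pb] * grad$dr[Pb] * mesh$Tz_r[nz + 1, ]
  } else {
    push(Pb, Pb, F)
  }

  ## wall faces (j = nr + 1, no mass flux) ----------------------------
  Pb <- idx(1:nz, nr)
  wtype <- bc$wall$type
  if (wtype %in% c("dirichlet", "mixed")) {
    mask <- if (wtype == "mixed") as.numeric(bc$wall$mask) else rep(1, nz)
    phib <- .bc_value(bc$wall, nz)
    D <- Gef[, nr + 1] * mesh$gdiff_eta[, nr + 1] * mask
    push(Pb, Pb, D)
    bvec[Pb] <- bvec[Pb] + D * phib
    if (!is.null(grad))
      bvec[Pb] <- bvec[Pb] + Gamma[Pb] * mask *
        (grad$dz[Pb] * mesh$Teta_z[, nr + 1] +
           grad$dr[Pb] * mesh$Teta_r[, nr + 1])
  }
  ## axis face has zero area: no contribution

  ## mass-imbalance diagonal compensation ------------------------------
  m_out <- (Fz[2:(nz + 1), , drop = FALSE] - Fz[1:nz, , drop = FALSE]) +
    (Fe[, 2:(nr + 1), drop = FALSE] - Fe[, 1:nr, drop = FALSE])
  push(1:N, 1:N, -as.vector(m_out))

  if (!is.null(trans_coef)) {
    push(1:N, 1:N, as.vector(trans_coef))
    bvec <- bvec + as.vector(trans_coef) * as.vector(phi_old)
  }
  if (!is.null(aP_extra)) push(1:N, 1:N, as.vector(aP_extra))
  if (!is.null(src)) bvec <- bvec + as.vector(src)

  A <- Matrix::sparseMatrix(i = unlist(Ti[1:ng]), j = unlist(Tj[1:ng]),
                            x = unlist(Tx[1:ng]), dims = c(N, N))
  list(A = A, b = bvec)
}

# implicit under-relaxation: a_P/alpha on the diagonal, the complement of
# the old iterate on the rhs; returns the relaxed system plus its diagonal
# (needed for Rhie-Chow interpolation)
relax_system <- function(sys, phi_prev, alpha) {
  d0 <- Matrix::diag(sys$A)
  extra <- d0 * (1 - alpha) / alpha
  list(A = sys$A + Matrix::Diagonal(length(d0), extra),
       b = sys$b + extra * as.vector(phi_prev),
       diag = d0 / alpha)
}

solve_field <- function(sys, nz, nr) {
  x <- as.numeric(Matrix::solve(sys$A, sys$b))
  if (!all(is.finite(x))) stop("linear solver returned non-finite values")
  matrix(x, nz, nr)
}
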