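# Cell-gradient and face-interpolation operators on the mapped grid.
#
# Gradients are computed by central differences in the mapped coordinates
# (z, eta) followed by the chain rule for r = eta * R(z):
#   d/dr   = (1/R) d/deta
#   d/dz|r = d/dz|eta - (eta R'/R) d/deta
# Boundary closures use the face value for Dirichlet sides, one-sided
# differences for Neumann sides, and mirror symmetry across the axis
# (parity +1 for scalars/axial velocity, -1 for radial velocity).

# bc: list(inlet = list(type = "dirichlet"|"neumann", value = scalar|vec),
#          outlet = ..., wall = ..., axis = list(parity = +1|-1))
bc_spec <- function(inlet = list(type = "neumann"),
                    outlet = list(type = "neumann"),
                    wall = list(type = "neumann"),
                    parity = 1) {
  list(inlet = inlet, outlet = outlet, wall = wall, parity = parity)
}

.bc_value <- function(side, n) {
  v <- side$value
  if (is.null(v)) v <- 0
  rep_len(v, n)
}

# returns list(dz, dr): nz x nr matrices of physical-space derivatives
cell_gradients <- function(phi, mesh, bc) {
  nz <- mesh$nz; nr <- mesh$nr
  z_c <- mesh$z_c; eta_c <- mesh$eta_c

  # d/dz at fixed eta
  gz <- matrix(0, nz, nr)
  gz[2:(nz - 1), ] <- (phi[3:nz, ] - phi[1:(nz - 2), ]) /
    (z_c[3:nz] - z_c[1:(nz - 2)])
  if (bc$inlet$type == "dirichlet") {
    fb <- .bc_value(bc$inlet, nr)
    gz[1, ] <- (phi[2, ] - rep(fb, length.out = nr)) / (z_c[2] - mesh$z_f[1])
  } else {
    gz[1, ] <- (phi[2, ] - phi[1, ]) / (z_c[2] - z_c[1])
  }
  if (bc$outlet$type == "dirichlet") {
    fb <- .bc_value(bc$outlet, nr)
    gz[nz, ] <- (rep(fb, length.out = nr) - phi[nz - 1, ]) /
      (mesh$z_f[nz + 1] - z_c[nz - 1])
  } else {
    gz[nz, ] <- (phi[nz, ] - phi[nz - 1, ]) / (z_c[nz] - z_c[nz - 1])
  }

  # d/deta at fixed z
  ge <- matrix(0, nz, nr)
  ge[, 2:(nr - 1)] <- sweep(phi[, 3:nr] - phi[, 1:(nr - 2)], 2,
                            eta_c[3:nr] - eta_c[1:(nr - 2)], "/")
  # axis: mirror cell at -eta_c[1] with parity
  ge[, 1] <- (phi[, 2] - bc$parity * phi[, 1]) / (eta_c[2] + eta_c[1])
  if (bc$wall$type == "dirichlet") {
    wv <- .bc_value(bc$wall, nz)
    ge[, nr] <- (wv - phi[, nr]) / (1 - eta_c[nr])
  } else {
    ge[, nr] <- (phi[, nr] - phi[, nr - 1]) / (eta_c[nr] - eta_c[nr - 1])
  }

  metric <- outer(mesh$Rpc / mesh$Rc, eta_c)   # eta R'/R
  list(dz = gz - metric * ge, dr = sweep(ge, 1, mesh$Rc, "/"))
}

# interpolate a cell field to constant-z faces: (nz+1) x nr
zface_interp <- function(phi) {
  nz <- nrow(phi)
  rbind(phi[1, ], 0.5 * (phi[1:(nz - 1), , drop = FALSE] +
                           phi[2:nz, , drop = FALSE]), phi[nz, ])
}

# interpolate a cell field to constant-eta faces: nz x (nr+1)
etaface_interp <- function(phi) {
  nr <- ncol(phi)
  cbind(phi[, 1], 0.5 * (phi[, 1:(nr - 1), drop = FALSE] +
                           phi[, 2:nr, drop = FALSE]), phi[, nr])
}
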