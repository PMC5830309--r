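#' Carreau shear-thinning viscosity parameters
#'
#' Four-parameter generalized-Newtonian law interpolating between a
#' zero-shear plateau `mu1` and an infinite-shear plateau `mu_inf`:
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_1 - \mu_\infty)
#'   \left[1 + (\lambda\dot\gamma)^2\right]^{(n-1)/2}.}
#' Defaults are the standard whole-blood fit used throughout this package:
#' mu1 = 0.056 Pa s, mu_inf = 0.036 Pa s, lambda = 3.313 s, n = 0.3568.
#'
#' Setting `mu1 == mu_inf` degenerates to a Newtonian fluid of that
#' viscosity (lambda and n then have no effect).
#'
#' @param mu1 Zero-shear viscosity, Pa s.
#' @param mu_inf Infinite-shear viscosity, Pa s; `mu_inf <= mu1`.
#' @param lam Relaxation time, s; positive.
#' @param n Power index; `0 < n <= 1` (shear-thinning for n < 1).
#' @return An object of class `carreau_params`.
#' @export
carreau_params <- function(mu1 = 0.056, mu_inf = 0.036,
                           lam = 3.313, n = 0.3568) {
  stopifnot(mu1 > 0, mu_inf > 0, lam > 0, n > 0, n <= 1)
  if (mu_inf > mu1)
    stop("mu_inf must not exceed mu1 (shear-thinning law)")
  structure(list(mu1 = mu1, mu_inf = mu_inf, lam = lam, n = n),
            class = "carreau_params")
}

#' Newtonian limit of the Carreau law
#'
#' @param mu Constant dynamic viscosity, Pa s.
#' @return A `carreau_params` with both plateaus equal to `mu`.
#' @export
newtonian_params <- function(mu) carreau_params(mu1 = mu, mu_inf = mu)

#' @export
print.carreau_params <- function(x, ...) {
  if (x$mu1 == x$mu_inf) {
    cat(sprintf("Newtonian fluid: mu = %g Pa s\n", x$mu1))
  } else {
    cat(sprintf("Carreau fluid: mu1 = %g, mu_inf = %g Pa s, lambda = %g s, n = %g\n",
                x$mu1, x$mu_inf, x$lam, x$n))
  }
  invisible(x)
}

#' Carreau dynamic viscosity
#'
#' @param gamma_dot Shear rate(s), 1/s; non-negative.
#' @param p A [carreau_params()].
#' @return Dynamic viscosity, Pa s, bounded in `[mu_inf, mu1]` and monotone
#'   non-increasing in `gamma_dot`.
#' @examples
#' carreau_viscosity(0, carreau_params())      # 0.056
#' carreau_viscosity(1e9, carreau_params())    # ~0.036
#' @export
carreau_viscosity <- function(gamma_dot, p) {
  stopifnot(inherits(p, "carreau_params"))
  if (any(gamma_dot < 0)) stop("shear rate must be non-negative")
  p$mu_inf + (p$mu1 - p$mu_inf) *
    (1 + (p$lam * gamma_dot)^2)^((p$n - 1) / 2)
}

#' Shear-rate invariant of an axisymmetric velocity gradient
#'
#' Computes the generalized-Newtonian shear rate
#' \eqn{\dot\gamma = \sqrt{2\,\mathbf{D}:\mathbf{D}}} from the components of
#' the velocity gradient in axisymmetric cylindrical coordinates
#' (swirl-free, `u_theta = 0`).  The rate-of-strain tensor has components
#' `D_rr = du_r/dr`, `D_zz = du_z/dz`, the hoop term `D_tt = u_r / r`, and
#' `D_rz = (du_r/dz + du_z/dr) / 2`, so
#' \deqn{\dot\gamma^2 = 2\left(D_{rr}^2 + D_{\theta\theta}^2 + D_{zz}^2\right)
#'   + 4 D_{rz}^2.}
#' On the axis (`r = 0`) the hoop term is taken as its regular limit
#' `du_r/dr`.
#'
#' For pure axial shear `du_z/dr = s` this reduces to `|s|`; a Poiseuille
#' profile `u_z = U (1 - r^2/R^2)` gives `2U/R` at the wall.
#'
#' @param duz_dz,duz_dr,dur_dz,dur_dr Velocity-gradient components (1/s),
#'   any common vector/matrix shape.
#' @param ur Radial velocity (m/s), same shape.
#' @param r Radial position (m), same shape; may contain zeros (axis).
#' @return Shear rate `gamma_dot >= 0`, same shape as inputs.
#' @export
shear_rate_invariant <- function(duz_dz, duz_dr, dur_dz, dur_dr, ur, r) {
  hoop <- ifelse(r > 0, ur / r, dur_dr)
  drz <- 0.5 * (dur_dz + duz_dr)
  sqrt(2 * (dur_dr^2 + hoop^2 + duz_dz^2) + 4 * drz^2)
}
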