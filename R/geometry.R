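#' Stenosed-vessel geometry
#'
#' Describes an axisymmetric vessel of unobstructed radius `R0` and length
#' `L_vessel` carrying a single stenosis that starts at axial position `d`,
#' extends over a length `L0`, and protrudes a height `delta` into the lumen
#' (blockage fraction `delta / R0`).
#'
#' The default wall profile is asymmetric: a straight converging ramp over
#' the proximal half of the stenosis and a cosine diverging ramp over the
#' distal half, so the throat sits at `z = d + L0/2`.  A symmetric
#' double-cosine variant is available via `profile = "cosine"`.
#'
#' @param R0 Unobstructed lumen radius (m).
#' @param L_vessel Vessel length (m).
#' @param d Axial position where the stenosis begins (m).
#' @param L0 Stenosis length (m).
#' @param delta Stenosis height (m); must satisfy `0 <= delta < R0`.
#' @param profile `"linear_cosine"` (default, converging ramp + cosine
#'   recovery) or `"cosine"` (symmetric double-cosine bump).
#' @return An object of class `stenosis_geometry`.
#' @examples
#' geom <- stenosis_geometry(R0 = 0.01, L_vessel = 0.07,
#'                           d = 0.00588, L0 = 0.02824, delta = 0.005)
#' stenosis_radius(0.02, geom) / geom$R0   # 0.5 at the throat
#' @export
stenosis_geometry <- function(R0, L_vessel, d, L0, delta,
                              profile = c("linear_cosine", "cosine")) {
  profile <- match.arg(profile)
  stopifnot(is.numeric(R0), R0 > 0, is.numeric(L_vessel), L_vessel > 0)
  if (!is.numeric(delta) || delta < 0 || delta >= R0)
    stop("stenosis height must satisfy 0 <= delta < R0 (got delta = ",
         delta, ", R0 = ", R0, ")")
  if (d < 0 || L0 < 0 || d + L0 > L_vessel + 1e-12 * L_vessel)
    stop("stenosis extent [d, d + L0] must lie inside [0, L_vessel]")
  structure(list(R0 = R0, L_vessel = L_vessel, d = d, L0 = L0,
                 delta = delta, profile = profile),
            class = "stenosis_geometry")
}

#' @export
print.stenosis_geometry <- function(x, ...) {
  cat(sprintf(
    "stenosis_geometry: R0 = %g m, L = %g m, stenosis [%g, %g] m, blockage %.1f%% (%s)\n",
    x$R0, x$L_vessel, x$d, x$d + x$L0, 100 * x$delta / x$R0, x$profile))
  invisible(x)
}

#' Lumen radius of the stenosed wall
#'
#' Evaluates the parametric wall profile.  With the default
#' `"linear_cosine"` profile the lumen radius is
#' \deqn{r(z)/R_0 = \cases{1 - \frac{2\delta}{R_0 L_0}(z - d) & d < z \le d + L_0/2 \cr
#'   1 - \frac{\delta}{2 R_0}\left[1 + \cos\frac{2\pi}{L_0}(z - d - L_0/2)\right] & d + L_0/2 < z \le d + L_0 \cr
#'   1 & otherwise}}
#' which is continuous, bounded in `[R0 - delta, R0]`, and attains its
#' minimum `R0 - delta` at the throat `z = d + L0/2`.
#'
#' @param z Axial position(s), m; must lie in `[0, L_vessel]`.
#' @param geom A [stenosis_geometry()].
#' @return Lumen radius (m), vectorized over `z`.
#' @export
stenosis_radius <- function(z, geom) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  tol <- 1e-12 * max(geom$L_vessel, 1)
  if (any(z < -tol) || any(z > geom$L_vessel + tol))
    stop("axial position outside the vessel [0, ", geom$L_vessel, "] m")
  R0 <- geom$R0; d <- geom$d; L0 <- geom$L0; delta <- geom$delta
  r <- rep(R0, length(z))
  if (delta == 0 || L0 == 0) return(r)
  if (geom$profile == "linear_cosine") {
    conv <- z > d & z <= d + L0 / 2
    div  <- z > d + L0 / 2 & z <= d + L0
    r[conv] <- R0 * (1 - (2 * delta / (R0 * L0)) * (z[conv] - d))
    r[div]  <- R0 * (1 - (delta / (2 * R0)) *
                       (1 + cos((2 * pi / L0) * (z[div] - d - L0 / 2))))
  } else {
    # symmetric double-cosine bump, throat at d + L0/2
    inb <- z > d & z <= d + L0
    r[inb] <- R0 - (delta / 2) *
      (1 - cos((2 * pi / L0) * (z[inb] - d)))
  }
  r
}

#' First derivative dR/dz of the wall profile
#'
#' Needed by the mesh metrics and wall-normal constructions.  Piecewise
#' analytic; at the (measure-zero) branch joints the right-sided derivative
#' is returned.
#'
#' @inheritParams stenosis_radius
#' @return dR/dz (dimensionless), vectorized over `z`.
#' @export
stenosis_radius_deriv <- function(z, geom) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  R0 <- geom$R0; d <- geom$d; L0 <- geom$L0; delta <- geom$delta
  dr <- numeric(length(z))
  if (delta == 0 || L0 == 0) return(dr)
  if (geom$profile == "linear_cosine") {
    conv <- z > d & z <= d + L0 / 2
    div  <- z > d + L0 / 2 & z <= d + L0
    dr[conv] <- -2 * delta / L0
    dr[div]  <- (delta * pi / L0) *
      sin((2 * pi / L0) * (z[div] - d - L0 / 2))
  } else {
    inb <- z > d & z <= d + L0
    dr[inb] <- -(delta * pi / L0) * sin((2 * pi / L0) * (z[inb] - d))
  }
  dr
}
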