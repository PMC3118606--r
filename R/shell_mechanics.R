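#' Shape coefficient of an ellipsoid of revolution
#'
#' The dimensionless coefficient s = 1 - a^2 / (2 b^2) giving the peak
#' equatorial hoop stress of a pressurized prolate ellipsoid of revolution
#' relative to a cylinder of the same equatorial radius. The two closed-form
#' limits are exact: s = 0.5 for a sphere (b = a) and s = 1 for a cylinder
#' (b = Inf).
#'
#' @param geom An [ellipsoid_geometry()].
#' @return The shape coefficient, a number in (0, 1] for `b >= a`.
#' @examples
#' shape_coefficient(ellipsoid_geometry(697, 697))  # sphere -> 0.5
#' shape_coefficient(ellipsoid_geometry(307))       # cylinder -> 1
#' shape_coefficient(ellipsoid_geometry(1, 2))      # 1 - 1/8 = 0.875
#' @export
shape_coefficient <- function(geom) {
  stopifnot(inherits(geom, "ellipsoid_geometry"))
  if (is.infinite(geom$b)) return(1)
  1 - geom$a^2 / (2 * geom$b^2)
}

#' Geometric stress factor
#'
#' The dimensionless multiplier GSF = s * r / w converting transmural
#' pressure into peak membrane hoop stress: shape coefficient `s` times the
#' thinness ratio r/w. It is scale invariant in (r, w): only their ratio
#' matters.
#'
#' @param s Shape coefficient (dimensionless, positive).
#' @param r Radius of curvature, microns (luminal convention).
#' @param w Wall thickness, microns.
#' @return The geometric stress factor, dimensionless.
#' @examples
#' geometric_stress_factor(1.0, r = 307, w = 70)  # anterior canal, ~4.39
#' geometric_stress_factor(0.5, r = 697, w = 58)  # lateral ampulla, ~6.01
#' @export
geometric_stress_factor <- function(s, r, w) {
  stopifnot(is.numeric(s), is.numeric(r), is.numeric(w))
  if (any(!is.finite(w)) || any(w == 0)) {
    stop("invalid measurement: wall thickness must be finite and nonzero")
  }
  if (any(s <= 0) || any(r <= 0) || any(w < 0)) {
    stop("invalid measurement: s, r and w must all be positive")
  }
  s * r / w
}

#' Peak hoop stress under a transmural load
#'
#' Peak membrane hoop stress t = GSF * p, in the units of `p`. Linear in the
#' pressure and zero only at zero load.
#'
#' @param gsf Geometric stress factor (dimensionless, positive).
#' @param load A [load_condition()].
#' @return Hoop stress in the units of the load's pressure.
#' @examples
#' peak_hoop_stress(4.4, load_condition(1))
#' @export
peak_hoop_stress <- function(gsf, load) {
  stopifnot(is.numeric(gsf), inherits(load, "load_condition"))
  if (any(gsf <= 0)) stop("invalid measurement: GSF must be positive")
  gsf * load$p
}

# Principal radii of curvature of the meridian of an ellipsoid of revolution
# at parametric latitude t (0 = equator): r1 meridional, r2 normal (hoop).
# For the cylinder limit r1 = Inf exactly.
principal_radii <- function(geom, latitude) {
  a <- geom$a
  b <- geom$b
  if (is.infinite(b)) {
    return(list(r1 = Inf, r2 = a))
  }
  n <- sqrt(a^2 * sin(latitude)^2 + b^2 * cos(latitude)^2)
  list(r1 = n^3 / (a * b), r2 = a * n / b)
}

#' Membrane stress profile along the meridian
#'
#' Hoop and meridional membrane stresses of a pressurized ellipsoid of
#' revolution at a given latitude, from the general membrane-equilibrium
#' relations for a shell of revolution with principal radii r1 (meridional)
#' and r2 (normal):
#' meridional = p * r2 / (2 w), hoop = (p * r2 / w) * (1 - r2 / (2 r1)).
#'
#' Latitude is the parametric (reduced) latitude of the meridian ellipse, in
#' radians, 0 at the equator and increasing toward the pole. At the equator
#' the hoop value specializes exactly to the shape-coefficient form
#' p * (a / w) * (1 - a^2 / (2 b^2)). For a sphere the state is isotropic and
#' constant in latitude; for a cylinder the meridional (axial) stress is half
#' the hoop stress.
#'
#' @param geom An [ellipsoid_geometry()].
#' @param w Wall thickness, microns.
#' @param load A [load_condition()].
#' @param latitude Parametric latitude in radians; `abs(latitude) < pi/2`
#'   for open (cylinder) profiles.
#' @return A list of class `shell_stress_state` with fields `hoop`,
#'   `meridional` (in the load's pressure units) and `latitude`.
#' @examples
#' sph <- ellipsoid_geometry(697, 697)
#' meridian_stress_profile(sph, w = 58, load_condition(1), latitude = 0.3)
#' @export
meridian_stress_profile <- function(geom, w, load, latitude = 0) {
  stopifnot(inherits(geom, "ellipsoid_geometry"),
            is.numeric(w), length(w) == 1L,
            inherits(load, "load_condition"),
            is.numeric(latitude), length(latitude) == 1L)
  if (!is.finite(w) || w <= 0) stop("invalid measurement: wall thickness must be positive")
  if (!is.finite(latitude) || abs(latitude) > pi / 2) {
    stop("domain error: latitude must lie in [-pi/2, pi/2] radians")
  }
  if (is.infinite(geom$b) && abs(latitude) >= pi / 2) {
    stop("domain error: a cylinder has no pole; |latitude| must be < pi/2")
  }
  rr <- principal_radii(geom, latitude)
  p <- load$p
  meridional <- p * rr$r2 / (2 * w)
  hoop <- (p * rr$r2 / w) * (1 - rr$r2 / (2 * rr$r1))
  structure(list(hoop = hoop, meridional = meridional, latitude = latitude),
            class = "shell_stress_state")
}

#' @export
print.shell_stress_state <- function(x, ...) {
  cat(sprintf("<shell_stress_state> latitude = %g rad: hoop = %g, meridional = %g\n",
              x$latitude, x$hoop, x$meridional))
  invisible(x)
}

#' Equatorial hoop-stress factors of a toroidal shell
#'
#' Hoop-stress multipliers (stress per unit transmural pressure) at the inner
#' and outer equators of a pressurized toroid of tube radius r and loop
#' radius R:
#' inner = (r/w) * (2R - r) / (2 (R - r)), outer = (r/w) * (2R + r) / (2 (R + r)).
#'
#' The inner equator is anticlastic and carries more stress than a straight
#' cylinder of the same bore (r/w); the outer equator carries less. As
#' R/r grows both factors approach the cylinder value r/w, the inner from
#' above. At R = 11 r the inner factor exceeds the cylinder value by 5%.
#'
#' @param geom A [torus_geometry()].
#' @param w Wall thickness, microns.
#' @return A named list with `inner_factor` and `outer_factor`
#'   (dimensionless hoop stress per unit pressure).
#' @examples
#' torus_equatorial_factors(torus_geometry(1, 11), w = 1)
#' @export
torus_equatorial_factors <- function(geom, w) {
  stopifnot(inherits(geom, "torus_geometry"), is.numeric(w), length(w) == 1L)
  if (!is.finite(w) || w <= 0) stop("invalid measurement: wall thickness must be positive")
  r <- geom$r_tube
  R <- geom$R_loop
  list(
    inner_factor = (r / w) * (2 * R - r) / (2 * (R - r)),
    outer_factor = (r / w) * (2 * R + r) / (2 * (R + r))
  )
}
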