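#' Ellipsoid-of-revolution chamber geometry
#'
#' Constructs the geometry of a membranous chamber emulated by a prolate
#' ellipsoid of revolution with equatorial (semiminor) radius `a` and polar
#' (semimajor) semi-axis `b`. Two limits are first-class: `b = a` is a sphere
#' and `b = Inf` is an infinite cylinder. The cylinder is represented by the
#' exact `Inf` sentinel, never by a large finite number, so its closed-form
#' limits are exact.
#'
#' Radii follow the luminal convention: `a` is the inner (endolymph-side)
#' radius as measured in surgery; no midwall correction is applied.
#'
#' @param a Equatorial (semiminor) radius in microns; must be positive.
#' @param b Polar (semimajor) semi-axis in microns; `Inf` for a cylinder.
#'   Defaults to `Inf`.
#' @param allow_oblate If `TRUE`, permit `b < a` (oblate) geometries. The
#'   sphere-to-cylinder continuum used for vestibular chambers only needs
#'   `b >= a`, so oblate shapes are rejected by default.
#' @return An object of class `ellipsoid_geometry` with fields `a` and `b`.
#' @examples
#' ellipsoid_geometry(a = 307)            # cylinder (b = Inf)
#' ellipsoid_geometry(a = 697, b = 697)   # sphere
#' ellipsoid_geometry(a = 1, b = 2)       # prolate ellipsoid
#' @export
ellipsoid_geometry <- function(a, b = Inf, allow_oblate = FALSE) {
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(b), length(b) == 1L)
  if (!is.finite(a) || a <= 0) {
    stop("invalid geometry: semiminor radius 'a' must be finite and positive, got ", a)
  }
  if (is.na(b) || b <= 0) {
    stop("invalid geometry: semimajor semi-axis 'b' must be positive (Inf for a cylinder)")
  }
  if (b < a && !allow_oblate) {
    stop("invalid geometry: oblate shape (b < a) rejected; pass allow_oblate = TRUE to override")
  }
  structure(list(a = a, b = b), class = "ellipsoid_geometry")
}

#' @export
print.ellipsoid_geometry <- function(x, ...) {
  kind <- if (is.infinite(x$b)) "cylinder" else if (x$b == x$a) "sphere" else "ellipsoid"
  cat(sprintf("<ellipsoid_geometry> %s: a = %g um, b = %s um\n",
              kind, x$a, if (is.infinite(x$b)) "Inf" else format(x$b)))
  invisible(x)
}

#' Toroidal chamber geometry
#'
#' Geometry of a semicircular-canal-like toroid: a tube of radius `r_tube`
#' bent into a loop of centerline radius `R_loop`. The inner equator of the
#' torus is anticlastic (principal curvatures of opposite sign), which raises
#' hoop stress above the straight-cylinder value.
#'
#' @param r_tube Tube (cross-section) radius in microns.
#' @param R_loop Centerline (loop) radius in microns; must exceed `r_tube`.
#' @return An object of class `torus_geometry`.
#' @examples
#' torus_geometry(r_tube = 307, R_loop = 307 * 11)
#' @export
torus_geometry <- function(r_tube, R_loop) {
  stopifnot(is.numeric(r_tube), length(r_tube) == 1L,
            is.numeric(R_loop), length(R_loop) == 1L)
  if (!is.finite(r_tube) || r_tube <= 0) {
    stop("invalid geometry: tube radius must be finite and positive")
  }
  if (!is.finite(R_loop) || R_loop <= r_tube) {
    stop("invalid geometry: loop radius must be finite and exceed the tube radius")
  }
  structure(list(r_tube = r_tube, R_loop = R_loop), class = "torus_geometry")
}

#' @export
print.torus_geometry <- function(x, ...) {
  cat(sprintf("<torus_geometry> r_tube = %g um, R_loop = %g um (R/r = %.3g)\n",
              x$r_tube, x$R_loop, x$R_loop / x$r_tube))
  invisible(x)
}

#' Transmural load condition
#'
#' A (quasi-)static transmural pressure acting across the membrane, in any
#' consistent pressure unit. Resting labyrinthine pressure is assumed
#' non-negative (a slight positive pressure keeps the membranes inflated),
#' so negative pressures are rejected.
#'
#' @param p Transmural pressure, `p >= 0`, arbitrary consistent units.
#' @return An object of class `load_condition`.
#' @examples
#' load_condition(1)   # unit pressure: stresses equal their GSF multipliers
#' @export
load_condition <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L)
  if (!is.finite(p) || p < 0) {
    stop("invalid load: transmural pressure must be finite and non-negative, got ", p)
  }
  structure(list(p = p), class = "load_condition")
}

#' @export
print.load_condition <- function(x, ...) {
  cat(sprintf("<load_condition> p = %g (arbitrary pressure units)\n", x$p))
  invisible(x)
}
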