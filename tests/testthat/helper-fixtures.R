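# Shared test helpers: random valid morphometry sets and an independent
# numerical-curvature oracle for the meridian profile.

# Random valid chamber: ordered positive triplets, any shape model.
random_chamber <- function(name, shape = NULL) {
  shape <- shape %||% sample(c("cylinder", "sphere", "ellipsoid", "torus"), 1)
  triplet <- function(scale) sort(stats::runif(3, 0.1, 1) * scale)  # min, mean, max
  w <- triplet(100)
  r <- triplet(800)
  geom <- switch(shape,
    ellipsoid = { a <- stats::runif(1, 1, 100); list(a = a, b = a * stats::runif(1, 1, 5)) },
    torus = { rt <- stats::runif(1, 1, 100); list(r_tube = rt, R_loop = rt * stats::runif(1, 1.5, 20)) },
    list())
  chamber_measurement(name, shape,
                      w_mean = w[2], w_max = w[3], w_min = w[1],
                      r_mean = r[2], r_max = r[3], r_min = r[1],
                      a = geom$a %||% NA_real_, b = geom$b %||% NA_real_,
                      r_tube = geom$r_tube %||% NA_real_,
                      R_loop = geom$R_loop %||% NA_real_)
}

random_measurement_set <- function(n = sample(1:5, 1)) {
  measurement_set(lapply(seq_len(n), function(i) random_chamber(paste0("chamber-", i))),
                  provenance = "randomly generated test set")
}

# Independent oracle: principal radii of the meridian ellipse
# (a cos t, b sin t) by central-difference curvature and normal-to-axis
# intersection, never via the package's closed forms.
numeric_principal_radii <- function(a, b, t, h = 1e-4) {
  rho <- function(t) a * cos(t)
  z <- function(t) b * sin(t)
  d1r <- (rho(t + h) - rho(t - h)) / (2 * h)
  d1z <- (z(t + h) - z(t - h)) / (2 * h)
  d2r <- (rho(t + h) - 2 * rho(t) + rho(t - h)) / h^2
  d2z <- (z(t + h) - 2 * z(t) + z(t - h)) / h^2
  kappa <- abs(d1r * d2z - d1z * d2r) / (d1r^2 + d1z^2)^1.5
  # normal direction (d1z, -d1r)/|.|; distance along it to the rotation axis
  r2 <- rho(t) * sqrt(d1r^2 + d1z^2) / abs(d1z)
  list(r1 = 1 / kappa, r2 = r2)
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps), tol)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
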