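#' Per-chamber sampling specification for a synthetic cohort
#'
#' Describes how one chamber's wall thickness and radius vary across
#' simulated individuals. The default `uniform` distribution draws
#' independently over the stated (min, max) ranges — published morphometry
#' tables give only ranges, no per-individual data or (w, r) covariance, so
#' independence and uniformity are the least-informative emulation. A
#' truncated normal (`truncnorm`) is available for sensitivity checks.
#'
#' @param name Chamber label.
#' @param shape_model `"cylinder"`, `"sphere"`, `"ellipsoid"` or `"torus"`.
#' @param w_range,r_range Length-2 numeric `(min, max)` ranges, microns,
#'   positive and ordered (equal endpoints give a degenerate, zero-variance
#'   chamber).
#' @param distribution `"uniform"` or `"truncnorm"`.
#' @param w_mean,w_sd,r_mean,r_sd Location and spread for `truncnorm`;
#'   default mean is the range midpoint, default sd a quarter of the range
#'   width.
#' @param a,b,r_tube,R_loop Optional geometry parameters carried through to
#'   the generated measurements (required by the ellipsoid/torus models).
#' @return An object of class `chamber_spec`.
#' @examples
#' chamber_spec("Utricle", "cylinder", w_range = c(20, 42), r_range = c(469, 654))
#' @export
chamber_spec <- function(name, shape_model, w_range, r_range,
                         distribution = c("uniform", "truncnorm"),
                         w_mean = NULL, w_sd = NULL, r_mean = NULL, r_sd = NULL,
                         a = NA_real_, b = NA_real_,
                         r_tube = NA_real_, R_loop = NA_real_) {
  distribution <- match.arg(distribution)
  chk_range <- function(rng, field) {
    if (!is.numeric(rng) || length(rng) != 2L || any(!is.finite(rng)) ||
        any(rng <= 0) || rng[1] > rng[2]) {
      stop(sprintf("validation error: chamber '%s': %s range must be positive and ordered (min, max)",
                   name, field))
    }
  }
  chk_range(w_range, "w")
  chk_range(r_range, "r")
  mid <- function(rng) (rng[1] + rng[2]) / 2
  qtr <- function(rng) (rng[2] - rng[1]) / 4
  structure(list(
    name = as.character(name), shape_model = as.character(shape_model),
    w_range = as.numeric(w_range), r_range = as.numeric(r_range),
    distribution = distribution,
    w_mean = w_mean %||% mid(w_range), w_sd = w_sd %||% qtr(w_range),
    r_mean = r_mean %||% mid(r_range), r_sd = r_sd %||% qtr(r_range),
    a = as.numeric(a), b = as.numeric(b),
    r_tube = as.numeric(r_tube), R_loop = as.numeric(R_loop)
  ), class = "chamber_spec")
}

#' Cohort specification for synthetic morphometry
#'
#' Bundles per-chamber sampling specs with a cohort size and a single
#' integer seed. Per-chamber random substreams are derived deterministically
#' from the seed, so a cohort is bit-reproducible from its spec alone.
#'
#' @param chambers List of [chamber_spec()] objects with unique names.
#' @param n_individuals Number of simulated individuals (>= 1). The default
#'   of 12 mirrors the lower end of the measurement counts behind typical
#'   surgical morphometry tables.
#' @param seed Integer seed governing the whole cohort.
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec(toadfish_chamber_specs(), n_individuals = 5, seed = 42)
#' @export
cohort_spec <- function(chambers, n_individuals = 12, seed = 1) {
  if (!is.list(chambers) || length(chambers) == 0L ||
      !all(vapply(chambers, inherits, logical(1), "chamber_spec"))) {
    stop("validation error: 'chambers' must be a non-empty list of chamber_spec objects")
  }
  nms <- vapply(chambers, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("validation error: chamber names must be unique")
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1L) {
    stop("validation error: n_individuals must be at least 1")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("validation error: seed must be an integer")
  structure(list(chambers = chambers, n_individuals = n_individuals, seed = seed),
            class = "cohort_spec")
}

#' Toadfish-range chamber specs
#'
#' Per-chamber sampling specs whose (min, max) ranges are the individual
#' extremes recorded for the toadfish labyrinth (see [toadfish_fixture()]),
#' with the default uniform distribution.
#'
#' @return A list of three [chamber_spec()] objects.
#' @examples
#' toadfish_chamber_specs()
#' @export
toadfish_chamber_specs <- function() {
  fx <- toadfish_fixture()
  lapply(fx$chambers, function(m) {
    chamber_spec(m$name, m$shape_model,
                 w_range = c(m$w_min, m$w_max),
                 r_range = c(m$r_min, m$r_max))
  })
}

draw_within <- function(n, rng, distribution, mean, sd) {
  if (rng[1] == rng[2]) return(rep(rng[1], n))
  if (distribution == "uniform") {
    stats::runif(n, rng[1], rng[2])
  } else {
    # inverse-CDF truncated normal on [min, max]
    lo <- stats::pnorm(rng[1], mean, sd)
    hi <- stats::pnorm(rng[2], mean, sd)
    stats::qnorm(stats::runif(n, lo, hi), mean, sd)
  }
}

#' Generate a synthetic morphometry cohort
#'
#' Draws per-individual (w, r) pairs for every chamber in the spec.
#' Draws are independent across chambers and across the two variables; each
#' chamber uses its own random substream derived deterministically from the
#' cohort seed, so the same spec always yields the identical cohort and
#' adding a chamber does not perturb the draws of the others.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list with `draws` (a
#'   long `data.frame` with columns `individual`, `chamber`, `w`, `r`) and
#'   `spec`.
#' @examples
#' generate_cohort(cohort_spec(toadfish_chamber_specs(), 5, seed = 7))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_individuals
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  blocks <- lapply(seq_along(spec$chambers), function(i) {
    cs <- spec$chambers[[i]]
    # deterministic per-chamber substream, kept within 32-bit integer range
    set.seed((abs(spec$seed) + 104729L * i) %% 2147483629L)
    w <- draw_within(n, cs$w_range, cs$distribution, cs$w_mean, cs$w_sd)
    r <- draw_within(n, cs$r_range, cs$distribution, cs$r_mean, cs$r_sd)
    data.frame(individual = seq_len(n), chamber = cs$name, w = w, r = r,
               stringsAsFactors = FALSE)
  })
  structure(list(draws = do.call(rbind, blocks), spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d individuals x %d chambers (seed %d)\n",
              x$spec$n_individuals, length(x$spec$chambers), x$spec$seed))
  invisible(x)
}

#' Summarize a cohort into a measurement set
#'
#' Collapses per-individual draws into the mean/max/min summary that
#' morphometry tables report, chamber by chamber, yielding a
#' [measurement_set()] ready for the stress pipeline.
#'
#' @param cohort A [generate_cohort()] result.
#' @return A [measurement_set()].
#' @examples
#' cohort_to_measurements(generate_cohort(cohort_spec(toadfish_chamber_specs(), 5, seed = 7)))
#' @export
cohort_to_measurements <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (nrow(cohort$draws) == 0L) stop("validation error: empty cohort")
  chambers <- lapply(cohort$spec$chambers, function(cs) {
    d <- cohort$draws[cohort$draws$chamber == cs$name, ]
    chamber_measurement(cs$name, cs$shape_model,
                        w_mean = mean(d$w), w_max = max(d$w), w_min = min(d$w),
                        r_mean = mean(d$r), r_max = max(d$r), r_min = min(d$r),
                        a = cs$a, b = cs$b,
                        r_tube = cs$r_tube, R_loop = cs$R_loop)
  })
  measurement_set(chambers,
                  provenance = sprintf("synthetic cohort: n = %d, seed = %d",
                                       cohort$spec$n_individuals, cohort$spec$seed))
}

#' Read or write a cohort spec as JSON
#'
#' @param path JSON file path.
#' @return For `read_cohort_spec()`, a [cohort_spec()]; for
#'   `write_cohort_spec()`, `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_cohort_spec(cohort_spec(toadfish_chamber_specs(), 5, seed = 7), f)
#' read_cohort_spec(f)
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  chambers <- lapply(obj$chambers, function(ch) {
    num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    chamber_spec(ch$name, ch$shape_model,
                 w_range = as.numeric(unlist(ch$w_range)),
                 r_range = as.numeric(unlist(ch$r_range)),
                 distribution = ch$distribution %||% "uniform",
                 w_mean = if (is.null(ch$w_mean)) NULL else as.numeric(ch$w_mean),
                 w_sd = if (is.null(ch$w_sd)) NULL else as.numeric(ch$w_sd),
                 r_mean = if (is.null(ch$r_mean)) NULL else as.numeric(ch$r_mean),
                 r_sd = if (is.null(ch$r_sd)) NULL else as.numeric(ch$r_sd),
                 a = num(ch$a), b = num(ch$b),
                 r_tube = num(ch$r_tube), R_loop = num(ch$R_loop))
  })
  cohort_spec(chambers,
              n_individuals = obj$n_individuals %||% 12,
              seed = obj$seed %||% 1)
}

#' @rdname read_cohort_spec
#' @param spec A [cohort_spec()] to serialize.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  obj <- list(
    n_individuals = spec$n_individuals,
    seed = spec$seed,
    chambers = lapply(spec$chambers, function(cs) {
      out <- unclass(cs)
      out[vapply(out, function(v) all(is.na(v)), logical(1))] <- NULL
      out
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
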