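# Round half away from zero at one decimal -- the convention used for all
# displayed table values (base round() is round-half-to-even).
round1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

# Shape coefficient implied by a chamber's assigned shape model.
chamber_shape_coefficient <- function(m) {
  switch(m$shape_model,
    cylinder  = 1,
    sphere    = 0.5,
    ellipsoid = shape_coefficient(ellipsoid_geometry(m$a, m$b)),
    # inner-equator (peak) multiplier of the toroid relative to a cylinder
    torus     = (2 * m$R_loop - m$r_tube) / (2 * (m$R_loop - m$r_tube)),
    stop("validation error: unknown shape model: ", m$shape_model)
  )
}

#' Membrane thinness ratio r/w
#'
#' The radius-to-thickness ratio of a chamber for a chosen statistic. The
#' `mean` statistic pairs the two means. Because individual (r, w) pairs are
#' not published, the extreme statistics use the widest physically recorded
#' envelope: `max` pairs the largest radius with the thinnest wall
#' (stress-maximizing) and `min` the smallest radius with the thickest wall
#' (stress-minimizing).
#'
#' @param m A [chamber_measurement()].
#' @param statistic `"mean"`, `"max"`, or `"min"`.
#' @return The dimensionless thinness ratio.
#' @examples
#' canal <- toadfish_fixture()$chambers[[1]]
#' thinness_ratio(canal, "mean")  # 307/70 ~ 4.4
#' @export
thinness_ratio <- function(m, statistic = c("mean", "max", "min")) {
  stopifnot(inherits(m, "chamber_measurement"))
  statistic <- match.arg(statistic)
  num_den <- switch(statistic,
    mean = c(m$r_mean, m$w_mean),
    max  = c(m$r_max, m$w_min),
    min  = c(m$r_min, m$w_max))
  if (num_den[2] == 0) stop("domain error: zero wall thickness")
  num_den[1] / num_den[2]
}

#' Thin-membrane criterion check
#'
#' Membrane (bending-free) shell analysis requires a thin wall; the
#' engineering criterion used here is a mean thinness ratio r/w of at least
#' 5 (chamber diameter tenfold the wall thickness). Ratios in [4, 5) are
#' flagged as "approaches" so borderline chambers, such as a semicircular
#' canal at 4.4, stay visible in reports rather than being silently failed.
#'
#' @param m A [chamber_measurement()].
#' @return A list with `ratio` (mean r/w), `thin_ok` (`TRUE` iff ratio >= 5)
#'   and `band` (`"thin"`, `"approaches"` for [4, 5), or `"below"`).
#' @examples
#' thin_membrane_check(toadfish_fixture()$chambers[[3]])  # utricle: thin
#' @export
thin_membrane_check <- function(m) {
  ratio <- thinness_ratio(m, "mean")
  band <- if (ratio >= 5) "thin" else if (ratio >= 4) "approaches" else "below"
  list(ratio = ratio, thin_ok = ratio >= 5, band = band)
}

#' Per-chamber stress summary
#'
#' Computes one chamber's shape coefficient, thinness ratios, and geometric
#' stress factors `gsf_stat = s * thinness_ratio(m, stat)` for the mean and
#' the stress-maximizing/minimizing extreme pairings, plus the thin-membrane
#' flag. Normalized stresses are filled in later by [normalize_stress()].
#'
#' @param m A [chamber_measurement()].
#' @return A one-row `data.frame` of class `chamber_stress_summary`.
#' @examples
#' summarize_chamber(toadfish_fixture()$chambers[[3]])  # utricle GSF ~ 17.4
#' @export
summarize_chamber <- function(m) {
  stopifnot(inherits(m, "chamber_measurement"))
  validate_chamber_measurement(m)
  s <- chamber_shape_coefficient(m)
  tm <- thin_membrane_check(m)
  out <- data.frame(
    chamber = m$name,
    shape_model = m$shape_model,
    s = s,
    thinness_mean = thinness_ratio(m, "mean"),
    thinness_max = thinness_ratio(m, "max"),
    thinness_min = thinness_ratio(m, "min"),
    gsf_mean = s * thinness_ratio(m, "mean"),
    gsf_max = s * thinness_ratio(m, "max"),
    gsf_min = s * thinness_ratio(m, "min"),
    thin_ok = tm$thin_ok,
    thin_band = tm$band,
    stringsAsFactors = FALSE
  )
  class(out) <- c("chamber_stress_summary", "data.frame")
  out
}

#' Stress summaries for every chamber in a measurement set
#'
#' @param set A [measurement_set()].
#' @return A `data.frame` with one [summarize_chamber()] row per chamber, in
#'   set order.
#' @examples
#' summarize_chambers(toadfish_fixture())
#' @export
summarize_chambers <- function(set) {
  stopifnot(inherits(set, "measurement_set"))
  out <- do.call(rbind, lapply(set$chambers, summarize_chamber))
  class(out) <- c("chamber_stress_summary", "data.frame")
  out
}

#' Normalize hoop stresses against a reference chamber
#'
#' Because all communicating chambers see the same transmural pressure, the
#' hoop-stress ratio between chambers reduces to the ratio of their
#' geometric stress factors; normalized stress t_n is therefore
#' pressure-free. With `reference = "auto"` the chamber with the smallest
#' mean GSF is the reference, so every mean t_n is >= 1 and the reference's
#' is exactly 1.
#'
#' Two scales are reported per statistic: the full-precision ratio
#' `t_n_<stat> = gsf_<stat> / gsf_mean(reference)` and a one-decimal display
#' value `t_n_<stat>_display` obtained by dividing the unrounded GSF by the
#' reference mean GSF *rounded to one decimal* and rounding the quotient to
#' one decimal. The display convention matches how such tables are
#' conventionally printed from already-rounded reference entries; the
#' full-precision columns are authoritative for further computation.
#'
#' @param summaries A summary `data.frame` from [summarize_chambers()].
#' @param reference `"auto"` (minimum mean GSF) or a chamber name.
#' @return The summaries with `t_n_*` and `t_n_*_display` columns filled and
#'   a `"reference"` attribute naming the reference chamber.
#' @examples
#' normalize_stress(summarize_chambers(toadfish_fixture()))
#' @export
normalize_stress <- function(summaries, reference = "auto") {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1L,
            all(c("chamber", "gsf_mean", "gsf_max", "gsf_min") %in% names(summaries)))
  if (identical(reference, "auto")) {
    ref_idx <- which.min(summaries$gsf_mean)
  } else {
    ref_idx <- match(reference, summaries$chamber)
    if (is.na(ref_idx)) {
      stop("lookup error: unknown reference chamber: ", reference)
    }
  }
  ref_gsf <- summaries$gsf_mean[ref_idx]
  ref_gsf_display <- round1(ref_gsf)
  summaries$t_n_mean <- summaries$gsf_mean / ref_gsf
  summaries$t_n_max <- summaries$gsf_max / ref_gsf
  summaries$t_n_min <- summaries$gsf_min / ref_gsf
  summaries$t_n_mean[ref_idx] <- 1  # exact by definition
  summaries$t_n_mean_display <- round1(summaries$gsf_mean / ref_gsf_display)
  summaries$t_n_max_display <- round1(summaries$gsf_max / ref_gsf_display)
  summaries$t_n_min_display <- round1(summaries$gsf_min / ref_gsf_display)
  attr(summaries, "reference") <- summaries$chamber[ref_idx]
  class(summaries) <- c("chamber_stress_summary", "data.frame")
  summaries
}

#' Individual-extremes (splay) analysis
#'
#' Tabulates, per chamber, the minimum, mean and maximum normalized hoop
#' stress implied by the recorded individual extremes, and reports the
#' cross-chamber disparity under both defensible conventions: the largest
#' individual t_n relative to the reference chamber's *mean* GSF and
#' relative to the reference chamber's *minimum* (stress-minimizing
#' pairing) GSF. Individual (r, w) pairs are not published, so both are
#' envelope estimates, not observed individuals.
#'
#' @param summaries A normalized summary `data.frame` from
#'   [normalize_stress()].
#' @return A `data.frame` (`chamber`, `t_n_min`, `t_n_mean`, `t_n_max`) with
#'   attributes `reference`, `disparity_vs_reference_mean` and
#'   `disparity_vs_reference_min`.
#' @examples
#' extremes_analysis(normalize_stress(summarize_chambers(toadfish_fixture())))
#' @export
extremes_analysis <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  if (!all(c("t_n_min", "t_n_mean", "t_n_max") %in% names(summaries))) {
    stop("extremes_analysis requires normalized summaries; run normalize_stress() first")
  }
  ref <- attr(summaries, "reference")
  ref_idx <- match(ref, summaries$chamber)
  out <- data.frame(
    chamber = summaries$chamber,
    t_n_min = summaries$t_n_min,
    t_n_mean = summaries$t_n_mean,
    t_n_max = summaries$t_n_max,
    stringsAsFactors = FALSE
  )
  attr(out, "reference") <- ref
  # largest individual envelope stress over the chambers, both conventions
  attr(out, "disparity_vs_reference_mean") <- max(summaries$t_n_max)
  attr(out, "disparity_vs_reference_min") <-
    max(summaries$gsf_max) / summaries$gsf_min[ref_idx]
  out
}

#' Render a chamber stress report
#'
#' Emits the per-chamber analysis as an aligned text table (shape model,
#' shape coefficient, thinness ratio, GSF, normalized stress, all at one
#' decimal), as CSV, or as JSON. The JSON form carries the full-precision
#' columns and round-trips to the same summaries.
#'
#' @param summaries A normalized summary `data.frame` from
#'   [normalize_stress()].
#' @param format `"table"`, `"csv"`, or `"json"`.
#' @return A character vector of report lines (`"table"`, `"csv"`) or a JSON
#'   string (`"json"`).
#' @examples
#' rep <- build_report(normalize_stress(summarize_chambers(toadfish_fixture())))
#' cat(rep, sep = "\n")
#' @export
build_report <- function(summaries, format = c("table", "csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) == 0L) stop("validation error: empty summary collection")
  if (!("t_n_mean" %in% names(summaries))) {
    stop("build_report requires normalized summaries; run normalize_stress() first")
  }
  if (format == "json") {
    payload <- list(reference = attr(summaries, "reference"),
                    summaries = as.data.frame(summaries))
    return(jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                            digits = NA))
  }
  if (format == "csv") {
    con <- textConnection("csv_lines", "w", local = TRUE)
    utils::write.csv(as.data.frame(summaries), con, row.names = FALSE)
    close(con)
    return(csv_lines)
  }
  hdr <- sprintf("%-16s %-10s %5s %6s %6s %6s", "chamber", "shape", "s",
                 "r/w", "GSF", "t_n")
  rows <- sprintf("%-16s %-10s %5.1f %6.1f %6.1f %6.1f",
                  summaries$chamber, summaries$shape_model,
                  round1(summaries$s), round1(summaries$thinness_mean),
                  round1(summaries$gsf_mean), summaries$t_n_mean_display)
  c(hdr, rows,
    sprintf("(normalized to reference chamber: %s)", attr(summaries, "reference")))
}
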