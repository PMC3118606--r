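#' A single chamber's morphometric record
#'
#' One membranous chamber's wall-thickness and radius-of-curvature summary
#' (mean with individual max/min, microns) together with the shape model used
#' to emulate it: `cylinder`, `sphere`, `ellipsoid` (requires semi-axes
#' `a`, `b`) or `torus` (requires `r_tube`, `R_loop`).
#'
#' @param name Chamber label (unique within a set).
#' @param shape_model One of `"cylinder"`, `"sphere"`, `"ellipsoid"`,
#'   `"torus"`.
#' @param w_mean,w_max,w_min Wall thickness statistics, microns;
#'   `0 < w_min <= w_mean <= w_max`.
#' @param r_mean,r_max,r_min Radius-of-curvature statistics, microns;
#'   `0 < r_min <= r_mean <= r_max`.
#' @param a,b Ellipsoid semi-axes, microns (ellipsoid model only; `b` may be
#'   `Inf`).
#' @param r_tube,R_loop Torus tube and loop radii, microns (torus model
#'   only).
#' @return An object of class `chamber_measurement`.
#' @examples
#' chamber_measurement("Anterior Canal", "cylinder",
#'                     w_mean = 70, w_max = 86, w_min = 45,
#'                     r_mean = 307, r_max = 322, r_min = 270)
#' @export
chamber_measurement <- function(name, shape_model,
                                w_mean, w_max, w_min,
                                r_mean, r_max, r_min,
                                a = NA_real_, b = NA_real_,
                                r_tube = NA_real_, R_loop = NA_real_) {
  m <- structure(
    list(name = as.character(name), shape_model = as.character(shape_model),
         w_mean = as.numeric(w_mean), w_max = as.numeric(w_max),
         w_min = as.numeric(w_min),
         r_mean = as.numeric(r_mean), r_max = as.numeric(r_max),
         r_min = as.numeric(r_min),
         a = as.numeric(a), b = as.numeric(b),
         r_tube = as.numeric(r_tube), R_loop = as.numeric(R_loop)),
    class = "chamber_measurement")
  validate_chamber_measurement(m)
  m
}

validate_chamber_measurement <- function(m) {
  nm <- m$name
  if (is.na(nm) || !nzchar(nm)) stop("validation error: chamber name must be non-empty")
  shapes <- c("cylinder", "sphere", "ellipsoid", "torus")
  if (!(m$shape_model %in% shapes)) {
    stop(sprintf("validation error: chamber '%s': shape_model must be one of %s",
                 nm, paste(shapes, collapse = ", ")))
  }
  chk_triplet <- function(mean, max, min, field) {
    v <- c(mean, max, min)
    if (any(is.na(v)) || any(v <= 0)) {
      stop(sprintf("validation error: chamber '%s': field '%s' statistics must be positive",
                   nm, field))
    }
    if (!(min <= mean && mean <= max)) {
      stop(sprintf("validation error: chamber '%s': field '%s' must satisfy min <= mean <= max",
                   nm, field))
    }
  }
  chk_triplet(m$w_mean, m$w_max, m$w_min, "w")
  chk_triplet(m$r_mean, m$r_max, m$r_min, "r")
  if (m$shape_model == "ellipsoid") {
    if (is.na(m$a) || is.na(m$b)) {
      stop(sprintf("validation error: chamber '%s': ellipsoid model requires fields 'a' and 'b'", nm))
    }
    ellipsoid_geometry(m$a, m$b)  # reuses geometry invariants
  }
  if (m$shape_model == "torus") {
    if (is.na(m$r_tube) || is.na(m$R_loop)) {
      stop(sprintf("validation error: chamber '%s': torus model requires fields 'r_tube' and 'R_loop'", nm))
    }
    torus_geometry(m$r_tube, m$R_loop)
  }
  invisible(m)
}

#' An ordered, validated collection of chamber measurements
#'
#' @param chambers A list of [chamber_measurement()] objects with unique
#'   names; order is preserved.
#' @param provenance Free-text note on the data source.
#' @return An object of class `measurement_set`.
#' @examples
#' measurement_set(list(
#'   chamber_measurement("Utricle", "cylinder", 32, 42, 20, 556, 654, 469)
#' ), provenance = "example")
#' @export
measurement_set <- function(chambers, provenance = "") {
  if (!is.list(chambers) || length(chambers) == 0L) {
    stop("validation error: a measurement set must contain at least one chamber")
  }
  for (m in chambers) {
    if (!inherits(m, "chamber_measurement")) {
      stop("validation error: every element must be a chamber_measurement")
    }
    validate_chamber_measurement(m)
  }
  nms <- vapply(chambers, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("validation error: chamber names must be unique; duplicated: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  structure(list(chambers = chambers, provenance = as.character(provenance)),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set> %d chambers\n", length(x$chambers)))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}

measurement_columns <- c("chamber", "shape_model",
                         "w_mean", "w_max", "w_min",
                         "r_mean", "r_max", "r_min",
                         "a", "b", "r_tube", "R_loop")

#' @export
as.data.frame.measurement_set <- function(x, ...) {
  rows <- lapply(x$chambers, function(m) {
    data.frame(chamber = m$name, shape_model = m$shape_model,
               w_mean = m$w_mean, w_max = m$w_max, w_min = m$w_min,
               r_mean = m$r_mean, r_max = m$r_max, r_min = m$r_min,
               a = m$a, b = m$b, r_tube = m$r_tube, R_loop = m$R_loop,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

measurement_set_from_df <- function(df, provenance = "") {
  missing <- setdiff(measurement_columns, names(df))
  if (length(missing)) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    stop("validation error: a measurement set must contain at least one chamber")
  }
  chambers <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    chamber_measurement(r$chamber, r$shape_model,
                        r$w_mean, r$w_max, r$w_min,
                        r$r_mean, r$r_max, r$r_min,
                        a = r$a, b = r$b, r_tube = r$r_tube, R_loop = r$R_loop)
  })
  measurement_set(chambers, provenance = provenance)
}

#' Built-in toadfish labyrinth measurements
#'
#' The surgical morphometry of the Oyster toadfish (*Opsanus tau*)
#' vestibular labyrinth: mean wall thickness and radius of curvature, with
#' individual maxima and minima, for the anterior semicircular canal
#' (modelled as a cylinder), the lateral ampulla (sphere), and the utricle
#' (cylinder, measured at its narrowest point). Values are in microns and
#' summarize 12-25 measurements from 3-5 live fish.
#'
#' A copy of the same table ships as a CSV at
#' `system.file("extdata", "toadfish_morphometry.csv", package = "vestress")`.
#'
#' @return A [measurement_set()] with three chambers.
#' @examples
#' toadfish_fixture()
#' @export
toadfish_fixture <- function() {
  measurement_set(
    list(
      chamber_measurement("Anterior Canal", "cylinder",
                          w_mean = 70, w_max = 86, w_min = 45,
                          r_mean = 307, r_max = 322, r_min = 270),
      chamber_measurement("Lateral Ampulla", "sphere",
                          w_mean = 58, w_max = 75, w_min = 44,
                          r_mean = 697, r_max = 788, r_min = 625),
      chamber_measurement("Utricle", "cylinder",
                          w_mean = 32, w_max = 42, w_min = 20,
                          r_mean = 556, r_max = 654, r_min = 469)
    ),
    provenance = paste("Live surgical measurements of the Oyster toadfish labyrinth;",
                       "means of 12-25 measurements from 3-5 fish with individual",
                       "max/min; utricle measured at its narrowest point.")
  )
}

fmt_num <- function(x) {
  ifelse(is.na(x), "", format(x, digits = 17, scientific = FALSE, trim = TRUE))
}

#' Read chamber measurements from CSV or JSON
#'
#' CSV files must carry the header
#' `chamber,shape_model,w_mean,w_max,w_min,r_mean,r_max,r_min,a,b,r_tube,R_loop`
#' with blank cells for inapplicable geometry fields; JSON files mirror the
#' same field names. The format is inferred from the file extension unless
#' given explicitly.
#'
#' @param path Path to an existing file.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @return A validated [measurement_set()]; row order preserved.
#' @examples
#' csv <- system.file("extdata", "toadfish_morphometry.csv", package = "vestress")
#' read_measurements(csv)
#' @export
read_measurements <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(obj$chambers, stringsAsFactors = FALSE)
    for (col in setdiff(measurement_columns, c("chamber", "shape_model"))) {
      if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
    }
    return(measurement_set_from_df(df, provenance = obj$provenance %||% ""))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  prov <- ""
  is_comment <- grepl("^#", lines)
  pline <- grep("^# provenance: ", lines, value = TRUE)
  if (length(pline)) prov <- sub("^# provenance: ", "", pline[[1]])
  body <- lines[!is_comment]
  if (length(body) == 0L) stop("validation error: empty file: ", path)
  df <- utils::read.csv(text = body, colClasses = "character", check.names = FALSE)
  missing <- setdiff(measurement_columns, names(df))
  if (length(missing)) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in setdiff(measurement_columns, c("chamber", "shape_model"))) {
    v <- df[[col]]
    v[!nzchar(v)] <- NA_character_
    df[[col]] <- as.numeric(v)
  }
  measurement_set_from_df(df, provenance = prov)
}

#' Write chamber measurements to CSV or JSON
#'
#' The inverse of [read_measurements()]; the round trip is lossless (numbers
#' are written at full double precision).
#'
#' @param set A [measurement_set()].
#' @param path Output path.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_measurements(toadfish_fixture(), f)
#' @export
write_measurements <- function(set, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(set, "measurement_set"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- list(provenance = set$provenance,
                chambers = as.data.frame(set))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(path))
  }
  df <- as.data.frame(set)
  out <- df
  for (col in setdiff(measurement_columns, c("chamber", "shape_model"))) {
    out[[col]] <- fmt_num(df[[col]])
  }
  con <- textConnection("csv_body", "w", local = TRUE)
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  close(con)
  header <- if (nzchar(set$provenance)) {
    paste0("# provenance: ", gsub("[\r\n]+", " ", set$provenance))
  } else character(0)
  writeLines(c(header, csv_body), path, useBytes = FALSE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
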