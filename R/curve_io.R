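#' Raw tensile test record
#'
#' Holds the samples of one tensile test before conversion to stress-strain:
#' either displacement (mm) vs force (N) or strain (mm/mm) vs stress (MPa).
#'
#' @param x first column: displacement in mm, or strain (dimensionless).
#' @param y second column: force in N, or stress in MPa.
#' @param sample_kind `"force_displacement"` or `"stress_strain"`.
#' @param specimen_id character scalar.
#' @param gauge_length_mm gauge length, used only to scale the monotonicity
#'   jitter tolerance for displacement records (default 1).
#'
#' @details At least 10 samples are required. Displacement/strain must be
#'   non-decreasing up to a jitter tolerance of 1e-9 of the gauge length;
#'   larger reversals are rejected. Force/stress must be finite and the
#'   first sample non-negative.
#'
#' @return An object of class `tensile_record`.
#' @export
tensile_record <- function(x, y,
                           sample_kind = c("force_displacement", "stress_strain"),
                           specimen_id = "specimen",
                           gauge_length_mm = 1) {
  sample_kind <- match.arg(sample_kind)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("columns must have equal length")
  if (length(x) < 10) stop("a tensile record needs at least 10 samples")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("samples must be finite")
  }
  tol <- 1e-9 * if (sample_kind == "force_displacement") gauge_length_mm else 1
  if (any(diff(x) < -tol)) {
    stop(sprintf("%s must be non-decreasing (reversal beyond jitter tolerance at sample %d)",
                 if (sample_kind == "force_displacement") "displacement" else "strain",
                 which(diff(x) < -tol)[1] + 1L))
  }
  x <- cummax(x)  # absorb sub-tolerance sensor jitter
  if (y[1] < 0) stop("first force/stress sample must be non-negative")
  structure(
    list(specimen_id = as.character(specimen_id)[1],
         x = x, y = y, sample_kind = sample_kind),
    class = "tensile_record"
  )
}

#' @export
print.tensile_record <- function(x, ...) {
  lab <- if (x$sample_kind == "force_displacement") {
    c("displacement [mm]", "force [N]")
  } else c("strain [-]", "stress [MPa]")
  cat(sprintf("Tensile record '%s': %d samples of %s vs %s\n",
              x$specimen_id, length(x$x), lab[1], lab[2]))
  invisible(x)
}

# Recognised header names -> (kind, column role). Units are mandatory: a file
# whose header is not one of these pairs is rejected rather than guessed at.
.known_headers <- list(
  force_displacement = c("displacement_mm", "force_N"),
  stress_strain      = c("strain", "stress_MPa")
)

#' Read a raw tensile record from delimited text
#'
#' Reads a two-column comma- or tab-delimited file with one mandatory header
#' line declaring the column names and units: either
#' `displacement_mm,force_N` or `strain,stress_MPa`. Units are taken from
#' the header; there is no silent unit inference.
#'
#' @param path file path.
#' @param delim field delimiter; `NULL` (default) auto-detects `,` vs tab
#'   from the header line.
#' @param specimen_id id for the record; defaults to the file name without
#'   extension.
#' @param gauge_length_mm passed to [tensile_record()] for the jitter
#'   tolerance.
#' @return A [tensile_record()].
#' @export
read_tensile_record <- function(path, delim = NULL, specimen_id = NULL,
                                gauge_length_mm = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(delim)) delim <- if (grepl("\t", header)) "\t" else ","
  cols <- trimws(strsplit(header, delim, fixed = TRUE)[[1]])
  kind <- NULL
  for (k in names(.known_headers)) {
    if (length(cols) == 2 && all(cols == .known_headers[[k]])) kind <- k
  }
  if (is.null(kind)) {
    stop("unrecognised header '", header,
         "'; expected 'displacement_mm,force_N' or 'strain,stress_MPa' ",
         "(units are mandatory)")
  }
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delim,
                      colClasses = "character", strip.white = TRUE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  dat <- as.data.frame(lapply(raw, function(col) {
    suppressWarnings(as.numeric(col))
  }))
  bad <- which(!stats::complete.cases(dat))
  if (length(bad)) {
    stop("malformed row at line ", bad[1] + 1L, " of ", path)
  }
  if (is.null(specimen_id)) {
    specimen_id <- sub("\\.[^.]*$", "", basename(path))
  }
  tensile_record(dat[[1]], dat[[2]], sample_kind = kind,
                 specimen_id = specimen_id,
                 gauge_length_mm = gauge_length_mm)
}

#' Write a raw tensile record as delimited text
#'
#' Emits the two-column dialect read by [read_tensile_record()], with the
#' unit-bearing header line.
#'
#' @param record a [tensile_record()].
#' @param path output file path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_tensile_record <- function(record, path, delim = ",") {
  stopifnot(inherits(record, "tensile_record"))
  hdr <- .known_headers[[record$sample_kind]]
  df <- data.frame(record$x, record$y)
  names(df) <- hdr
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write fitted-parameter and indicator results
#'
#' Writes one machine-readable JSON document carrying every fitted parameter
#' at full precision, and one flat delimited summary table with a stable
#' column set covering all reported model symbols and mechanical indicators.
#'
#' @param fits a list of `composite_fit` objects (possibly empty).
#' @param indicators optional data frame of mechanical indicators, one row
#'   per specimen (as returned by [extract_indicators()] rows bound
#'   together).
#' @param dir output directory; created if missing.
#' @return invisibly, a list with the paths written (`json`, `csv`).
#' @export
write_results <- function(fits, indicators = NULL, dir = ".") {
  if (length(fits) == 0 && is.null(indicators)) {
    stop("nothing to write: no fits and no indicators")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(fits, report_table)
  tab <- flat_bind(rows)
  payload <- list(
    fits = lapply(fits, unclass_fit),
    indicators = indicators
  )
  json_path <- file.path(dir, "results.json")
  csv_path <- file.path(dir, "summary.csv")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  utils::write.csv(format(tab, digits = 17, trim = TRUE), csv_path,
                   row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(indicators)) {
    ind_path <- file.path(dir, "indicators.csv")
    utils::write.csv(format(indicators, digits = 17, trim = TRUE), ind_path,
                     row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(list(json = json_path, csv = csv_path))
}

#' Read back a results document
#'
#' Parses the JSON document written by [write_results()]; numeric fields are
#' restored at full stored precision.
#'
#' @param path path to `results.json` or to the directory holding it.
#' @return the parsed list (`fits`, `indicators`).
#' @export
read_results <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "results.json")
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

# internal: strip classes recursively so jsonlite serialises plainly
unclass_fit <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_fit)
  } else {
    x
  }
}

# internal: rbind named numeric rows with differing column sets into one
# data frame with a stable, first-seen column order
flat_bind <- function(rows) {
  if (length(rows) == 0) return(data.frame())
  cols <- unique(unlist(lapply(rows, names)))
  out <- lapply(cols, function(cn) {
    vapply(rows, function(r) {
      v <- r[[cn]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  })
  names(out) <- cols
  id <- vapply(rows, function(r) {
    v <- attr(r, "specimen_id")
    if (is.null(v)) NA_character_ else v
  }, character(1))
  cbind(data.frame(specimen_id = id, stringsAsFactors = FALSE),
        as.data.frame(out, check.names = FALSE))
}
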