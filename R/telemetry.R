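#' Construct a telemetry track
#'
#' A telemetry track holds the irregular, noisy location fixes for one animal:
#' times in hours and planar (projected) coordinates in kilometres. An optional
#' per-fix error class (e.g. Argos location class) scales the observation-error
#' standard deviation during path imputation, and an optional subgroup label
#' (sex, tagging year, ...) is carried through to population-level analyses.
#'
#' @param id animal identifier (coerced to character).
#' @param times numeric vector of fix times in hours, strictly increasing.
#' @param x,y numeric vectors of planar coordinates in km.
#' @param error_class optional character/factor vector, one entry per fix.
#' @param group optional single subgroup label for the animal.
#' @return An object of class `telemetry_track`.
#' @export
telemetry_track <- function(id, times, x, y, error_class = NULL, group = NULL) {
  id <- as.character(id)[1L]
  times <- as.numeric(times)
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(times)
  if (n < 2L) stop("a telemetry track needs at least 2 fixes, got ", n)
  if (length(x) != n || length(y) != n)
    stop("times, x and y must have equal length")
  if (!all(is.finite(times)) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in telemetry track '", id, "'")
  d <- diff(times)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L] + 1L
    if (d[bad - 1L] == 0)
      stop("duplicate timestamp in track '", id, "' at row ", bad,
           " (time = ", times[bad], ")")
    stop("times not strictly increasing in track '", id, "' at row ", bad)
  }
  if (!is.null(error_class)) {
    error_class <- as.character(error_class)
    if (length(error_class) != n) stop("error_class must have one entry per fix")
  }
  structure(
    list(id = id, times = times, x = x, y = y,
         error_class = error_class, group = if (is.null(group)) NA_character_ else as.character(group)[1L]),
    class = "telemetry_track")
}

#' @export
print.telemetry_track <- function(x, ...) {
  cat("Telemetry track '", x$id, "': ", length(x$times), " fixes over ",
      round(diff(range(x$times)), 2), " h\n", sep = "")
  cat("  x range [", round(min(x$x), 2), ", ", round(max(x$x), 2),
      "] km;  y range [", round(min(x$y), 2), ", ", round(max(x$y), 2), "] km\n", sep = "")
  if (!is.na(x$group)) cat("  group:", x$group, "\n")
  invisible(x)
}

#' @export
length.telemetry_track <- function(x) length(x$times)

#' Read telemetry tracks from a delimited file
#'
#' Reads a CSV with one row per fix and returns one `telemetry_track` per
#' animal id. Rows are sorted by time within animal; duplicated timestamps
#' within an animal are an error (the offending row is named).
#'
#' @param path path to a delimited text file.
#' @param schema named character vector mapping the roles
#'   `id,time,x,y,error_class,group` to column names in the file. Only the
#'   first four are required.
#' @param sep field separator, default comma.
#' @return named list of `telemetry_track` objects, one per animal id.
#' @export
read_telemetry <- function(path,
                           schema = c(id = "id", time = "time", x = "x", y = "y",
                                      error_class = "error_class", group = "group"),
                           sep = ",") {
  if (!file.exists(path)) stop("telemetry file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  for (role in c("time", "x", "y")) {
    cn <- schema[[role]]
    if (!is.null(cn) && cn %in% names(df)) df[[cn]] <- as.numeric(df[[cn]])
  }
  need <- c("id", "time", "x", "y")
  for (role in need) {
    cn <- schema[[role]]
    if (is.null(cn) || !(cn %in% names(df)))
      stop("telemetry schema error: required column '", schema[[role]],
           "' (role '", role, "') not found in ", path)
  }
  has_ec <- !is.na(schema["error_class"]) && schema[["error_class"]] %in% names(df)
  has_gr <- !is.na(schema["group"]) && schema[["group"]] %in% names(df)
  ids <- as.character(df[[schema[["id"]]]])
  out <- list()
  for (a in unique(ids)) {
    rows <- which(ids == a)
    o <- order(df[[schema[["time"]]]][rows])
    rows <- rows[o]
    out[[a]] <- telemetry_track(
      id = a,
      times = df[[schema[["time"]]]][rows],
      x = df[[schema[["x"]]]][rows],
      y = df[[schema[["y"]]]][rows],
      error_class = if (has_ec) df[[schema[["error_class"]]]][rows] else NULL,
      group = if (has_gr) df[[schema[["group"]]]][rows][1L] else NULL)
  }
  out
}

#' Write telemetry tracks to CSV
#'
#' Inverse of [read_telemetry()]; values round-trip at full double precision.
#'
#' @param tracks a `telemetry_track` or list of them.
#' @param path output file path.
#' @export
write_telemetry <- function(tracks, path) {
  if (inherits(tracks, "telemetry_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    data.frame(id = tr$id, time = tr$times, x = tr$x, y = tr$y,
               error_class = if (is.null(tr$error_class)) NA_character_ else tr$error_class,
               group = tr$group, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
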