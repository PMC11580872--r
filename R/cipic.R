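#' CIPIC-layout HRIR files
#'
#' The CIPIC HRTF database stores, per subject, two arrays `hrir_l` and
#' `hrir_r` of dimension azimuth x elevation x time, on a fixed interaural-
#' polar grid of 25 azimuths (-80..80 degrees, negative = left) and 50
#' elevations (-45 + 5.625 * (0:49) degrees), sampled at 44.1 kHz. The native
#' distribution is a MATLAB binary; this package serializes the same layout
#' (field names, array shapes, grids) as JSON so fixtures stay plain text.
#' [read_cipic_hrir()] extracts the horizontal-plane (elevation 0) slice and
#' converts it to this package's convention (degrees, 0 = front, positive =
#' right, which CIPIC's interaural-polar azimuth already follows).
#'
#' @param x an `hrir_set` to serialize. The set is written as the elevation-0
#'   row of a CIPIC-shaped array; other elevations are zero-filled.
#' @param path file to write / read.
#' @param elevations elevation grid to embed (default the CIPIC 50-point
#'   grid).
#' @return `write_cipic_hrir()` returns `path` invisibly;
#'   `read_cipic_hrir()` returns an `hrir_set`.
#' @name cipic
NULL

cipic_elevation_grid <- function() -45 + 5.625 * (0:49)

#' @rdname cipic
#' @export
write_cipic_hrir <- function(x, path, elevations = cipic_elevation_grid()) {
  stopifnot(inherits(x, "hrir_set"))
  n_az <- length(x$azimuths)
  n_el <- length(elevations)
  n_t <- ncol(x$left)
  shape <- function(m) {
    a <- array(0, dim = c(n_az, n_el, n_t))
    iel <- which(abs(elevations) < 1e-9)[1]
    if (is.na(iel)) stop("elevation grid must contain 0")
    a[, iel, ] <- m
    a
  }
  obj <- list(
    name = "cipic_subject",
    subject_id = x$subject_id,
    sample_rate = x$sample_rate,
    azimuths = x$azimuths,
    elevations = elevations,
    hrir_l = shape(x$left),
    hrir_r = shape(x$right)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname cipic
#' @param subject_id identifier to assign; defaults to the one stored in the
#'   file.
#' @export
read_cipic_hrir <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("sample_rate", "azimuths", "elevations", "hrir_l", "hrir_r")) {
    if (is.null(obj[[field]])) {
      stop("malformed CIPIC layout: missing field '", field, "'")
    }
  }
  for (ear in c("hrir_l", "hrir_r")) {
    d <- dim(obj[[ear]])
    if (length(d) != 3 || d[1] != length(obj$azimuths) ||
      d[2] != length(obj$elevations)) {
      stop(
        "malformed CIPIC layout: '", ear,
        "' is not an azimuth x elevation x time array"
      )
    }
  }
  iel <- which(abs(obj$elevations) < 1e-9)
  if (length(iel) != 1) {
    stop("malformed CIPIC layout: no elevation-0 slice in 'elevations'")
  }
  slice <- function(a) {
    s <- a[, iel, , drop = FALSE]
    matrix(s, nrow = dim(a)[1], ncol = dim(a)[3])
  }
  new_hrir_set(
    subject_id = subject_id %||% obj$subject_id %||% basename(path),
    sample_rate = obj$sample_rate,
    azimuths = obj$azimuths,
    left = slice(obj$hrir_l),
    right = slice(obj$hrir_r)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
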