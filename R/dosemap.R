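## 2D dose maps on a regular pixel grid, centered on the beam axis.

#' Construct a dose map
#'
#' @param values numeric matrix of doses in Gy (non-negative); rows index
#'   x, columns index y, origin at the grid center.
#' @param pixel_um pixel size in um (default 250).
#' @param z_mm optional plane position for bookkeeping.
#' @return an object of class `dose_map`.
#' @export
dose_map <- function(values, pixel_um = 250, z_mm = NA_real_) {
  stopifnot(is.matrix(values), pixel_um > 0)
  if (any(values < 0)) stop("dose values must be non-negative")
  structure(list(values = values, pixel_um = pixel_um, z_mm = z_mm),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %d x %d pixels of %g um; max %.4g Gy\n",
              nrow(x$values), ncol(x$values), x$pixel_um, max(x$values)))
  invisible(x)
}

## pixel center coordinates (mm) along one axis
.pixel_centers <- function(n, pixel_um) {
  (seq_len(n) - (n + 1) / 2) * pixel_um / 1000
}

#' Mean dose over a centered circular region of interest
#'
#' Averages pixels whose centers fall within the disc of the given
#' diameter, centered on the beam axis.
#'
#' @param map a [dose_map].
#' @param diameter_mm ROI diameter in mm.
#' @return mean dose in Gy.
#' @export
roi_dose <- function(map, diameter_mm) {
  cx <- .pixel_centers(nrow(map$values), map$pixel_um)
  cy <- .pixel_centers(ncol(map$values), map$pixel_um)
  r2 <- outer(cx^2, cy^2, `+`)
  sel <- r2 <= (diameter_mm / 2)^2
  if (!any(sel)) stop("ROI contains no pixel centers")
  mean(map$values[sel])
}

#' Write / read a dose map as a CSV matrix with a JSON sidecar
#'
#' The CSV holds the raw pixel matrix (no headers); the sidecar records
#' pixel size, plane position and units so a map round-trips losslessly.
#'
#' @param map a [dose_map].
#' @param path CSV file path; the sidecar is `<path>.json`.
#' @return `read_dose_map()` returns a [dose_map].
#' @export
write_dose_map <- function(map, path) {
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(pixel_um = map$pixel_um, z_mm = map$z_mm,
                            units = "Gy"),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dose_map
#' @export
read_dose_map <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(v) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"))
  dose_map(v, pixel_um = side$pixel_um,
           z_mm = if (is.null(side$z_mm)) NA_real_ else side$z_mm)
}
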