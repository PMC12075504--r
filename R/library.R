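## Dose-per-unit-charge libraries: one Monte Carlo transport entry per
## spectral temperature on a grid, plus summary accessors.

#' Build a dose-per-charge library over a temperature grid
#'
#' Runs [mc_transport] once per spectral temperature and collects the
#' entries into a `dose_library`.  Each temperature uses a seed derived
#' deterministically from `seed`.
#'
#' @param line a [beamline_config].
#' @param stack list of [slab]s at the irradiation plane.
#' @param temperatures spectral temperature grid in MeV (default 1:5).
#' @param n_primaries primaries per temperature (default 2e5).
#' @param seed integer base seed.
#' @param keep_maps retain full 2D dose maps (memory-heavy).
#' @param ... further arguments passed to [mc_transport].
#' @return an object of class `dose_library`.
#' @export
build_dose_library <- function(line, stack, temperatures = 1:5,
                               n_primaries = 2e5, seed = 1,
                               keep_maps = FALSE, ...) {
  entries <- lapply(seq_along(temperatures), function(i) {
    sp <- exponential_spectrum(Q0_star = 1, E0 = temperatures[i])
    mc_transport(sp, line, stack, n_primaries = n_primaries,
                 seed = seed + i, keep_maps = keep_maps, ...)
  })
  names(entries) <- as.character(temperatures)
  structure(list(entries = entries, temperatures = temperatures,
                 line = line, stack = stack, seed = seed,
                 n_primaries = n_primaries),
            class = "dose_library")
}

#' @export
print.dose_library <- function(x, ...) {
  cat(sprintf("<dose_library> %d temperatures (%s MeV), %g primaries each\n",
              length(x$temperatures),
              paste(x$temperatures, collapse = ", "), x$n_primaries))
  invisible(x)
}

#' Fetch a library entry by temperature
#'
#' @param library a `dose_library`.
#' @param E0 temperature in MeV (must be on the grid).
#' @return a `dose_library_entry`.
#' @export
library_entry <- function(library, E0) {
  i <- match(E0, library$temperatures)
  if (is.na(i)) stop("temperature ", E0, " not on the library grid")
  library$entries[[i]]
}

#' Transport efficiency of a library entry
#'
#' Charge fraction of the source prefactor `Q0*` arriving at the sample
#' plane within the region of interest.
#'
#' @param entry a `dose_library_entry`.
#' @return dimensionless value in [0, 1].
#' @export
transport_efficiency <- function(entry) entry$efficiency

#' Depth-dose profile of a library entry
#'
#' Collects the ROI doses of the water sub-layer planes (labels starting
#' with "water") in depth order and reports the profile together with
#' its relative error (standard deviation over mean across depth).
#'
#' @param entry a `dose_library_entry`.
#' @return list with `depth_um`, `dose` (Gy/nC*) and `relative_error`.
#' @export
depth_dose_profile <- function(entry) {
  labs <- names(entry$planes)
  wl <- grep("^water", labs, value = TRUE)
  if (!length(wl)) stop("entry has no water sub-layer planes")
  depth <- as.numeric(sub("^water +([0-9.]+) um$", "\\1", wl))
  o <- order(depth)
  d <- vapply(entry$planes[wl[o]], `[[`, 0, "d_roi")
  rel <- if (length(d) > 1) stats::sd(d) / mean(d) else 0
  list(depth_um = depth[o], dose = unname(d), relative_error = rel)
}

#' Single-film summary table of a zebrafish-style library
#'
#' Per temperature: depth-averaged sample dose `d_avg`, front-film dose
#' `d_rcf`, their ratio, the depth-dose relative error, and the film
#' corrections (DWE, QCF) at the front film.  This is the table consumed
#' by the single-film weighted dose protocol.
#'
#' @param library a `dose_library` built on a stack with a front film and
#'   water sub-layers.
#' @param rcf_label label of the front film plane (default "RCF 1").
#' @return data.frame with one row per temperature.
#' @export
library_summary_table <- function(library, rcf_label = "RCF 1") {
  rows <- lapply(library$entries, function(en) {
    prof <- depth_dose_profile(en)
    rcf <- en$planes[[rcf_label]]
    if (is.null(rcf)) stop("no plane labelled '", rcf_label, "'")
    data.frame(E0 = en$E0,
               d_avg = mean(prof$dose),
               depth_error = prof$relative_error,
               d_rcf = rcf$d_roi,
               dose_ratio = mean(prof$dose) / rcf$d_roi,
               DWE = dwe(rcf$spectrum),
               QCF = qcf(rcf$spectrum))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble a single-film library from explicit per-temperature values
#'
#' Builds the minimal object needed by [single_film_dose] from already
#' tabulated quantities (for instance when the transport results come
#' from an external simulation).
#'
#' @param df data.frame with columns `E0`, `d_avg`, `d_rcf`,
#'   `depth_error`, `DWE`, `QCF`.
#' @return an object of class `single_film_table`.
#' @export
single_film_table <- function(df) {
  need <- c("E0", "d_avg", "d_rcf", "depth_error", "DWE", "QCF")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  structure(df[need], class = c("single_film_table", "data.frame"))
}

#' Persist a dose library as a directory of CSV maps plus an index JSON
#'
#' Writes each plane's ROI dose and spectral tally (CSV), optional dose
#' maps (CSV + sidecar), and an `index.json` with the grid, seeds, and
#' per-plane summaries.
#'
#' @param library a `dose_library`.
#' @param dir output directory (created if needed).
#' @return invisibly, the index path.
#' @export
write_dose_library <- function(library, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- list(temperatures = library$temperatures,
              n_primaries = library$n_primaries, seed = library$seed,
              entries = list())
  for (nm in names(library$entries)) {
    en <- library$entries[[nm]]
    ed <- file.path(dir, paste0("E0_", nm))
    dir.create(ed, showWarnings = FALSE)
    planes <- list()
    for (p in en$planes) {
      safe <- gsub("[^A-Za-z0-9_.-]", "_", p$label)
      utils::write.csv(p$spectrum, file.path(ed, paste0(safe, "_spectrum.csv")),
                       row.names = FALSE)
      if (!is.null(p$map))
        write_dose_map(p$map, file.path(ed, paste0(safe, "_map.csv")))
      planes[[p$label]] <- list(d_roi = p$d_roi)
    }
    idx$entries[[nm]] <- list(E0 = en$E0, seed = en$seed,
                              efficiency = en$efficiency, planes = planes)
  }
  path <- file.path(dir, "index.json")
  jsonlite::write_json(idx, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
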