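## Configuration files, reconstruction reports, and the command-line
## dispatcher.  Configs are YAML (or JSON, which yaml parses), reports
## are JSON; machine artifacts never go to stdout.

.run_config_keys <- c("preset", "stack", "temperatures", "n_primaries",
                      "seed", "roi_diameter_mm", "filter_dz_mm",
                      "filter_thickness_um", "output_dir")

#' Load and validate a run configuration
#'
#' Reads a YAML/JSON configuration, rejects unknown keys, fills defaults,
#' and resolves the beamline geometry and target stack.
#'
#' @param path configuration file.
#' @return an object of class `run_config` with elements `line` (a
#'   [beamline_config]), `stack` (list of [slab]s), `temperatures`,
#'   `n_primaries`, `seed`, `output_dir`, and the `resolved` list that is
#'   written back alongside every run.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .run_config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$preset)) stop("missing required field: preset")
  preset <- match.arg(cfg$preset, c("DE", "ZF"))
  line <- beamline_config(
    preset,
    filter_dz_mm = cfg$filter_dz_mm,
    filter_thickness_um = cfg$filter_thickness_um,
    roi_diameter_mm = cfg$roi_diameter_mm)
  stack_id <- if (is.null(cfg$stack)) {
    if (preset == "DE") "invitro" else "zebrafish"
  } else cfg$stack
  stack <- switch(stack_id,
                  invitro = stack_invitro(),
                  zebrafish = stack_zebrafish(),
                  stop("unknown stack id: ", stack_id))
  temps <- if (is.null(cfg$temperatures)) 1:5 else as.numeric(cfg$temperatures)
  if (any(diff(temps) <= 0)) stop("temperatures must be increasing")
  n_primaries <- if (is.null(cfg$n_primaries)) 2e5 else cfg$n_primaries
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  resolved <- list(preset = preset, stack = stack_id,
                   temperatures = temps, n_primaries = n_primaries,
                   seed = seed, roi_diameter_mm = line$roi_diameter_mm,
                   filter_dz_mm = line$filter_z_mm -
                     (line$q2$z_entrance + line$q2$length_mm),
                   filter_thickness_um = line$filter_thickness_um,
                   output_dir = cfg$output_dir)
  structure(list(line = line, stack = stack, temperatures = temps,
                 n_primaries = n_primaries, seed = seed,
                 output_dir = cfg$output_dir, resolved = resolved),
            class = "run_config")
}

#' Write a reconstruction report
#'
#' JSON report carrying the fitted parameters, the per-temperature
#' charge table (the dispersion-minimization curve), per-film
#' corrections, the seed and a content hash of the library.  Reports
#' round-trip losslessly through [read_report()].
#'
#' @param result a `reconstruction_result`.
#' @param path output JSON path.
#' @param library optional `dose_library` used for the fit (hashed).
#' @param seed seed recorded in the report.
#' @return invisibly, `path`.
#' @export
write_report <- function(result, path, library = NULL, seed = NULL) {
  lib_hash <- if (!is.null(library)) {
    d <- vapply(library$entries, function(en)
      sum(vapply(en$planes, `[[`, 0, "d_roi")), 0)
    sprintf("%08x", as.integer(sum(floor(d * 1e9)) %% 2147483647))
  } else NULL
  rep <- list(
    E0_fit = result$E0_fit, Q_bar_star = result$Q_bar_star,
    sigma_over_Q = result$sigma_over_Q, sample_dose = result$sample_dose,
    rejected = result$rejected, boundary = result$boundary,
    reason = result$reason,
    table = result$table, films = result$films,
    seed = seed, library_hash = lib_hash)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$table <- as.data.frame(rep$table)
  if (!is.null(rep$films)) rep$films <- as.data.frame(rep$films)
  rep
}
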