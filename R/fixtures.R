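## Synthetic fixtures: phantom shots, dose-map fixtures, and stacked-film
## calibration fixtures with known ground truth.  Every generator is pure
## given its seed and embeds the truth in its return value.

#' Generate a phantom shot with known source parameters
#'
#' Forward-simulates the plane doses at the true `(E0, Q0*)` from a dose
#' library, converts them to "measured readings" by inverting the
#' correction chain used in reconstruction (divide by plane QCF and the
#' calibration factor, multiply by plane DWE applied to the simulated
#' side), and applies multiplicative lognormal noise.  Reconstructing a
#' noiseless phantom round-trips to the truth.
#'
#' @param E0 true spectral temperature in MeV (on the library grid).
#' @param Q0_star true effective charge in nC*.
#' @param library a `dose_library`.
#' @param films labels of the film planes to read (default all "RCF"
#'   planes in the library).
#' @param noise_sigma lognormal sigma of the multiplicative reading noise
#'   (0.03 for film-reading error, 0.3 to mimic shot-to-shot spread).
#' @param seed integer seed.
#' @return list with `shot` (a [shot_record] of uncorrected readings) and
#'   `truth` (E0, Q0_star, noise_sigma, seed, noiseless readings).
#' @export
make_phantom_shot <- function(E0, Q0_star, library, films = NULL,
                              noise_sigma = 0, seed = 1) {
  stopifnot(noise_sigma >= 0, Q0_star > 0)
  entry <- library_entry(library, E0)
  if (is.null(films))
    films <- grep("^RCF", names(entry$planes), value = TRUE)
  if (!length(films)) stop("no film planes in the library entry")
  readings <- vapply(films, function(lab) {
    p <- entry$planes[[lab]]
    if (is.null(p) || p$d_roi <= 0)
      stop("no penetration to plane '", lab, "' at the truth temperature")
    d_read <- p$d_roi / dwe(p$spectrum)
    Q0_star * d_read / (qcf(p$spectrum) * (1 - 0.065))
  }, 0)
  names(readings) <- films
  set.seed(seed)
  noisy <- readings *
    stats::rlnorm(length(readings), meanlog = -noise_sigma^2 / 2,
                  sdlog = noise_sigma)
  preset <- if (!is.null(library$line$preset)) library$line$preset else "DE"
  list(shot = shot_record(noisy, preset = preset,
                          roi_diameter_mm = library$line$roi_diameter_mm),
       truth = list(E0 = E0, Q0_star = Q0_star, noise_sigma = noise_sigma,
                    seed = seed, noiseless = readings))
}

#' Generate a synthetic dose map
#'
#' Radially symmetric Gaussian (or flat) profile on the standard pixel
#' grid with optional multiplicative Gaussian noise.
#'
#' @param amplitude_gy peak (or flat) dose in Gy.
#' @param sigma_mm Gaussian transverse sigma in mm; `Inf` gives a flat
#'   map.
#' @param noise_sigma relative noise standard deviation.
#' @param seed integer seed.
#' @param extent_mm map extent (default 40).
#' @param pixel_um pixel size (default 250).
#' @return a [dose_map].
#' @export
make_dose_map_fixture <- function(amplitude_gy, sigma_mm = Inf,
                                  noise_sigma = 0, seed = 1,
                                  extent_mm = 40, pixel_um = 250) {
  n <- ceiling(extent_mm * 1000 / pixel_um)
  cx <- .pixel_centers(n, pixel_um)
  r2 <- outer(cx^2, cx^2, `+`)
  v <- if (is.infinite(sigma_mm)) matrix(amplitude_gy, n, n)
       else amplitude_gy * exp(-r2 / (2 * sigma_mm^2))
  if (noise_sigma > 0) {
    set.seed(seed)
    v <- v * matrix(pmax(stats::rnorm(n * n, 1, noise_sigma), 0), n, n)
  }
  dose_map(v, pixel_um)
}

#' Generate a stacked-film calibration fixture
#'
#' Forward-models the per-film doses of an HD810 spectrometry stack close
#' to the source for a known `(Q0, E0, E_cutoff)` and divergence model,
#' including divergence-driven geometric dilution, then applies optional
#' multiplicative lognormal noise and flags saturated films.
#'
#' @param Q0_nc true total source charge in nC.
#' @param E0 true spectral temperature in MeV.
#' @param E_cutoff spectral cutoff in MeV (default 19.6).
#' @param divergence a [divergence_model].
#' @param n_films number of films (>= 4; default 25).
#' @param z_mm source-to-stack distance (default 48).
#' @param noise_sigma lognormal reading noise.
#' @param saturation_gy saturation threshold (default 400).
#' @param seed integer seed.
#' @return list with `doses` (Gy per film), `saturated` (indices),
#'   `stack`, and `truth`.
#' @export
make_stack_fixture <- function(Q0_nc, E0, E_cutoff = 19.6,
                               divergence = divergence_model(),
                               n_films = 25, z_mm = 48, noise_sigma = 0,
                               saturation_gy = 400, seed = 1) {
  stopifnot(n_films >= 4)
  stack <- stack_hd810(n_films)
  doses <- .stack_forward_doses(Q0_nc, E0, stack, divergence, z_mm,
                                E_high = E_cutoff)
  if (noise_sigma > 0) {
    set.seed(seed)
    doses <- doses * stats::rlnorm(length(doses),
                                   meanlog = -noise_sigma^2 / 2,
                                   sdlog = noise_sigma)
  }
  list(doses = doses, saturated = which(doses >= saturation_gy),
       stack = stack,
       truth = list(Q0_nc = Q0_nc, E0 = E0, E_cutoff = E_cutoff,
                    noise_sigma = noise_sigma, seed = seed, z_mm = z_mm))
}
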