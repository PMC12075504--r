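# Independent oracles and shared fixtures for the test suite.

# Plain-text Bethe evaluation, coded independently of the package
# (simple maximum-energy-transfer approximation, adequate for protons
# below ~50 MeV).  Constants written out literally on purpose.
oracle_bethe_water <- function(energy_mev, I_ev = 78) {
  mp <- 938.27208816; me <- 0.51099895
  gamma <- 1 + energy_mev / mp
  beta2 <- 1 - 1 / gamma^2
  bg2 <- beta2 * gamma^2
  0.307075 * 0.555087 / beta2 *
    (log(2 * me * bg2 / (I_ev * 1e-6)) - beta2)
}

# Fine-step quadrature of 1/S for the proton range in water, independent
# of the package's cached tables.
oracle_range_water <- function(energy_mev, floor_mev = 0.50364) {
  e <- seq(floor_mev, energy_mev, length.out = 20000L)
  s <- oracle_bethe_water(e)
  sum(diff(e) * (1 / s[-1] + 1 / s[-length(s)]) / 2) +
    floor_mev / oracle_bethe_water(floor_mev)
}

# Shared Monte Carlo libraries, built once per test session.
.test_cache <- new.env()

de_library <- function() {
  if (is.null(.test_cache$de))
    .test_cache$de <- build_dose_library(beamline_config("DE"),
                                         stack_invitro(), 1:5,
                                         n_primaries = 2e5, seed = 1)
  .test_cache$de
}

zf_library <- function() {
  if (is.null(.test_cache$zf))
    .test_cache$zf <- build_dose_library(beamline_config("ZF"),
                                         stack_zebrafish(), 1:5,
                                         n_primaries = 2e5, seed = 1)
  .test_cache$zf
}

# A beamline with all optics and foils disabled: field-off quadrupoles
# with a wide bore and the window collapsed onto the irradiation plane,
# i.e. a pure vacuum drift.  Used for MC-vs-deterministic comparisons.
free_drift_line <- function(roi_mm = 30) {
  beamline_config(preset = NULL,
                  q1 = quadrupole(48, 40, 0, 1000, "x"),
                  q2 = quadrupole(108, 20, 0, 1000, "y"),
                  filter_dz_mm = 275, filter_thickness_um = 0,
                  window_z_mm = 827, window_thickness_um = 0,
                  plane_z_mm = 827, roi_diameter_mm = roi_mm)
}

# Near-monoenergetic pencil-beam spectrum.
pencil_spectrum <- function(energy = 10) {
  exponential_spectrum(Q0_star = 1, E0 = 1000, E_low = energy * 0.9999,
                       E_high = energy * 1.0001, theta_max = 1e-6)
}

# Minimal hand-built library for arithmetic-level reconstruction tests:
# plane doses are set directly and every plane has a single-bin spectrum
# (so QCF and DWE are simple closed forms).
fake_entry <- function(E0, d, sample_d = NULL, e_bin = 10) {
  planes <- lapply(names(d), function(lab) {
    list(label = lab, d_roi = d[[lab]], map = NULL,
         spectrum = data.frame(E_mid = e_bin, N = 100, D = d[[lab]] / 100))
  })
  names(planes) <- names(d)
  if (!is.null(sample_d))
    planes[["Sample"]] <- list(label = "Sample", d_roi = sample_d,
                               map = NULL,
                               spectrum = data.frame(E_mid = e_bin, N = 100,
                                                     D = sample_d / 100))
  structure(list(E0 = E0, planes = planes, n_primaries = 0, seed = 0,
                 efficiency = NA_real_, pixel_um = 250,
                 roi_diameter_mm = 10, empty = FALSE),
            class = "dose_library_entry")
}

fake_library <- function(entries) {
  temps <- vapply(entries, `[[`, 0, "E0")
  names(entries) <- as.character(temps)
  structure(list(entries = entries, temperatures = temps,
                 line = beamline_config("DE"), stack = list(),
                 seed = 0, n_primaries = 0),
            class = "dose_library")
}
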