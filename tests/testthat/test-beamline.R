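test_that("quadrupole transfer matrices are symplectic hard-edge optics", {
  q <- quadrupole(48, 40, 332)
  for (g in c(50, 332, 700)) for (e in c(1, 5, 19.5)) {
    qq <- quadrupole(48, 40, g)
    tm <- quad_transfer_matrix(qq, e)
    expect_lt(abs(det(tm$focusing) - 1), 1e-12)
    expect_lt(abs(det(tm$defocusing) - 1), 1e-12)
  }
  # zero gradient reduces to a drift
  tm0 <- quad_transfer_matrix(quadrupole(48, 40, 0), 5)
  expect_equal(tm0$focusing, matrix(c(1, 0, 40, 1), 2, 2))
  expect_equal(tm0$defocusing, tm0$focusing)
})

test_that("the thin-lens limit recovers the focal length 1/(k^2 L)", {
  e <- 8
  L <- 0.1                       # mm
  g <- 332 * 400                 # keep gL finite and strong
  tm <- quad_transfer_matrix(quadrupole(0, L, g), e)
  f_matrix <- -1 / tm$focusing[2, 1]
  f_thin <- 1 / (tm$k_mm^2 * L)
  # series expansion of the exact matrix: relative error (kL)^2/6
  expect_equal(f_matrix, f_thin, tolerance = 1e-3)
})

test_that("preset geometry matches the study configuration", {
  de <- beamline_config("DE")
  expect_equal(de$filter_z_mm, 128 + 275)
  expect_equal(de$filter_thickness_um, 70)
  expect_equal(de$roi_diameter_mm, 10)
  zf <- beamline_config("ZF")
  expect_equal(zf$filter_z_mm, 128 + 250)
  expect_equal(zf$filter_thickness_um, 50)
  expect_equal(zf$roi_diameter_mm, 5)
  expect_equal(de$window_z_mm, 772)
  expect_equal(de$plane_z_mm, 827)
  # acceptance half-angle of Q1's bore seen from the source
  expect_equal(acceptance_half_angle(de), atan(5 / 48) * 180 / pi)
})

test_that("ROI dose averages pixels inside the centered disc", {
  flat <- dose_map(matrix(3.5, 80, 80), 250)
  expect_equal(roi_dose(flat, 10), 3.5)
  # one-pixel ROI picks the central pixel
  m <- matrix(0, 81, 81); m[41, 41] <- 7
  expect_equal(roi_dose(dose_map(m, 250), 0.2), 7)
  # half-plane map averages to v/2 up to pixelization
  hp <- matrix(0, 160, 160); hp[1:80, ] <- 2
  expect_equal(roi_dose(dose_map(hp, 250), 20), 1, tolerance = 0.02)
  expect_error(roi_dose(dose_map(matrix(1, 4, 4), 250), 1e-9), "no pixel")
})

test_that("transport is bit-reproducible for a fixed seed", {
  line <- beamline_config("DE")
  st <- stack_invitro()
  sp <- exponential_spectrum(E0 = 3)
  a <- mc_transport(sp, line, st, n_primaries = 2e4, seed = 99)
  b <- mc_transport(sp, line, st, n_primaries = 2e4, seed = 99)
  expect_identical(a, b)
  c2 <- mc_transport(sp, line, st, n_primaries = 2e4, seed = 100)
  expect_false(identical(a$planes[["RCF 1"]]$d_roi,
                         c2$planes[["RCF 1"]]$d_roi))
})

test_that("quad-free pencil beam reproduces the deterministic Bragg curve", {
  line <- free_drift_line()
  slices <- lapply(1:60, function(i)
    slab("water", 25, label = sprintf("water %04.0f um", (i - 0.5) * 25),
         sensitive = TRUE))
  en <- mc_transport(pencil_spectrum(10), line, slices,
                     n_primaries = 1e5, seed = 3)
  prof <- depth_dose_profile(en)
  # deterministic 1D oracle: per-slab deposit of a single 10 MeV proton
  e <- 10
  dep <- numeric(60)
  for (i in 1:60) {
    e_out <- energy_after_slab("water", 25, e)
    dep[i] <- e - e_out
    e <- e_out
  }
  w <- en$truncation_fraction * 1e-9 / 1.602176634e-19 / 1e5
  roi_mass_kg <- pi * (15 * 0.1)^2 * 25e-4 * 1 * 1e-3   # 30 mm ROI disc
  oracle <- dep * 1e5 * w * 1.602176634e-13 / roi_mass_kg
  expect_equal(prof$dose, oracle, tolerance = 0.01)
  # Bragg peak near the expected 1.23 mm range
  expect_equal(prof$depth_um[which.max(prof$dose)], 1212.5,
               tolerance = 0.05)
})

test_that("moving the DE filter closer to the plane raises the ROI dose", {
  st <- stack_invitro()
  sp <- exponential_spectrum(E0 = 3)
  near <- mc_transport(sp, beamline_config("DE", filter_dz_mm = 150),
                       st, 5e4, seed = 4)
  far <- mc_transport(sp, beamline_config("DE", filter_dz_mm = 350),
                      st, 5e4, seed = 4)
  expect_gt(far$planes$Sample$d_roi, near$planes$Sample$d_roi)
})

test_that("shrinking the bore never increases any scored dose", {
  st <- stack_invitro()
  sp <- exponential_spectrum(E0 = 3)
  wide <- mc_transport(sp, beamline_config("DE"), st, 5e4, seed = 8)
  narrow_line <- beamline_config("DE",
                                 q1 = quadrupole(48, 40, 332, 3, "x"),
                                 q2 = quadrupole(108, 20, 322, 3, "y"))
  narrow <- mc_transport(sp, narrow_line, st, 5e4, seed = 8)
  for (lab in names(wide$planes))
    expect_lte(narrow$planes[[lab]]$d_roi, wide$planes[[lab]]$d_roi)
})

test_that("a fully absorbing filter yields a flagged empty result", {
  st <- stack_invitro()
  sp <- exponential_spectrum(E0 = 3)
  en <- mc_transport(sp, beamline_config("DE", filter_thickness_um = 5000),
                     st, 1e4, seed = 5)
  expect_true(en$empty)
  expect_equal(en$planes$Sample$d_roi, 0)
  expect_equal(transport_efficiency(en), 0)
})

test_that("transport efficiency is a charge fraction in [0, 1]", {
  en <- library_entry(de_library(), 3)
  eff <- transport_efficiency(en)
  expect_gte(eff, 0); expect_lte(eff, 1)
  # independent recount: arrivals at the sample ROI over primaries,
  # scaled by the spectral truncation fraction
  expect_equal(eff,
               en$n_in_roi_sample / en$n_primaries * en$truncation_fraction)
})

test_that("depth-dose degenerate cases give zero relative error", {
  one <- list(list(label = "water 0010 um", d_roi = 1, map = NULL,
                   spectrum = NULL))
  names(one) <- "water 0010 um"
  entry <- structure(list(E0 = 3, planes = one), class = "dose_library_entry")
  expect_equal(depth_dose_profile(entry)$relative_error, 0)
  # uniform synthetic deposition
  uni <- lapply(1:5, function(i)
    list(label = sprintf("water %04.0f um", i * 10), d_roi = 2, map = NULL))
  names(uni) <- vapply(uni, `[[`, "", "label")
  entry2 <- structure(list(E0 = 3, planes = uni),
                      class = "dose_library_entry")
  expect_equal(depth_dose_profile(entry2)$relative_error, 0)
})

test_that("dose maps round-trip through CSV with their sidecar", {
  dm <- make_dose_map_fixture(5, sigma_mm = 4, noise_sigma = 0.05,
                              seed = 2, extent_mm = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dose_map(dm, path)
  back <- read_dose_map(path)
  expect_equal(back$values, dm$values, tolerance = 1e-12)
  expect_equal(back$pixel_um, 250)
})
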