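test_that("perfectly proportional readings give zero charge dispersion", {
  lib <- fake_library(list(
    fake_entry(3, c("RCF 1" = 0.2, "RCF 2" = 0.15, "RCF 3" = 0.1),
               sample_d = 0.18)))
  d_read <- vapply(c("RCF 1", "RCF 2", "RCF 3"), function(lab) {
    p <- lib$entries[["3"]]$planes[[lab]]
    p$d_roi / dwe(p$spectrum)
  }, 0)
  shot <- shot_record(50 * d_read, corrected = TRUE)
  fit <- extrapolate_charge(shot, lib, 3)
  expect_equal(fit$Q_bar_star, 50)
  expect_equal(fit$sigma, 0)
})

test_that("the two-film hand example gives Qbar = 3 and sigma = sqrt(2)/2", {
  lib <- fake_library(list(
    fake_entry(3, c("RCF 1" = 0.4, "RCF 2" = 0.2), sample_d = 0.3)))
  dw <- vapply(c("RCF 1", "RCF 2"), function(lab) {
    p <- lib$entries[["3"]]$planes[[lab]]
    dwe(p$spectrum)
  }, 0)
  shot <- shot_record(c("RCF 1" = 2 * 0.4 / unname(dw[1]),
                        "RCF 2" = 4 * 0.2 / unname(dw[2])),
                      corrected = TRUE)
  fit <- extrapolate_charge(shot, lib, 3)
  expect_equal(fit$Q_bar_star, 3)
  # Eq. 3 puts 1/N outside the root: (1/2) sqrt(1 + 1)
  expect_equal(fit$sigma, sqrt(2) / 2)
})

test_that("single-film shots are routed away from charge extrapolation", {
  lib <- fake_library(list(fake_entry(3, c("RCF 1" = 0.2), sample_d = 0.1)))
  shot <- shot_record(c("RCF 1" = 5))
  expect_error(extrapolate_charge(shot, lib, 3), "single_film_dose")
})

test_that("noiseless phantoms round-trip to the grid truth", {
  lib <- de_library()
  for (e0 in c(2, 3, 4)) {
    ph <- make_phantom_shot(e0, 70, lib, noise_sigma = 0, seed = 21)
    # a truth of 2 MeV sits at the edge of the penetrating grid range and
    # legitimately carries a boundary warning
    fit <- suppressWarnings(fit_temperature(ph$shot, lib))
    expect_equal(fit$E0_fit, e0)
    expect_equal(fit$Q_bar_star, 70, tolerance = 1e-9)
  }
})

test_that("reconstruction is scale equivariant in the readings", {
  lib <- de_library()
  ph <- make_phantom_shot(3, 50, lib, noise_sigma = 0.05, seed = 31)
  f1 <- fit_temperature(ph$shot, lib)
  shot2 <- shot_record(ph$shot$doses * 4, preset = ph$shot$preset)
  f2 <- fit_temperature(shot2, lib)
  expect_equal(f2$E0_fit, f1$E0_fit)
  expect_equal(f2$Q_bar_star, 4 * f1$Q_bar_star)
  expect_equal(f2$sample_dose, 4 * f1$sample_dose)
  expect_equal(f2$sigma_over_Q, f1$sigma_over_Q)
})

test_that("ties break to the lowest temperature and monotone curves warn", {
  e1 <- fake_entry(2, c("RCF 1" = 0.2, "RCF 2" = 0.1), sample_d = 0.15)
  e2 <- fake_entry(3, c("RCF 1" = 0.4, "RCF 2" = 0.2), sample_d = 0.3)
  lib <- fake_library(list(e1, e2))
  dw <- dwe(e1$planes[["RCF 1"]]$spectrum)
  # readings proportional to both entries: sigma = 0 at both -> tie
  shot <- shot_record(c("RCF 1" = 0.2 / dw, "RCF 2" = 0.1 / dw),
                      corrected = TRUE)
  expect_warning(fit <- fit_temperature(shot, lib), "boundary")
  expect_equal(fit$E0_fit, 2)
})

test_that("shots that no temperature can penetrate are rejected", {
  e1 <- fake_entry(2, c("RCF 1" = 0.2, "RCF 3" = 0))
  lib <- fake_library(list(e1))
  shot <- shot_record(c("RCF 1" = 1, "RCF 3" = 1), corrected = TRUE)
  res <- fit_temperature(shot, lib)
  expect_true(res$rejected)
  expect_match(res$reason, "penetrate")
})

test_that("single-film dose reduces to one term under a delta weight", {
  tab <- single_film_table(data.frame(
    E0 = 1:5,
    d_avg = c(0.00236, 0.082, 0.251, 0.424, 0.561),
    d_rcf = c(0.0154, 0.15, 0.33, 0.49, 0.6),
    depth_error = c(0.575, 0.241, 0.132, 0.085, 0.0599),
    DWE = c(0.963, 0.970, 0.974, 0.976, 0.977),
    QCF = c(1.21, 1.19, 1.18, 1.17, 1.169)))
  w3 <- temperature_distribution(1:5, c(0, 0, 1, 0, 0))
  res <- single_film_dose(10, tab, w3)
  expect_equal(res$ratio, (0.251 / 0.33) * (1.18 / 0.974))
  expect_equal(res$sample_dose, 10 * res$ratio)
  expect_equal(res$relative_error, 0.132)
})

test_that("uniform weights reproduce the hand-computed weighted sum", {
  tab <- single_film_table(data.frame(
    E0 = 1:5,
    d_avg = c(0.16, 0.55, 0.77, 0.87, 0.94),   # ratio folded into d_avg
    d_rcf = rep(1, 5),
    depth_error = c(0.575, 0.241, 0.132, 0.085, 0.0599),
    DWE = c(0.963, 0.970, 0.974, 0.976, 0.977),
    QCF = c(1.21, 1.19, 1.18, 1.17, 1.169)))
  w <- temperature_distribution(1:5)
  res <- single_film_dose(12, tab, w)
  hand <- mean(c(0.16 * 1.21 / 0.963, 0.55 * 1.19 / 0.970,
                 0.77 * 1.18 / 0.974, 0.87 * 1.17 / 0.976,
                 0.94 * 1.169 / 0.977))
  expect_equal(res$ratio, hand)
  expect_equal(res$relative_error,
               mean(c(0.575, 0.241, 0.132, 0.085, 0.0599)))
  # zero reading: zero dose, unchanged error
  res0 <- single_film_dose(0, tab, w)
  expect_equal(res0$sample_dose, 0)
  expect_equal(res0$relative_error, res$relative_error)
})

test_that("temperature weights are validated", {
  expect_error(temperature_distribution(1:3, c(-1, 1, 1)))
  tab <- single_film_table(data.frame(
    E0 = 1:2, d_avg = c(1, 1), d_rcf = c(1, 1),
    depth_error = c(0.1, 0.1), DWE = c(1, 1), QCF = c(1, 1)))
  w_bad <- temperature_distribution(c(1, 3))
  expect_error(single_film_dose(1, tab, w_bad), "grid")
})

test_that("the linear-quadratic fit has exact closed-form behavior", {
  # beta = 0: D10 = ln(10)/alpha
  a <- log(10) / 8.2
  d <- c(2, 4, 6, 8, 10)
  fit <- lq_fit(d, exp(-a * d))
  expect_equal(fit$D10, 8.2, tolerance = 1e-8)
  expect_equal(fit$beta, 0, tolerance = 1e-10)
  # exact recovery of (alpha, beta) from noiseless points
  al <- 0.12; be <- 0.02
  s <- exp(-(al * d + be * d^2))
  fit2 <- lq_fit(d, s)
  expect_equal(fit2$alpha, al, tolerance = 1e-10)
  expect_equal(fit2$beta, be, tolerance = 1e-10)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-10)
  expect_equal(al * fit2$D10 + be * fit2$D10^2, log(10), tolerance = 1e-8)
})

test_that("the LQ fit recovers D10 within 10% under 5% lognormal noise", {
  al <- 0.12; be <- 0.02
  d <- seq(1.5, 12, length.out = 8)
  s_true <- exp(-(al * d + be * d^2))
  set.seed(77)
  s_noisy <- pmin(s_true * rlnorm(8, 0, 0.05), 1)
  fit <- lq_fit(d, s_noisy)
  d10_true <- (-al + sqrt(al^2 + 4 * be * log(10))) / (2 * be)
  expect_equal(fit$D10, d10_true, tolerance = 0.1)
})

test_that("LQ fit rejects degenerate inputs", {
  expect_error(lq_fit(c(1, 1, 1), c(0.9, 0.8, 0.7)), "distinct")
  expect_error(lq_fit(c(1, 2, 3), c(0.5, 0.6, 1.2)), "\\(0, 1\\]")
  # survival increasing with dose: no physical LQ solution
  expect_error(lq_fit(c(1, 2, 3), c(0.5, 0.7, 0.9)),
               "non-positive|discriminant|positive D10")
})
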