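## Per-shot source reconstruction: charge extrapolation per temperature,
## variance-minimizing temperature fit, single-film weighted dose, and a
## linear-quadratic survival utility.

#' Measured film doses of one laser shot
#'
#' @param doses named numeric vector of measured ROI doses in Gy; names
#'   must match library plane labels (e.g. "RCF 1", "RCF 2", "RCF 3").
#' @param preset beamline preset id ("DE" or "ZF") for bookkeeping.
#' @param roi_diameter_mm ROI diameter used for the readings.
#' @param corrected logical: TRUE when the doses are already
#'   quenching-corrected (QCF and calibration factor applied).
#' @param maps optional named list of [dose_map]s.
#' @return an object of class `shot_record`.
#' @export
shot_record <- function(doses, preset = "DE", roi_diameter_mm = NULL,
                        corrected = FALSE, maps = NULL) {
  if (is.null(names(doses)) || any(!nzchar(names(doses))))
    stop("doses must be named by plane label")
  if (any(doses < 0)) stop("doses must be >= 0")
  if (length(doses) < 1) stop("at least one film required")
  if (is.null(roi_diameter_mm))
    roi_diameter_mm <- if (identical(preset, "ZF")) 5 else 10
  structure(list(doses = doses, preset = preset,
                 roi_diameter_mm = roi_diameter_mm,
                 corrected = isTRUE(corrected), maps = maps),
            class = "shot_record")
}

## corrections + reading-equivalent simulated doses for one temperature.
## Returns per-film data.frame or NULL when any film is beyond range.
.per_film_table <- function(shot, entry, calibration_factor = 1 - 0.065) {
  labs <- names(shot$doses)
  rows <- lapply(labs, function(lab) {
    p <- entry$planes[[lab]]
    if (is.null(p)) stop("library has no plane labelled '", lab, "'")
    if (p$d_roi <= 0 || !any(p$spectrum$N > 0)) return(NULL)
    dwe_i <- dwe(p$spectrum)
    qcf_i <- qcf(p$spectrum)
    d_corr <- if (shot$corrected) shot$doses[[lab]]
              else shot$doses[[lab]] * qcf_i * calibration_factor
    data.frame(label = lab, d_meas = shot$doses[[lab]],
               QCF = qcf_i, DWE = dwe_i, d_corr = d_corr,
               d_sim = p$d_roi, d_read = p$d_roi / dwe_i)
  })
  if (any(vapply(rows, is.null, TRUE))) return(NULL)
  do.call(rbind, rows)
}

#' Extrapolate the source charge at a fixed temperature
#'
#' Per-film charges `Q_i = D_i / d_i` (corrected measured dose over
#' reading-equivalent simulated dose per unit charge), their mean, and
#' the population-style deviation `sigma = sqrt(sum (Q_i - Qbar)^2) / N`.
#' Measured doses are quenching-corrected per plane (unless the shot is
#' flagged as already corrected) and simulated doses are converted to
#' reading equivalents by dividing by the plane DWE.
#'
#' @param shot a [shot_record] with at least two films.
#' @param library a `dose_library`.
#' @param E0 temperature in MeV (on the library grid).
#' @return list with `Q_bar_star`, `sigma`, `sigma_over_Q`, and the
#'   per-film table.
#' @export
extrapolate_charge <- function(shot, library, E0) {
  if (length(shot$doses) < 2)
    stop("charge extrapolation requires >= 2 films; use single_film_dose()")
  entry <- library_entry(library, E0)
  tab <- .per_film_table(shot, entry)
  if (is.null(tab))
    stop("insufficient penetration at E0 = ", E0,
         " MeV (a simulated film dose is zero)")
  q <- tab$d_corr / tab$d_read
  qbar <- mean(q)
  sigma <- sqrt(sum((q - qbar)^2)) / length(q)
  list(Q_bar_star = qbar, sigma = sigma, sigma_over_Q = sigma / qbar,
       films = cbind(tab, Q = q))
}

## sample dose per unit charge of a library entry: ROI mean of the
## "Sample" plane, or the depth average of the water sub-layers.
.sample_dose_per_charge <- function(entry) {
  if (!is.null(entry$planes[["Sample"]]))
    return(entry$planes[["Sample"]]$d_roi)
  prof <- depth_dose_profile(entry)
  mean(prof$dose)
}

#' Fit the spectral temperature of a shot
#'
#' Evaluates [extrapolate_charge] on every library temperature and
#' selects the one minimizing the relative charge dispersion
#' `sigma / Q_bar` (ties break to the lowest temperature).  The sample
#' dose is the fitted charge times the sample-plane dose per unit charge
#' at the fitted temperature.  Shots whose implied spectrum cannot
#' penetrate the stack at any temperature are flagged as rejected.
#'
#' @param shot a [shot_record] with >= 2 films.
#' @param library a `dose_library`.
#' @return an object of class `reconstruction_result`: `E0_fit`,
#'   `Q_bar_star`, `sigma_over_Q`, `sample_dose`, the per-temperature
#'   table, `rejected`, `boundary` flags, and the per-film detail at the
#'   fit.
#' @export
fit_temperature <- function(shot, library) {
  temps <- library$temperatures
  per_t <- lapply(temps, function(t0)
    tryCatch(extrapolate_charge(shot, library, t0),
             error = function(e) NULL))
  ok <- !vapply(per_t, is.null, TRUE)
  if (!any(ok)) {
    return(structure(list(E0_fit = NA_real_, Q_bar_star = NA_real_,
                          sigma_over_Q = NA_real_, sample_dose = NA_real_,
                          table = data.frame(E0 = temps, Q_bar = NA_real_,
                                             sigma = NA_real_,
                                             sigma_over_Q = NA_real_),
                          rejected = TRUE, boundary = FALSE,
                          reason = "no temperature penetrates the stack",
                          films = NULL),
                     class = "reconstruction_result"))
  }
  tab <- data.frame(
    E0 = temps,
    Q_bar = vapply(per_t, function(x) if (is.null(x)) NA_real_ else x$Q_bar_star, 0),
    sigma = vapply(per_t, function(x) if (is.null(x)) NA_real_ else x$sigma, 0),
    sigma_over_Q = vapply(per_t, function(x) if (is.null(x)) NA_real_ else x$sigma_over_Q, 0))
  i <- which(tab$sigma_over_Q == min(tab$sigma_over_Q, na.rm = TRUE))[1]
  valid <- which(ok)
  boundary <- i == valid[1] || i == valid[length(valid)]
  if (boundary)
    warning("sigma/Q minimized at (or monotone toward) the grid boundary")
  fit <- per_t[[i]]
  entry <- library_entry(library, temps[i])
  sample_dose <- fit$Q_bar_star * .sample_dose_per_charge(entry)
  structure(list(E0_fit = temps[i], Q_bar_star = fit$Q_bar_star,
                 sigma_over_Q = fit$sigma_over_Q,
                 sample_dose = sample_dose, table = tab,
                 rejected = FALSE, boundary = boundary,
                 reason = NULL, films = fit$films),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  if (isTRUE(x$rejected)) {
    cat("<reconstruction_result> REJECTED:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<reconstruction_result> E0 = %.3g MeV, Q* = %.4g nC*, sigma/Q = %.3g, sample dose = %.4g Gy\n",
    x$E0_fit, x$Q_bar_star, x$sigma_over_Q, x$sample_dose))
  invisible(x)
}

#' Temperature occurrence distribution
#'
#' Empirical weights of spectral temperatures over a set of shots, used
#' by the single-film protocol.
#'
#' @param E0 temperature grid in MeV.
#' @param weights non-negative occurrence weights (normalized to sum 1).
#' @return an object of class `temperature_distribution`.
#' @export
temperature_distribution <- function(E0, weights = rep(1, length(E0))) {
  stopifnot(length(E0) == length(weights), all(weights >= 0),
            sum(weights) > 0)
  structure(list(E0 = E0, weights = weights / sum(weights)),
            class = "temperature_distribution")
}

#' Single-film weighted sample dose
#'
#' When only one film is available the sample dose is inferred by
#' weighting the per-temperature sample-to-film dose ratio with the
#' empirical temperature occurrence distribution:
#' `D_sample / D_rcf = sum_E0 w(E0) (d_avg/d_rcf)_E0 (QCF/DWE)_E0`,
#' and the relative error is the weighted depth-dose error
#' `sum_E0 w(E0) sigma_depth(E0)`.
#'
#' @param shot a [shot_record] with exactly one (uncorrected) film, or a
#'   single measured dose in Gy.
#' @param library a `dose_library` over a thick water stack, or a
#'   [single_film_table].
#' @param weights a [temperature_distribution] on the library grid.
#' @return list with `sample_dose` (Gy), `relative_error`, and `ratio`
#'   (the weighted dose-conversion factor).
#' @export
single_film_dose <- function(shot, library, weights) {
  reading <- if (inherits(shot, "shot_record")) {
    if (length(shot$doses) != 1)
      stop("single_film_dose requires exactly one film")
    unname(shot$doses[1])
  } else {
    stopifnot(is.numeric(shot), length(shot) == 1)
    shot
  }
  tab <- if (inherits(library, "single_film_table")) library
         else single_film_table(library_summary_table(library))
  stopifnot(inherits(weights, "temperature_distribution"))
  i <- match(weights$E0, tab$E0)
  if (any(is.na(i))) stop("weights grid does not match the library grid")
  if (abs(sum(weights$weights) - 1) > 1e-8)
    stop("weights must sum to 1")
  ratio <- sum(weights$weights *
                 (tab$d_avg[i] / tab$d_rcf[i]) * (tab$QCF[i] / tab$DWE[i]))
  rel_err <- sum(weights$weights * tab$depth_error[i])
  list(sample_dose = reading * ratio, relative_error = rel_err,
       ratio = ratio)
}

#' Linear-quadratic survival fit
#'
#' Least-squares fit of `ln S = -(alpha D + beta D^2)` and the dose at
#' 10% survival, `D10`, from the positive root of
#' `alpha D + beta D^2 = ln 10`.
#'
#' @param dose doses in Gy (>= 3 distinct values).
#' @param surviving_fraction fractions in (0, 1].
#' @return list with `alpha`, `beta`, `D10`, `r_squared`.
#' @export
lq_fit <- function(dose, surviving_fraction) {
  stopifnot(length(dose) == length(surviving_fraction))
  if (length(unique(dose)) < 3) stop("need >= 3 distinct doses")
  if (any(surviving_fraction <= 0 | surviving_fraction > 1))
    stop("surviving fractions must be in (0, 1]")
  y <- -log(surviving_fraction)
  d2 <- dose^2
  fit <- stats::lm(y ~ 0 + dose + d2)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (a <= 0 && b <= 0) stop("non-positive alpha and beta; no LQ solution")
  ln10 <- log(10)
  d10 <- if (abs(b) < 1e-12) ln10 / a else {
    disc <- a^2 + 4 * b * ln10
    if (disc < 0) stop("negative discriminant; no positive D10 root")
    (-a + sqrt(disc)) / (2 * b)
  }
  if (!is.finite(d10) || d10 <= 0) stop("no positive D10 root")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(alpha = a, beta = b, D10 = d10,
       r_squared = 1 - ss_res / ss_tot)
}
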