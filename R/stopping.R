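## Single-particle physics kernels: Bethe stopping power, CSDA range,
## slab traversal, LET, Highland multiple scattering.
##
## Units: energies in MeV (total kinetic energy of the ion), thicknesses
## in um, densities in g/cm^3, mass stopping power in MeV cm^2/g, LET in
## keV/um.  Projectiles are specified by charge number z and mass number
## A (in u); protons are the default (z = 1, A = 1.00727).

.projectile_mass <- function(mass_number) mass_number * .const$amu

## Bethe validity floor for a given projectile (0.5 MeV per nucleon).
.e_floor <- function(mass_number) .const$e_floor_per_u * mass_number

#' Electronic mass stopping power (relativistic Bethe formula)
#'
#' Computes the electronic mass stopping power of an ion in a compound
#' material using the relativistic Bethe formula with the full maximum
#' energy transfer term and Bragg additivity over the composition.  The
#' result scales as the square of the projectile charge.  Below the
#' low-energy validity floor (0.5 MeV per nucleon) the value is clamped
#' to the floor value and a warning is issued; transport code deposits
#' the remaining energy locally below the floor instead.
#'
#' @param material a [material] or registry name.
#' @param energy kinetic energy in MeV (vectorized).
#' @param charge_number projectile charge number z (1 for protons).
#' @param mass_number projectile mass in u (1.00727 for protons).
#' @param warn_clamp warn when energies fall below the validity floor.
#' @return mass stopping power in MeV cm^2/g.
#' @export
mass_stopping_power <- function(material, energy, charge_number = 1L,
                                mass_number = 1.00727, warn_clamp = TRUE) {
  m <- get_material(material)
  if (any(energy <= 0)) stop("energy must be > 0")
  floor_e <- .e_floor(mass_number)
  clamped <- energy < floor_e
  if (any(clamped) && warn_clamp)
    warning("stopping power clamped below the ", signif(floor_e, 3),
            " MeV validity floor")
  e <- pmax(energy, floor_e)
  M <- .projectile_mass(mass_number)
  gamma <- 1 + e / M
  beta2 <- 1 - 1 / gamma^2
  bg2 <- beta2 * gamma^2
  me_M <- .const$me / M
  wmax <- 2 * .const$me * bg2 / (1 + 2 * gamma * me_M + me_M^2)
  I <- m$I_eV * 1e-6  # MeV
  L <- 0.5 * log(2 * .const$me * bg2 * wmax / I^2) - beta2
  s <- .const$K * charge_number^2 * m$ZA_eff / beta2 * L
  structure(s, clamped = clamped)
}

## ---- cached range tables -------------------------------------------------

.range_env <- new.env(parent = emptyenv())

## Build (and cache) a CSDA range table for (material, projectile).
## R(E) = r_residual + integral_floor^E dE'/S(E'), with the residual range
## at the floor taken as E_floor / S(E_floor) (constant-stopping
## extrapolation; about 12 um of water for protons).
.range_table <- function(material, charge_number = 1L, mass_number = 1.00727) {
  m <- get_material(material)
  key <- sprintf("%s|z%d|A%.5f|I%.4f|rho%.5g", m$name, charge_number,
                 mass_number, m$I_eV, m$density)
  tab <- .range_env[[key]]
  if (!is.null(tab)) return(tab)
  floor_e <- .e_floor(mass_number)
  emax <- 500 * mass_number
  e <- exp(seq(log(floor_e), log(emax), length.out = 2000L))
  s <- as.numeric(mass_stopping_power(m, e, charge_number, mass_number,
                                      warn_clamp = FALSE))
  inv <- 1 / s
  ## cumulative trapezoid
  r <- c(0, cumsum(diff(e) * (inv[-1] + inv[-length(inv)]) / 2))
  r_res <- floor_e / s[1]
  tab <- list(e = e, r = r + r_res, floor = floor_e, r_residual = r_res)
  .range_env[[key]] <- tab
  tab
}

#' CSDA range
#'
#' Continuous-slowing-down range obtained by numerical integration of the
#' reciprocal stopping power from the validity floor up to the requested
#' energy, plus the (documented) residual range of the floor energy.
#'
#' @inheritParams mass_stopping_power
#' @return range in g/cm^2 (vectorized over `energy`).
#' @export
csda_range <- function(material, energy, charge_number = 1L,
                       mass_number = 1.00727) {
  tab <- .range_table(material, charge_number, mass_number)
  if (any(energy <= 0)) stop("energy must be > 0")
  e <- pmax(energy, tab$floor)
  stats::approx(tab$e, tab$r, xout = pmin(e, max(tab$e)), rule = 2)$y
}

## Inverse range lookup: energy whose range equals r (g/cm^2).  Values at
## or below the residual range map to 0 ("stopped").
.energy_from_range <- function(r, tab) {
  out <- stats::approx(tab$r, tab$e, xout = r, rule = 2)$y
  out[r <= tab$r_residual] <- 0
  out
}

#' Energy after traversing a slab
#'
#' Solves the range arithmetic `R(E_out) = R(E_in) - rho * t`.  Returns 0
#' for particles that stop inside the slab (a proton never exits a slab
#' with exactly zero energy); energies emerging below the Bethe validity
#' floor are treated as stopped, with all energy deposited locally.
#'
#' @param material a [material] or registry name.
#' @param thickness_um slab thickness in micrometers.
#' @param energy_in incident kinetic energy in MeV (vectorized).
#' @inheritParams mass_stopping_power
#' @return exit kinetic energies in MeV; 0 denotes STOPPED.
#' @export
energy_after_slab <- function(material, thickness_um, energy_in,
                              charge_number = 1L, mass_number = 1.00727) {
  if (thickness_um < 0) stop("thickness must be >= 0")
  if (thickness_um == 0) return(energy_in)
  m <- get_material(material)
  tab <- .range_table(m, charge_number, mass_number)
  areal <- thickness_um * 1e-4 * m$density
  e_out <- numeric(length(energy_in))
  pos <- energy_in > 0           # already-stopped entries stay stopped
  if (any(pos)) {
    r_in <- csda_range(m, energy_in[pos], charge_number, mass_number)
    e_pos <- .energy_from_range(r_in - areal, tab)
    e_pos[e_pos <= tab$floor] <- 0
    e_out[pos] <- e_pos
  }
  e_out
}

#' Linear energy transfer in a material
#'
#' Electronic linear stopping power (mass stopping power times density)
#' expressed in keV/um; the quantity entering the film quenching model.
#'
#' @inheritParams mass_stopping_power
#' @return LET in keV/um.
#' @export
let_in_material <- function(material, energy, charge_number = 1L,
                            mass_number = 1.00727) {
  m <- get_material(material)
  s <- mass_stopping_power(m, energy, charge_number, mass_number,
                           warn_clamp = FALSE)
  ## MeV cm^2/g * g/cm^3 = MeV/cm = 0.1 keV/um
  as.numeric(s) * m$density * 0.1
}

#' Highland multiple-scattering angle
#'
#' RMS projected scattering angle after a slab, via the Highland
#' parameterization with the logarithmic thickness correction:
#' `theta_0 = 13.6 MeV / (beta c p) * z * sqrt(x/X0) * (1 + 0.038 ln(x z^2 / (X0 beta^2)))`.
#'
#' @inheritParams energy_after_slab
#' @param energy kinetic energy in MeV.
#' @return RMS projected angle in rad (0 at zero thickness).
#' @export
highland_angle <- function(material, thickness_um, energy,
                           charge_number = 1L, mass_number = 1.00727) {
  if (thickness_um < 0) stop("thickness must be >= 0")
  if (thickness_um == 0) return(rep(0, length(energy)))
  m <- get_material(material)
  M <- .projectile_mass(mass_number)
  gamma <- 1 + energy / M
  beta2 <- 1 - 1 / gamma^2
  p <- sqrt(energy^2 + 2 * energy * M)  # MeV/c
  x_over_x0 <- thickness_um * 1e-4 * m$density / m$X0
  corr <- 1 + 0.038 * log(x_over_x0 * charge_number^2 / beta2)
  th <- 13.6 / (sqrt(beta2) * p) * abs(charge_number) *
    sqrt(x_over_x0) * corr
  pmax(th, 0)
}

#' Water-equivalent thickness of a slab sequence
#'
#' Mass-stopping-power scaling at a representative energy: each layer
#' contributes `t * rho * S_layer(E) / S_water(E)` micrometers of water.
#'
#' @param slabs a list of [slab]s (or a single slab).
#' @param energy representative proton energy in MeV (default 10).
#' @return water-equivalent thickness in micrometers.
#' @export
water_equivalent_thickness <- function(slabs, energy = 10) {
  if (inherits(slabs, "slab")) slabs <- list(slabs)
  sw <- as.numeric(mass_stopping_power("water", energy))
  sum(vapply(slabs, function(s) {
    sm <- as.numeric(mass_stopping_power(s$material, energy))
    s$thickness_um * s$material$density * sm / sw
  }, 0))
}
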