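#' @keywords internal
"_PACKAGE"

## Physical constants (MeV, cm, g units unless noted)
.const <- list(
  K          = 0.307075,        # 4 pi N_A r_e^2 m_e c^2, MeV cm^2 / mol
  me         = 0.51099895,      # electron rest mass, MeV
  mp         = 938.27208816,    # proton rest mass, MeV
  amu        = 931.49410242,    # atomic mass unit, MeV
  mev_to_j   = 1.602176634e-13, # J per MeV
  protons_per_nc = 1e-9 / 1.602176634e-19, # protons in 1 nC of charge
  e_floor_per_u  = 0.5          # Bethe validity floor, MeV per nucleon
)

## Element data used for Bragg additivity.  I-values follow the ICRU
## convention for elements bound in compounds (hydrogen 19.2 eV, carbon
## 81 eV, oxygen 106 eV, ...); elemental solids keep their bulk values.
.elements <- data.frame(
  symbol = c("H",   "Li",  "C",   "N",   "O",   "Na",  "Al",  "Si",
             "Cl",  "Ar",  "Au"),
  Z      = c(1,     3,     6,     7,     8,     11,    13,    14,
             17,    18,    79),
  A      = c(1.008, 6.94,  12.011, 14.007, 15.999, 22.990, 26.982, 28.085,
             35.45, 39.948, 196.967),
  I_eV   = c(19.2,  40,    81,    82,    106,   149,   166,   173,
             174,   188,   790),
  stringsAsFactors = FALSE
)

#' Define a material
#'
#' A material is described by its density, elemental composition by mass
#' fraction, and (optionally) an overriding mean excitation energy.  When
#' no I-value is given it is derived from the composition by Bragg
#' additivity over the per-element I-values.
#'
#' @param name identifier.
#' @param density mass density in g/cm^3.
#' @param composition named numeric vector of mass fractions by element
#'   symbol; must sum to 1 within 1e-6.
#' @param I_eV optional composite mean excitation energy in eV, overriding
#'   Bragg additivity (used for materials with well-established condensed
#'   phase values, e.g. water at 78 eV).
#' @return an object of class `material`.
#' @export
material <- function(name, density, composition, I_eV = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || density <= 0)
    stop("density must be positive")
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop("composition must be a named vector of mass fractions")
  unknown <- setdiff(names(composition), .elements$symbol)
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  if (abs(sum(composition) - 1) > 1e-6)
    stop("mass fractions must sum to 1 (got ", signif(sum(composition), 8), ")")

  idx  <- match(names(composition), .elements$symbol)
  za   <- .elements$Z[idx] / .elements$A[idx]
  wza  <- composition * za
  ZA_eff <- sum(wza)
  ## Bragg additivity: <ln I> weighted by electron fractions
  lnI <- sum(wza * log(.elements$I_eV[idx])) / ZA_eff
  I_add <- exp(lnI)
  ## Radiation length (Tsai-style approximation per element)
  x0_el <- 716.408 * .elements$A[idx] /
    (.elements$Z[idx] * (.elements$Z[idx] + 1) *
       log(287 / sqrt(.elements$Z[idx])))
  X0 <- 1 / sum(composition / x0_el)

  structure(list(
    name = name, density = density, composition = composition,
    I_eV = if (is.null(I_eV)) I_add else I_eV,
    I_from_additivity = is.null(I_eV),
    ZA_eff = ZA_eff, X0 = X0
  ), class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s  rho = %.4g g/cm^3  I = %.1f eV  Z/A = %.4f\n",
              x$name, x$density, x$I_eV, x$ZA_eff))
  comp <- paste(sprintf("%s %.3f", names(x$composition), x$composition),
                collapse = ", ")
  cat(" composition:", comp, "\n")
  invisible(x)
}

## Built-in registry.  Compositions: water, air and polymer films follow
## standard dosimetry compendia; the radiochromic active layer follows the
## manufacturer-style elemental breakdown (51.1% C, 8.8% H, 0.6% Li,
## 32.8% O, 6.7% Al at 1.15 g/cm^3).  Lumox is a silicone (PDMS) membrane
## at its measured density of 1.10 g/cm^3; Parafilm is a paraffin blend at
## 0.922 g/cm^3.
.build_registry <- function() {
  list(
    water = material("water", 1.000,
                     c(H = 0.111894, O = 0.888106), I_eV = 78),
    aluminum = material("aluminum", 2.699, c(Al = 1)),
    gold     = material("gold", 19.32, c(Au = 1)),
    kapton   = material("kapton", 1.42,
                        c(H = 0.026362, C = 0.691133, N = 0.073270,
                          O = 0.209235)),
    mylar    = material("mylar", 1.40,
                        c(H = 0.041959, C = 0.625016, O = 0.333025)),
    ebtxd_active = material("ebtxd_active", 1.15,
                            c(C = 0.511, H = 0.088, Li = 0.006,
                              O = 0.328, Al = 0.067)),
    hd810_active = material("hd810_active", 1.15,
                            c(C = 0.511, H = 0.088, Li = 0.006,
                              O = 0.328, Al = 0.067)),
    hd810_substrate = material("hd810_substrate", 1.40,
                               c(H = 0.041959, C = 0.625016, O = 0.333025)),
    lumox    = material("lumox", 1.10,
                        c(Si = 0.3790, O = 0.2159, C = 0.3244, H = 0.0807)),
    parafilm = material("parafilm", 0.922,
                        c(H = 0.148605, C = 0.851395)),
    air      = material("air", 1.20479e-3,
                        c(N = 0.755267, O = 0.231781, Ar = 0.012827,
                          C = 0.000125), I_eV = 85.7)
  )
}

.registry_env <- new.env(parent = emptyenv())

#' Built-in material registry
#'
#' @return named list of [material] objects.
#' @export
material_registry <- function() {
  if (is.null(.registry_env$materials))
    .registry_env$materials <- .build_registry()
  .registry_env$materials
}

#' Look up a material by name (or pass one through)
#'
#' @param x a `material` object or the name of a registry entry.
#' @return a `material` object.
#' @export
get_material <- function(x) {
  if (inherits(x, "material")) return(x)
  reg <- material_registry()
  if (!is.character(x) || length(x) != 1L || is.na(match(x, names(reg))))
    stop("unknown material: ", deparse(substitute(x)))
  reg[[x]]
}

#' Serialize / deserialize the material registry
#'
#' Writes the registry (name, density, composition, I-value) as a YAML
#' document, and reads such a document back into `material` objects.
#'
#' @param path file path.
#' @param materials named list of `material` objects (defaults to the
#'   built-in registry).
#' @return `read_materials()` returns a named list of `material` objects.
#' @export
write_materials <- function(path, materials = material_registry()) {
  doc <- lapply(materials, function(m)
    list(name = m$name, density = m$density,
         composition = as.list(m$composition), I_eV = m$I_eV))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_materials
#' @export
read_materials <- function(path) {
  doc <- yaml::read_yaml(path)
  out <- lapply(doc, function(d)
    material(d$name, d$density, unlist(d$composition), I_eV = d$I_eV))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Describe a slab of material
#'
#' @param material a `material` or registry name.
#' @param thickness_um slab thickness in micrometers (>= 0).
#' @param label identifier used to match film readings to planes.
#' @param sensitive logical; sensitive slabs accumulate dose maps and
#'   spectra during transport.
#' @return an object of class `slab`.
#' @export
slab <- function(material, thickness_um, label = NULL, sensitive = FALSE) {
  m <- get_material(material)
  if (!is.numeric(thickness_um) || thickness_um < 0)
    stop("thickness must be >= 0")
  structure(list(material = m, thickness_um = thickness_um,
                 label = if (is.null(label)) m$name else label,
                 sensitive = isTRUE(sensitive)),
            class = "slab")
}

#' @export
print.slab <- function(x, ...) {
  cat(sprintf("<slab> %-14s %8.1f um  %s%s\n", x$label, x$thickness_um,
              x$material$name, if (x$sensitive) "  [sensitive]" else ""))
  invisible(x)
}

## areal density of a slab in g/cm^2
.slab_areal <- function(s) s$thickness_um * 1e-4 * s$material$density
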