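# Elemental data used for Bragg-additivity mean excitation energies and
# PDG-style radiation lengths. I values are condensed-history working values
# for elements bound in tissue-like compounds.
.element_table <- data.frame(
  symbol = c("H", "C", "N", "O", "F", "Na", "Mg", "Al", "Si", "P", "S",
             "Cl", "Ar", "K", "Ca", "Ti", "Fe"),
  Z = c(1, 6, 7, 8, 9, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 22, 26),
  A = c(1.008, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305, 26.982,
        28.085, 30.974, 32.06, 35.45, 39.948, 39.098, 40.078, 47.867, 55.845),
  I_eV = c(19.2, 78, 82, 95, 115, 149, 156, 166, 173, 173, 180,
           174, 188, 190, 191, 233, 286),
  stringsAsFactors = FALSE
)

.element_lookup <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  if (anyNA(i)) stop("unknown element symbol(s): ",
                     paste(symbol[is.na(i)], collapse = ", "))
  .element_table[i, , drop = FALSE]
}

# elemental radiation length, g/cm^2 (Tsai approximation)
.x0_element <- function(Z, A) 716.408 * A / (Z * (Z + 1) * log(287 / sqrt(Z)))

#' Construct a material
#'
#' A material is an elemental mixture with a bulk density and a mean
#' excitation energy \eqn{I}. The electron density
#' \eqn{n_e = \rho N_{Av} \sum_i w_i Z_i / A_i} and the radiation length
#' are derived at construction and cached. When `I_eV` is omitted it is
#' computed by Bragg additivity over the elemental \eqn{I} values
#' (electron-fraction weighted log average).
#'
#' @param name label.
#' @param elements either a character vector of element symbols with
#'   `mass_fractions`, or a data.frame with columns `symbol`, `Z`, `A`,
#'   `w` (mass fraction).
#' @param mass_fractions numeric vector of mass fractions (same length as
#'   `elements` when the latter is a character vector). Fractions are
#'   renormalized to sum to one; inputs off by more than 1e-3 are rejected.
#' @param density bulk density in g/cm^3 (> 0).
#' @param I_eV mean excitation energy in eV; computed from the composition
#'   when `NULL`.
#' @param sternheimer optional list of density-effect coefficients
#'   (`Cbar`, `x0`, `x1`, `a`, `m`, `delta0`); when omitted a generic
#'   Sternheimer parameterization is derived from `I` and the plasma
#'   energy.
#' @return An object of class `material` with fields `name`, `elements`,
#'   `density`, `I_eV`, `electron_density`, `z_over_a`, `zbar`,
#'   `radiation_length`, `sternheimer`.
#' @examples
#' w <- material_water()
#' w$electron_density
#' @export
material <- function(name, elements, mass_fractions = NULL, density,
                     I_eV = NULL, sternheimer = NULL) {
  if (is.character(elements)) {
    tab <- .element_lookup(elements)
    comp <- data.frame(symbol = elements, Z = tab$Z, A = tab$A,
                       w = mass_fractions, stringsAsFactors = FALSE)
  } else {
    comp <- as.data.frame(elements)
    if (is.null(comp$w) && !is.null(mass_fractions)) comp$w <- mass_fractions
  }
  if (nrow(comp) == 0L) stop("material '", name, "' has an empty composition")
  stopifnot(all(comp$w >= 0), density > 0)
  s <- sum(comp$w)
  if (abs(s - 1) > 1e-3)
    stop("mass fractions of '", name, "' sum to ", signif(s, 6), ", not 1")
  comp$w <- comp$w / s

  z_over_a <- sum(comp$w * comp$Z / comp$A)
  const <- physical_constants()
  ne <- density * const$avogadro * z_over_a

  if (is.null(I_eV)) {
    tab <- .element_lookup(comp$symbol)
    lw <- comp$w * comp$Z / comp$A
    I_eV <- exp(sum(lw * log(tab$I_eV)) / sum(lw))
  }
  stopifnot(I_eV > 0)

  # atom-number-weighted mean Z (enters the shell and Barkas surrogates)
  n_atoms <- comp$w / comp$A
  zbar <- sum(n_atoms * comp$Z) / sum(n_atoms)

  x0 <- 1 / sum(comp$w / .x0_element(comp$Z, comp$A))

  if (is.null(sternheimer))
    sternheimer <- .sternheimer_generic(I_eV, density, z_over_a)

  structure(list(
    name = name, elements = comp, density = density, I_eV = I_eV,
    electron_density = ne, z_over_a = z_over_a, zbar = zbar,
    radiation_length = x0, sternheimer = sternheimer
  ), class = "material")
}

# Generic Sternheimer density-effect coefficients from I and the plasma
# energy; the Sternheimer-Peierls selection rules pick x0/x1, and `a` is
# fixed by continuity of delta at x0.
.sternheimer_generic <- function(I_eV, density, z_over_a) {
  hwp <- 28.8159 * sqrt(density * z_over_a) # plasma energy, eV
  Cbar <- 2 * log(I_eV / hwp) + 1
  gas <- density < 0.05
  if (gas) {
    x0 <- if (Cbar < 10) 1.6 else if (Cbar < 10.5) 1.7 else
          if (Cbar < 11) 1.8 else if (Cbar < 11.5) 1.9 else
          if (Cbar < 12.25) 2.0 else 2.0
    x1 <- if (Cbar < 12.25) 4.0 else 5.0
  } else if (I_eV < 100) {
    x1 <- 2.0
    x0 <- if (Cbar < 3.681) 0.2 else 0.326 * Cbar - 1.0
  } else {
    x1 <- 3.0
    x0 <- if (Cbar < 5.215) 0.2 else 0.326 * Cbar - 1.5
  }
  m <- 3.0
  a <- (Cbar - 2 * log(10) * x0) / (x1 - x0)^m
  list(Cbar = Cbar, x0 = x0, x1 = x1, a = max(a, 0), m = m, delta0 = 0)
}

#' @describeIn material Liquid water; the default mean excitation energy is
#'   78 eV (user-overridable, as experimental re-evaluations suggest) and
#'   the packaged Sternheimer coefficients are used for the density effect.
#' @export
material_water <- function(I_eV = 78) {
  material("water", c("H", "O"), c(0.111894, 0.888106), density = 1.0,
           I_eV = I_eV,
           sternheimer = list(Cbar = 3.5017, x0 = 0.2400, x1 = 2.8004,
                              a = 0.09116, m = 3.4773, delta0 = 0))
}

#' @describeIn material Dry air near sea level.
#' @export
material_air <- function() {
  material("air", c("C", "N", "O", "Ar"),
           c(0.000124, 0.755268, 0.231781, 0.012827),
           density = 1.20479e-3, I_eV = 85.7,
           sternheimer = list(Cbar = 10.5961, x0 = 1.7418, x1 = 4.2759,
                              a = 0.10914, m = 3.3994, delta0 = 0))
}

#' @describeIn material ICRU-style compact bone.
#' @export
material_bone <- function() {
  material("bone", c("H", "C", "N", "O", "Mg", "P", "S", "Ca"),
           c(0.063984, 0.278, 0.027, 0.410016, 0.002, 0.07, 0.002, 0.147),
           density = 1.85, I_eV = 91.9)
}

#' @describeIn material Deflated lung tissue.
#' @export
material_lung <- function() {
  material("lung", c("H", "C", "N", "O", "Na", "P", "S", "Cl", "K"),
           c(0.103, 0.105, 0.031, 0.749, 0.002, 0.002, 0.003, 0.003, 0.002),
           density = 0.26, I_eV = 75.3)
}

#' @describeIn material Average soft tissue.
#' @export
material_soft_tissue <- function() {
  material("soft_tissue", c("H", "C", "N", "O", "Na", "P", "S", "Cl", "K"),
           c(0.105, 0.256, 0.027, 0.602, 0.001, 0.002, 0.003, 0.002, 0.002),
           density = 1.03)
}

#' @describeIn material PMMA (acrylic), a common phantom plastic.
#' @export
material_pmma <- function() {
  material("pmma", c("H", "C", "O"), c(0.080538, 0.599848, 0.319614),
           density = 1.190, I_eV = 74)
}

# registry of built-in materials by name (used by slab phantoms and the CLI)
.builtin_materials <- function() {
  list(water = material_water(), air = material_air(), bone = material_bone(),
       lung = material_lung(), soft_tissue = material_soft_tissue(),
       pmma = material_pmma())
}

#' Electron density of a material
#'
#' Recomputes \eqn{n_e = \rho N_{Av} \sum_i w_i Z_i / A_i} from the stored
#' composition; the value cached at construction equals this recomputation.
#'
#' @param mat a [material()].
#' @return electrons per cm^3.
#' @examples
#' electron_density(material_water())  # ~3.343e23
#' @export
electron_density <- function(mat) {
  stopifnot(inherits(mat, "material"))
  if (nrow(mat$elements) == 0L) stop("empty composition")
  const <- physical_constants()
  mat$density * const$avogadro * sum(mat$elements$w * mat$elements$Z / mat$elements$A)
}
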