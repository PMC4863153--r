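#' Physical constants used throughout the engine
#'
#' Returns the fixed set of physical constants entering the stopping-power
#' prefactor and kinematics: the electron rest energy \eqn{m_e c^2},
#' the classical electron radius \eqn{r_e}, Avogadro's number and the
#' fine-structure constant. All modules share this single source so that
#' cross-module invariants (e.g. energy bookkeeping) hold exactly.
#'
#' @return A list with elements `electron_mass_energy` (MeV),
#'   `classical_electron_radius` (cm), `avogadro` (1/mol),
#'   `fine_structure_constant` (dimensionless), `amu` (MeV/c^2, atomic
#'   mass unit) and `proton_mass` (MeV/c^2).
#' @examples
#' physical_constants()$electron_mass_energy
#' @export
physical_constants <- function() {
  list(
    electron_mass_energy      = 0.51099895,      # MeV
    classical_electron_radius = 2.8179403262e-13, # cm
    avogadro                  = 6.02214076e23,    # 1/mol
    fine_structure_constant   = 7.2973525693e-3,
    amu                       = 931.49410242,     # MeV/c^2
    proton_mass               = 938.27208816      # MeV/c^2
  )
}

# speed of light, used for photon/particle times of flight
.c_cm_per_ns <- 29.9792458

#' Projectile specification
#'
#' Defines a primary ion by charge number, mass and mass number. Helpers
#' for the four therapeutic species are provided via [projectile()].
#'
#' @param name label, e.g. `"proton"`.
#' @param z charge number (>= 1).
#' @param mass rest mass in MeV/c^2.
#' @param A mass number (>= 1).
#' @return An object of class `projectile_spec`.
#' @export
projectile_spec <- function(name, z, mass, A) {
  stopifnot(z >= 1, mass > 0, A >= 1)
  structure(list(name = name, z = as.integer(z), mass = mass, A = as.integer(A)),
            class = "projectile_spec")
}

#' Built-in therapeutic projectiles
#'
#' @param name one of `"proton"`, `"helium"`, `"carbon"`, `"oxygen"`.
#' @return A [projectile_spec()].
#' @examples
#' projectile("carbon")$z
#' @export
projectile <- function(name = c("proton", "helium", "carbon", "oxygen")) {
  name <- match.arg(name)
  switch(name,
    proton = projectile_spec("proton", 1, 938.27208816, 1),
    helium = projectile_spec("helium", 2, 3727.3794066, 4),
    carbon = projectile_spec("carbon", 6, 11174.86339, 12),
    oxygen = projectile_spec("oxygen", 8, 14895.08177, 16)
  )
}
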