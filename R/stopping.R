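#' Relativistic kinematics for an ion of given kinetic energy
#'
#' Total kinetic energy is `E * A` (MeV per nucleon times mass number), so
#' \eqn{\gamma = 1 + E A / M} and \eqn{\beta = \sqrt{1 - 1/\gamma^2}}.
#'
#' @param E kinetic energy in MeV/u (> 0; vectorized).
#' @param proj a [projectile_spec()].
#' @return list with `kinetic_energy_per_nucleon`, `beta`, `gamma`
#'   (each vectorized over `E`).
#' @export
kinematics_from_energy <- function(E, proj) {
  stopifnot(inherits(proj, "projectile_spec"))
  if (any(E <= 0)) stop("kinetic energy must be positive")
  gamma <- 1 + E * proj$A / proj$mass
  beta <- sqrt(1 - 1 / gamma^2)
  list(kinetic_energy_per_nucleon = E, beta = beta, gamma = gamma)
}

#' @rdname kinematics_from_energy
#' @param state a kinematic state as returned by [kinematics_from_energy()].
#' @export
energy_from_kinematics <- function(state, proj) {
  (state$gamma - 1) * proj$mass / proj$A
}

#' Maximum energy transfer to a stationary electron
#'
#' Kinematic limit for a single collision,
#' \deqn{T_{max} = \frac{2 m_e c^2 \beta^2 \gamma^2}
#'   {1 + 2\gamma m_e/M + (m_e/M)^2},}
#' with all mass-ratio terms kept (no heavy-projectile approximation).
#'
#' @inheritParams energy_from_kinematics
#' @return MeV (vectorized).
#' @export
tmax <- function(state, proj) {
  me <- physical_constants()$electron_mass_energy
  r <- me / proj$mass
  2 * me * state$beta^2 * state$gamma^2 /
    (1 + 2 * state$gamma * r + r^2)
}

#' Projectile effective charge
#'
#' Accounts for partial neutralization of the projectile charge at low
#' velocity. For very light ions (protons and alphas, z <= 2) the bare
#' charge is used at all energies; heavier ions follow a Barkas-type
#' parameterization \eqn{z_{eff} = z (1 - e^{-k \beta z^{-2/3}})} with
#' `k = 125` by default (configurable, as published re-fits differ).
#'
#' @inheritParams tmax
#' @param k velocity-scaling constant of the Barkas form.
#' @return effective charge in elementary charges (vectorized over beta).
#' @export
effective_charge <- function(proj, state, k = 125) {
  if (proj$z <= 2) return(rep(proj$z, length(state$beta)))
  proj$z * (1 - exp(-k * state$beta * proj$z^(-2 / 3)))
}

#' Density-effect correction (Sternheimer)
#'
#' Medium-polarization suppression of the distant-collision term.
#' Evaluated from the material's packaged Sternheimer coefficients (or the
#' generic parameterization derived at construction): with
#' `x = log10(beta*gamma)`,
#' `delta = 4.6052 x - Cbar + a (x1 - x)^m` for `x0 <= x < x1`,
#' `4.6052 x - Cbar` above `x1`, and `delta0 * 10^{2(x - x0)}` below `x0`.
#'
#' @inheritParams tmax
#' @param mat a [material()].
#' @return dimensionless delta >= 0 (vectorized).
#' @export
density_correction <- function(state, mat) {
  p <- mat$sternheimer
  x <- log10(state$beta * state$gamma)
  delta <- ifelse(x >= p$x1, 2 * log(10) * x - p$Cbar,
           ifelse(x >= p$x0, 2 * log(10) * x - p$Cbar + p$a * (p$x1 - x)^p$m,
                  p$delta0 * 10^(2 * (x - p$x0))))
  pmax(delta, 0)
}

# Barkas-Bichsel shell-correction fit domain: eta = beta*gamma
.shell_eta_min <- 0.13

#' Shell correction C/Z
#'
#' Accounts for the breakdown of the Bethe assumption that the projectile
#' is much faster than the atomic electrons; important at low energy.
#' Implemented as the classic Barkas-Bichsel polynomial in
#' \eqn{1/\eta^2} (\eqn{\eta = \beta\gamma}) with the material's mean
#' excitation energy, a parameterization originally fitted to proton
#' stopping tables. Below its validity domain (\eqn{\eta < 0.13}) the
#' argument is clamped with a warning.
#'
#' @inheritParams density_correction
#' @return C/Z, dimensionless (vectorized).
#' @export
shell_correction <- function(state, mat) {
  eta <- state$beta * state$gamma
  if (any(eta < .shell_eta_min)) {
    warning("shell correction evaluated below its fit domain; clamped at eta = ",
            .shell_eta_min)
    eta <- pmax(eta, .shell_eta_min)
  }
  I <- mat$I_eV
  e2 <- eta^-2
  C <- (0.422377 * e2 + 0.0304043 * e2^2 - 0.00038106 * e2^3) * 1e-6 * I^2 +
       (3.850190 * e2 - 0.1667989 * e2^2 + 0.00157955 * e2^3) * 1e-9 * I^3
  C / mat$zbar
}

#' Barkas (z^3) and Bloch (z^4) corrections
#'
#' Corrections beyond the first Born approximation. The Bloch term uses
#' the standard closed form in \eqn{y = z_{eff}\alpha/\beta},
#' \eqn{L_2(y) = -y^2 \sum_{n\ge1} 1/(n(n^2+y^2))}. The Barkas term uses
#' an Ashley-Ritchie-Brandt-shaped parameterization
#' \eqn{L_1 = F_0/(\sqrt{\bar Z}\, V^3)} with scaled velocity
#' \eqn{V = \beta\gamma/(\alpha\sqrt{\bar Z})} and fitted constant
#' `F0 = 0.35` (capped at 0.2 at very low velocity). Both terms enter the
#' stopping bracket as \eqn{2 z L_1 + 2 z^2 L_2} and vanish faster than
#' the leading logarithm as \eqn{\beta \to 1}. The Barkas term is odd in
#' the projectile charge (particle/antiparticle convention: positive
#' projectiles get `+2 z L1`).
#'
#' @inheritParams density_correction
#' @param F0 Barkas-term amplitude.
#' @return list with elements `L1` and `L2` (vectorized).
#' @export
barkas_bloch_terms <- function(proj, state, mat, F0 = 0.35) {
  alpha <- physical_constants()$fine_structure_constant
  V <- state$beta * state$gamma / (alpha * sqrt(mat$zbar))
  L1 <- pmin(F0 / (sqrt(mat$zbar) * V^3), 0.2)
  zeff <- effective_charge(proj, state)
  y <- zeff * alpha / state$beta
  # full Bloch correction -y^2 sum_n 1/(n(n^2+y^2)); since it enters the
  # bracket as 2 z^2 L2, L2 is the correction divided by z_eff^2
  L2 <- vapply(y, .bloch_full, 0.0) / zeff^2
  list(L1 = L1, L2 = L2)
}

# Bloch closed form; 2000 terms leave a relative tail below 1e-7
.bloch_full <- function(y) {
  n <- 1:2000
  -y^2 * (sum(1 / (n * (n^2 + y^2))) + 1 / (2 * 2000^2))
}

#' Mott correction to the average stopping power
#'
#' Higher-order correction from the electron-ion Mott cross section,
#' needed once \eqn{z\alpha/\beta} is no longer small; grows with the
#' projectile charge and is relevant for medium-heavy ions. Implemented as
#' the documented surrogate \eqn{K_M = c_M\, y/(1+y)},
#' \eqn{y = z_{eff}\alpha/\beta} (the published fit family is not
#' reproducible from open sources). Returns 0 when disabled.
#'
#' @inheritParams tmax
#' @param enabled logical toggle; the engine default is off for z <= 2 and
#'   on for z >= 3.
#' @param c_M surrogate amplitude.
#' @return dimensionless (vectorized).
#' @export
mott_correction <- function(proj, state, enabled = proj$z >= 3, c_M = 0.6) {
  if (!enabled) return(rep(0, length(state$beta)))
  alpha <- physical_constants()$fine_structure_constant
  y <- effective_charge(proj, state) * alpha / state$beta
  c_M * y / (1 + y)
}

#' Stopping-power correction toggles
#'
#' @param density,shell,barkas,bloch,effective_charge logical toggles.
#' @param mott logical or `NULL` (auto: on for z >= 3).
#' @param barkas_k effective-charge constant `k`.
#' @param barkas_F0 Barkas-term amplitude.
#' @param mott_c Mott surrogate amplitude.
#' @return list of options for [electronic_stopping_power()].
#' @export
stopping_options <- function(density = TRUE, shell = TRUE, barkas = TRUE,
                             bloch = TRUE, mott = NULL,
                             effective_charge = TRUE,
                             barkas_k = 125, barkas_F0 = 0.35, mott_c = 0.6) {
  list(density = density, shell = shell, barkas = barkas, bloch = bloch,
       mott = mott, effective_charge = effective_charge,
       barkas_k = barkas_k, barkas_F0 = barkas_F0, mott_c = mott_c)
}

# operating domain in MeV/u; below .bethe_switch the Bethe bracket is
# abandoned for a velocity-proportional (Ziegler-style) low-energy branch
.energy_domain <- c(0.01, 1000)
.bethe_switch <- 0.5

#' Electronic mass stopping power
#'
#' Mean electronic energy loss per unit mass thickness,
#' \deqn{-\frac{1}{\rho}\frac{dE}{dx} =
#'   \frac{2\pi n_e r_e^2 m_e c^2 z_{eff}^2}{\rho\,\beta^2}
#'   \Big[\ln\frac{2 m_e c^2 \beta^2 T_{max}}{I^2 (1-\beta^2)}
#'   - 2\beta^2 + 2 z L_1 + 2 z^2 L_2 + K_M - 2\frac{C}{Z} - \delta\Big]}
#' in MeV cm^2/g, with every correction individually toggleable. Below
#' 0.5 MeV/u (still inside the 0.01--1000 MeV/u operating domain) a
#' velocity-proportional low-energy branch
#' \eqn{S(E) = S(0.5)\sqrt{E/0.5}} replaces the Bethe bracket, which is
#' no longer valid there.
#'
#' @param E kinetic energy, MeV/u (vectorized; must lie in \[0.01, 1000\]).
#' @param proj a [projectile_spec()].
#' @param mat a [material()].
#' @param options see [stopping_options()].
#' @return MeV cm^2/g, strictly positive over the operating domain.
#' @examples
#' electronic_stopping_power(150, projectile("proton"), material_water())
#' @export
electronic_stopping_power <- function(E, proj, mat, options = stopping_options()) {
  if (any(E < .energy_domain[1] | E > .energy_domain[2]))
    stop("energy outside the operating domain [",
         .energy_domain[1], ", ", .energy_domain[2], "] MeV/u")
  lo <- E < .bethe_switch
  S <- numeric(length(E))
  if (any(!lo)) S[!lo] <- .bethe_eq1(E[!lo], proj, mat, options)
  if (any(lo)) {
    s0 <- .bethe_eq1(.bethe_switch, proj, mat, options)
    S[lo] <- s0 * sqrt(E[lo] / .bethe_switch)
  }
  S
}

# full Eq.-1 assembly (valid above .bethe_switch)
.bethe_eq1 <- function(E, proj, mat, options, tcut = Inf) {
  const <- physical_constants()
  st <- kinematics_from_energy(E, proj)
  me <- const$electron_mass_energy
  Tm <- tmax(st, proj)
  Tup <- pmin(Tm, tcut)
  I <- mat$I_eV * 1e-6  # MeV

  zeff <- if (options$effective_charge)
    effective_charge(proj, st, k = options$barkas_k) else rep(proj$z, length(E))
  delta <- if (options$density) density_correction(st, mat) else 0
  shell <- if (options$shell) shell_correction(st, mat) else 0
  if (options$barkas || options$bloch) {
    bb <- barkas_bloch_terms(proj, st, mat, F0 = options$barkas_F0)
  } else bb <- list(L1 = 0, L2 = 0)
  L1 <- if (options$barkas) bb$L1 else 0
  L2 <- if (options$bloch) bb$L2 else 0
  mott_on <- if (is.null(options$mott)) proj$z >= 3 else options$mott
  KM <- mott_correction(proj, st, enabled = mott_on, c_M = options$mott_c)

  bracket <- log(2 * me * st$beta^2 * Tup / (I^2 * (1 - st$beta^2))) -
    st$beta^2 * (1 + Tup / Tm) +
    2 * zeff * L1 + 2 * zeff^2 * L2 + KM - 2 * shell - delta
  if (any(bracket <= 0))
    stop("non-positive stopping bracket at E = ",
         paste(signif(E[bracket <= 0], 4), collapse = ", "),
         " MeV/u in ", mat$name)
  pref <- 2 * pi * mat$electron_density * const$classical_electron_radius^2 *
    me * zeff^2 / st$beta^2           # MeV/cm
  pref * bracket / mat$density        # MeV cm^2/g
}

#' Restricted stopping power below a delta-ray threshold
#'
#' Mean energy loss per unit mass thickness restricted to transfers below
#' `delta_threshold`: the kinematic maximum in the logarithm is replaced
#' by \eqn{T_{up} = \min(T_{max}, T_{cut})} and the velocity term becomes
#' \eqn{-\beta^2 (1 + T_{up}/T_{max})}. Equals the unrestricted value
#' whenever the threshold exceeds Tmax. Thresholds may be as low as 1 keV.
#'
#' @inheritParams electronic_stopping_power
#' @param delta_threshold delta-ray production threshold, MeV (>= 1e-3).
#' @return MeV cm^2/g.
#' @export
restricted_stopping_power <- function(E, proj, mat, delta_threshold,
                                      options = stopping_options()) {
  if (delta_threshold < 1e-3)
    stop("delta-ray threshold below 1 keV is not supported")
  if (any(E < .energy_domain[1] | E > .energy_domain[2]))
    stop("energy outside the operating domain")
  lo <- E < .bethe_switch
  S <- numeric(length(E))
  if (any(!lo)) S[!lo] <- .bethe_eq1(E[!lo], proj, mat, options, tcut = delta_threshold)
  if (any(lo)) {
    s0 <- .bethe_eq1(.bethe_switch, proj, mat, options, tcut = delta_threshold)
    S[lo] <- s0 * sqrt(E[lo] / .bethe_switch)
  }
  S
}

#' CSDA range
#'
#' Continuous-slowing-down-approximation range in mass thickness,
#' \eqn{R(E) = \int_0^E A\, dE'/S(E')} (g/cm^2), by adaptive quadrature at
#' relative tolerance 1e-6. The sub-0.01 MeV/u contribution uses the
#' velocity-proportional branch analytically (it is a few micrometers of
#' water).
#'
#' @inheritParams electronic_stopping_power
#' @return g/cm^2 (vectorized over `E`); 0 at E = 0.
#' @examples
#' csda_range(150, projectile("proton"), material_water())  # ~15.8 g/cm^2
#' @export
csda_range <- function(E, proj, mat, options = stopping_options()) {
  emin <- .energy_domain[1]
  s_at <- function(e) electronic_stopping_power(e, proj, mat, options)
  one <- function(e) {
    if (e <= 0) return(0)
    if (e <= emin) {
      # S ~ sqrt(E): integral = 2 e / S(e)
      s0 <- s_at(emin) * sqrt(e / emin)
      return(proj$A * 2 * e / s0)
    }
    tail <- proj$A * 2 * emin / s_at(emin)
    q <- tryCatch(
      stats::integrate(function(x) proj$A / s_at(x), emin, e,
                       rel.tol = 1e-6, subdivisions = 400L),
      error = function(err)
        stop("range quadrature failed on [", emin, ", ", e, "] MeV/u: ",
             conditionMessage(err)))
    tail + q$value
  }
  vapply(E, one, 0.0)
}

#' Precompute a stopping table for transport
#'
#' Evaluates unrestricted and restricted stopping, CSDA range and
#' effective charge on a log-spaced energy grid (default 200 points per
#' decade) for fast monotone interpolation inside the transport kernel.
#'
#' @inheritParams restricted_stopping_power
#' @param E_max top of the grid, MeV/u.
#' @param points_per_decade grid density.
#' @return data.frame with columns `E_MeV_u`, `S_el`, `S_restricted`,
#'   `range_g_cm2`, `z_eff`.
#' @export
stopping_table <- function(proj, mat, delta_threshold = 0.1,
                           E_max = 500, points_per_decade = 200,
                           options = stopping_options()) {
  emin <- .energy_domain[1]
  n <- ceiling(log10(E_max / emin) * points_per_decade) + 1
  E <- exp(seq(log(emin), log(E_max), length.out = n))
  st <- kinematics_from_energy(E, proj)
  S <- electronic_stopping_power(E, proj, mat, options)
  # cumulative trapezoid of A/S on the dense grid (matches the adaptive
  # quadrature of csda_range to well below the grid interpolation error)
  f <- proj$A / S
  rng <- c(0, cumsum(0.5 * (f[-1] + f[-n]) * diff(E))) + proj$A * 2 * emin / S[1]
  data.frame(
    E_MeV_u = E,
    S_el = S,
    S_restricted = restricted_stopping_power(E, proj, mat, delta_threshold, options),
    range_g_cm2 = rng,
    z_eff = effective_charge(proj, st, k = options$barkas_k))
}

#' Export a stopping table as CSV
#'
#' @param table a [stopping_table()].
#' @param path output CSV path.
#' @export
write_stopping_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
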