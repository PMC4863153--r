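#' Beam specification
#'
#' Pencil-beam source: particle species, nominal kinetic energy per
#' nucleon with optional Gaussian energy spread, Gaussian spot size, start
#' position and direction (the conventional beam axis is +z).
#'
#' @param proj a [projectile_spec()].
#' @param nominal_energy MeV/u.
#' @param energy_sigma Gaussian sigma of the energy spectrum, MeV/u.
#' @param spot_sigma_x,spot_sigma_y Gaussian spot sigmas, mm.
#' @param position start position, mm; x and y are offsets from the
#'   phantom's transverse center (the beam axis through a centered pencil
#'   beam is x = y = 0), z is absolute (0 = entrance face; default 1 mm
#'   upstream).
#' @param direction unit vector (normalized here).
#' @param n_primaries number of primaries (>= 1).
#' @return object of class `beam_spec`.
#' @export
beam_spec <- function(proj, nominal_energy, energy_sigma = 0,
                      spot_sigma_x = 0, spot_sigma_y = 0,
                      position = c(0, 0, -1), direction = c(0, 0, 1),
                      n_primaries = 1e4) {
  stopifnot(inherits(proj, "projectile_spec"), nominal_energy > 0,
            energy_sigma >= 0, spot_sigma_x >= 0, spot_sigma_y >= 0,
            length(position) == 3, length(direction) == 3, n_primaries >= 1)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be a non-zero vector")
  structure(list(projectile = proj, nominal_energy = nominal_energy,
                 energy_sigma = energy_sigma,
                 spot_sigma_x = spot_sigma_x, spot_sigma_y = spot_sigma_y,
                 position = as.numeric(position),
                 direction = as.numeric(direction) / nrm,
                 n_primaries = as.integer(n_primaries)),
            class = "beam_spec")
}

#' Transport configuration
#'
#' All condensed-history knobs: step control, delta-ray threshold,
#' straggling / multiple-scattering / nuclear model selection, the
#' fragment-tail surrogate parameters and the RNG seed.
#'
#' @param max_fractional_energy_loss maximum expected fractional energy
#'   loss per step (0 < f <= 0.05).
#' @param delta_threshold delta-ray production threshold, MeV (>= 1 keV);
#'   losses below it are treated as continuous (restricted stopping).
#' @param straggling_model `"gaussian"` (Bohr) or `"none"`.
#' @param mcs_model `"highland"` or `"none"`.
#' @param nuclear_model `"attenuation+tail"`, `"attenuation"` or `"none"`.
#' @param tail_params list with `local_fraction`, `tail_mfp` (cm),
#'   `forward_dose_fraction`; fractions in \[0, 1\] with sum <= 1. Defaults
#'   (0.6, 2 cm, 0.3) reproduce the qualitative forward fragment-tail
#'   build-up only and are not fitted to any nuclear event generator.
#' @param rng_seed integer seed.
#' @param n_batches batches for statistical uncertainties.
#' @param energy_cutoff MeV/u below which the residual energy is deposited
#'   locally.
#' @param fluence_bins number of log-spaced energy bins for the scored
#'   per-depth fluence spectra.
#' @return object of class `transport_config`.
#' @export
transport_config <- function(max_fractional_energy_loss = 0.02,
                             delta_threshold = 0.1,
                             straggling_model = c("gaussian", "none"),
                             mcs_model = c("highland", "none"),
                             nuclear_model = c("attenuation+tail", "attenuation", "none"),
                             tail_params = list(local_fraction = 0.6,
                                                tail_mfp = 2,
                                                forward_dose_fraction = 0.3),
                             rng_seed = 1L, n_batches = 10L,
                             energy_cutoff = 0.1, fluence_bins = 60L) {
  stopifnot(max_fractional_energy_loss > 0, max_fractional_energy_loss <= 0.05,
            delta_threshold >= 1e-3,
            tail_params$local_fraction >= 0, tail_params$local_fraction <= 1,
            tail_params$forward_dose_fraction >= 0,
            tail_params$local_fraction + tail_params$forward_dose_fraction <= 1,
            tail_params$tail_mfp > 0, n_batches >= 1)
  structure(list(max_fractional_energy_loss = max_fractional_energy_loss,
                 delta_threshold = delta_threshold,
                 straggling_model = match.arg(straggling_model),
                 mcs_model = match.arg(mcs_model),
                 nuclear_model = match.arg(nuclear_model),
                 tail_params = tail_params, rng_seed = as.integer(rng_seed),
                 n_batches = as.integer(n_batches),
                 energy_cutoff = energy_cutoff,
                 fluence_bins = as.integer(fluence_bins)),
            class = "transport_config")
}

#' Condensed-history step length
#'
#' The step is capped so that the expected energy loss does not exceed
#' `max_fractional_energy_loss` of the current kinetic energy, and by the
#' remaining chord inside the current voxel. Zero-density voxels are
#' crossed as vacuum drift (step = chord, no loss).
#'
#' @param E kinetic energy, MeV/u.
#' @param mat a [material()] of the current voxel.
#' @param config a [transport_config()].
#' @param proj a [projectile_spec()].
#' @param density_scale per-voxel density multiplier.
#' @param chord remaining chord in the voxel, cm.
#' @return step length in cm (positive).
#' @export
choose_step <- function(E, mat, config, proj, density_scale = 1, chord = Inf) {
  stopifnot(E > 0)
  rho <- mat$density * density_scale
  if (rho <= 0) return(chord)  # vacuum drift
  S <- restricted_stopping_power(E, proj, mat, config$delta_threshold)
  step <- config$max_fractional_energy_loss * (E * proj$A) / (S * rho)
  max(min(step, chord), 1e-6)
}

#' Bohr variance of the energy-loss straggling
#'
#' Gaussian straggling variance over a path `step`:
#' \deqn{\sigma^2 = 0.1569\, z_{eff}^2\, (Z/A)\, \rho\, \Delta x\,
#'   \frac{1-\beta^2/2}{1-\beta^2} \quad [\mathrm{MeV}^2]}
#' with `rho dx` in g/cm^2 (the 0.1569 MeV^2 cm^2/g coefficient is
#' \eqn{4\pi r_e^2 (m_e c^2)^2 N_{Av}}).
#'
#' @inheritParams choose_step
#' @param step path length, cm.
#' @return variance in MeV^2.
#' @export
bohr_straggling_variance <- function(E, proj, mat, step, density_scale = 1) {
  st <- kinematics_from_energy(E, proj)
  zeff <- effective_charge(proj, st)
  0.1569 * zeff^2 * mat$z_over_a * mat$density * density_scale * step *
    (1 - st$beta^2 / 2) / (1 - st$beta^2)
}

#' Sample a fluctuating energy loss over a step
#'
#' Gaussian surrogate for collision straggling: mean equal to the
#' restricted mean loss, variance from [bohr_straggling_variance()],
#' truncated to \[0, E A\]. With `straggling_model = "none"` the mean is
#' returned deterministically. Uses R's RNG stream.
#'
#' @param mean_loss mean energy loss over the step, MeV (>= 0).
#' @inheritParams bohr_straggling_variance
#' @param config a [transport_config()].
#' @param n number of samples.
#' @return sampled energy losses, MeV.
#' @export
sample_energy_loss <- function(mean_loss, E, proj, mat, step, config,
                               density_scale = 1, n = 1) {
  stopifnot(mean_loss >= 0)
  if (config$straggling_model == "none") return(rep(mean_loss, n))
  s <- sqrt(bohr_straggling_variance(E, proj, mat, step, density_scale))
  pmin(pmax(stats::rnorm(n, mean_loss, s), 0), E * proj$A)
}

#' Highland multiple-scattering angle
#'
#' Standard deviation of the projected scattering angle over a step of
#' mass thickness `t` (g/cm^2):
#' \deqn{\theta_0 = \frac{13.6\,\mathrm{MeV}}{\beta c p} z
#'   \sqrt{t/X_0}\,[1 + 0.038 \ln(t/X_0)]}
#' with the material radiation length \eqn{X_0} computed from the
#' composition.
#'
#' @inheritParams choose_step
#' @param step path length, cm.
#' @return theta0 in radians (0 when `t/X0 <= 0`).
#' @export
highland_theta0 <- function(E, proj, mat, step, density_scale = 1) {
  t_over_x0 <- step * mat$density * density_scale / mat$radiation_length
  if (t_over_x0 <= 0) return(0)
  st <- kinematics_from_energy(E, proj)
  p <- st$gamma * proj$mass * st$beta   # MeV/c
  th <- 13.6 / (st$beta * p) * proj$z * sqrt(t_over_x0) *
    (1 + 0.038 * log(t_over_x0))
  max(th, 0)
}

#' Sample multiple-Coulomb-scattering deflections
#'
#' Independent zero-mean Gaussian projected angles in two transverse
#' planes with the Highland width; `mcs_model = "none"` returns zeros.
#'
#' @inheritParams highland_theta0
#' @param config a [transport_config()].
#' @param n number of samples.
#' @return n x 2 matrix of (theta_x, theta_y) in radians.
#' @export
sample_mcs_deflection <- function(E, proj, step, mat, config,
                                  density_scale = 1, n = 1) {
  stopifnot(step >= 0)
  if (config$mcs_model == "none" || step == 0)
    return(matrix(0, n, 2, dimnames = list(NULL, c("theta_x", "theta_y"))))
  th0 <- highland_theta0(E, proj, mat, step, density_scale)
  matrix(stats::rnorm(2 * n, 0, th0), n, 2,
         dimnames = list(NULL, c("theta_x", "theta_y")))
}

#' Default inelastic nuclear cross sections
#'
#' Packaged phenomenological projectile-element inelastic cross sections:
#' a Bradt-Peters geometric plateau
#' \eqn{\sigma_g = \pi r_0^2 (A_p^{1/3} + A_t^{1/3} - b)^2}
#' (r0 = 1.36 fm, b = 1.04) with a threshold rise
#' \eqn{\sigma(E) = \sigma_g (1 - e^{-(E - E_{thr})/25})} above
#' `E_thr = 8` MeV/u. These are surrogates for evaluated nuclear data and
#' can be replaced by per-reaction CSV tables.
#'
#' @param proj a [projectile_spec()].
#' @param A_t target mass number (vectorized).
#' @param E energy grid, MeV/u.
#' @return matrix (length(E) x length(A_t)) of cross sections in mb.
#' @export
default_inelastic_sigma <- function(proj, A_t, E) {
  sg <- pi * 1.36^2 * (proj$A^(1 / 3) + A_t^(1 / 3) - 1.04)^2 * 10  # mb
  rise <- pmax(0, 1 - exp(-(E - 8) / 25))
  outer(rise, sg)
}

#' Nuclear mean free path in a material
#'
#' \eqn{\lambda(E) = 1 / \sum_i n_i \sigma_i(E)} over the material's
#' elements, with per-element number densities at nominal density and
#' inelastic cross sections from `sigma_fun` (default
#' [default_inelastic_sigma()]).
#'
#' @inheritParams choose_step
#' @param sigma_fun function `(proj, A_t, E) -> mb matrix`; supply a table
#'   interpolator to use evaluated cross sections.
#' @return mean free path in cm (vectorized over `E`).
#' @export
nuclear_mean_free_path <- function(proj, E, mat, sigma_fun = default_inelastic_sigma) {
  stopifnot(all(E > 0))
  const <- physical_constants()
  n_i <- mat$density * const$avogadro * mat$elements$w / mat$elements$A  # 1/cm^3
  sig <- sigma_fun(proj, mat$elements$A, E) * 1e-27  # mb -> cm^2
  inv <- as.numeric(sig %*% n_i)
  if (any(inv <= 0)) return(ifelse(inv > 0, 1 / inv, Inf))
  1 / inv
}

#' Energy bookkeeping of a nuclear interaction
#'
#' When a primary undergoes an inelastic nuclear interaction it is
#' removed; its residual kinetic energy is split into a locally deposited
#' fraction, a forward fragment-tail fraction deposited exponentially
#' downstream with decay length `tail_mfp`, and an escaping remainder.
#' Every MeV is accounted to exactly one of the three channels.
#'
#' @param E_residual residual kinetic energy, MeV.
#' @param config a [transport_config()].
#' @return list with `local`, `tail`, `escaped` (MeV, summing to
#'   `E_residual`) and `tail_mfp` (cm).
#' @export
apply_nuclear_interaction <- function(E_residual, config) {
  tp <- config$tail_params
  if (config$nuclear_model == "attenuation")
    return(list(local = 0, tail = 0, escaped = E_residual,
                tail_mfp = tp$tail_mfp))
  local <- tp$local_fraction * E_residual
  tail <- tp$forward_dose_fraction * E_residual
  list(local = local, tail = tail, escaped = E_residual - local - tail,
       tail_mfp = tp$tail_mfp)
}
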