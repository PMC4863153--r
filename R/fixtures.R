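# Deterministic fixture generators: toy radiobiological tables, toy
# cross sections and analytic test curves used by examples and tests.

#' Fixture LQ tables
#'
#' Deterministic toy radiobiological databases for tests and examples.
#' The carbon-like table has alpha rising steeply as the energy falls
#' (high-LET behavior toward the Bragg peak); the proton-like table is
#' nearly photon-like with a mild low-energy rise. Both have
#' beta = 0.05 Gy^-2, matching the photon reference beta so the
#' RBE-weighted dose never falls below the absorbed dose. These are
#' shaped fixtures, not LEM-derived data; real tables are user-supplied.
#'
#' @param energy energy grid, MeV/u.
#' @return an [lq_table()].
#' @export
lq_table_carbon_like <- function(energy = exp(seq(log(0.1), log(500),
                                                  length.out = 80))) {
  alpha <- 0.1 + 0.9 / (1 + (energy / 20)^1.5)
  beta <- rep(0.05, length(energy))
  lq_table("carbon", energy, alpha, beta)
}

#' @rdname lq_table_carbon_like
#' @export
lq_table_proton_like <- function(energy = exp(seq(log(0.1), log(500),
                                                   length.out = 80))) {
  alpha <- 0.1 + 0.04 / (1 + (energy / 5)^2)
  beta <- rep(0.05, length(energy))
  lq_table("proton", energy, alpha, beta)
}

#' Fixture reaction cross sections for PET emitter production
#'
#' Analytic threshold-plateau excitation functions shaped like the
#' dominant proton-induced beta+ production channels in tissue:
#' a smooth rise above threshold to a broad plateau with a slow fall.
#' Values are fixture-scale surrogates, not evaluated nuclear data.
#'
#' @param reaction `"16O(p,x)15O"` or `"12C(p,x)11C"`.
#' @return an [xs_table()] (half-lives 122.24 s for 15O, 1221.8 s for 11C).
#' @export
fixture_xs_table <- function(reaction = c("16O(p,x)15O", "12C(p,x)11C")) {
  reaction <- match.arg(reaction)
  E <- seq(0, 250, by = 2)
  shape <- function(thr, peak, sig_peak) {
    s <- ifelse(E <= thr, 0,
                sig_peak * (1 - exp(-(E - thr) / 8)) / (1 + ((E - thr) / 120)^1.2))
    pmax(s, 0)
  }
  if (reaction == "16O(p,x)15O")
    xs_table(reaction, "15O", half_life = 122.24, target_Z = 8, target_A = 16,
             energy = E, sigma = shape(16.6, 40, 70))
  else
    xs_table(reaction, "11C", half_life = 1221.8, target_Z = 6, target_A = 12,
             energy = E, sigma = shape(20.3, 45, 90))
}

#' Analytic Bragg-like test curve
#'
#' Deterministic depth-dose shape with a known peak position: an entrance
#' plateau rising into a Gaussian peak at `peak_mm` with width `width_mm`,
#' then a sharp distal falloff. Useful as a metrics fixture with an exact
#' known maximum.
#'
#' @param peak_mm peak depth.
#' @param width_mm Gaussian sigma of the peak.
#' @param depth_mm depth grid (default 0.5 mm steps to 1.3 x peak).
#' @param entrance entrance-plateau level relative to the peak.
#' @return a `depth_dose_curve`.
#' @export
analytic_bragg_curve <- function(peak_mm = 150, width_mm = 3,
                                 depth_mm = seq(0.5, peak_mm * 1.3, by = 0.5),
                                 entrance = 0.25) {
  rise <- entrance * (1 + 0.25 * depth_mm / peak_mm)
  peak <- exp(-0.5 * ((depth_mm - peak_mm) / width_mm)^2)
  dose <- ifelse(depth_mm <= peak_mm, pmax(rise, peak), peak)
  structure(list(depth_mm = depth_mm, dose = dose,
                 sigma = rep(0, length(depth_mm))),
            class = "depth_dose_curve")
}

#' Water column phantom for depth-dose work
#'
#' Single-voxel-cross-section water column along z: the standard geometry
#' for laterally integrated depth-dose curves (all lateral spread stays
#' inside the one transverse voxel).
#'
#' @param length_mm column length.
#' @param dz_mm slice thickness.
#' @param width_mm transverse voxel size (large enough to contain the
#'   scattered beam).
#' @return a `voxel_phantom`.
#' @export
water_column_phantom <- function(length_mm = 300, dz_mm = 1, width_mm = 200) {
  make_slab_phantom(list(list(material = "water", thickness = length_mm)),
                    cross_section = width_mm,
                    spacing = c(width_mm, width_mm, dz_mm))
}
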