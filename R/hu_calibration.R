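#' Hounsfield unit from linear attenuation coefficients
#'
#' CT numbers are a linear transformation of the X-ray attenuation
#' coefficient relative to distilled water:
#' \deqn{HU = 1000 (\mu_x - \mu_{H_2O}) / (\mu_{H_2O} - \mu_{air})}
#' so air maps to -1000 and water to 0.
#'
#' @param mu_x attenuation coefficient of the voxel, 1/cm.
#' @param mu_water,mu_air attenuation coefficients of water and air, 1/cm.
#' @return Hounsfield units (vectorized over `mu_x`).
#' @examples
#' hounsfield_from_mu(0.05, 0.19, 0.05)  # air -> -1000
#' @export
hounsfield_from_mu <- function(mu_x, mu_water, mu_air) {
  stopifnot(all(mu_x >= 0), mu_water >= 0, mu_air >= 0)
  d <- mu_water - mu_air
  if (abs(d) < .Machine$double.eps * max(1, abs(mu_water)))
    stop("degenerate HU denominator: mu_water = ", mu_water,
         ", mu_air = ", mu_air)
  1000 * (mu_x - mu_water) / d
}

#' Read a Hounsfield-unit calibration from CSV tables
#'
#' A calibration segments the HU axis into half-open intervals
#' `[hu_low, hu_high)` (the last interval is closed), each assigned to a
#' material of fixed elemental composition plus a linear continuous
#' density scaling in HU: `density(hu) = nominal_density +
#' density_slope * (hu - center)`. Construction validates that segments
#' tile the HU range with no gaps or overlaps and that every density
#' inside every segment is non-negative.
#'
#' @param segments_csv CSV with columns `hu_low`, `hu_high`, `material`,
#'   `nominal_density`, `density_slope`.
#' @param materials_csv CSV with columns `material`, `symbol`, `Z`, `A`,
#'   `mass_fraction`, `ref_density_g_cm3`.
#' @return An object of class `hu_calibration` with fields `segments`
#'   (data.frame), `materials` (named list of [material()]), `hu_min`,
#'   `hu_max`.
#' @export
read_hu_calibration <- function(segments_csv, materials_csv) {
  seg <- utils::read.csv(segments_csv, stringsAsFactors = FALSE)
  mats <- utils::read.csv(materials_csv, stringsAsFactors = FALSE)
  need <- c("hu_low", "hu_high", "material", "nominal_density", "density_slope")
  if (!all(need %in% names(seg)))
    stop("segment table must have columns: ", paste(need, collapse = ", "))
  seg <- seg[order(seg$hu_low), ]
  if (any(seg$hu_low >= seg$hu_high))
    stop("segment with hu_low >= hu_high")
  gaps <- which(abs(seg$hu_high[-nrow(seg)] - seg$hu_low[-1]) > 1e-9)
  if (length(gaps))
    stop("calibration has gaps/overlaps at HU = ",
         paste(seg$hu_high[gaps], collapse = ", "))
  # density must stay >= 0 over each full interval
  ctr <- (seg$hu_low + seg$hu_high) / 2
  d_lo <- seg$nominal_density + seg$density_slope * (seg$hu_low - ctr)
  d_hi <- seg$nominal_density + seg$density_slope * (seg$hu_high - ctr)
  if (any(pmin(d_lo, d_hi) < 0))
    stop("negative density inside segment(s) ",
         paste(which(pmin(d_lo, d_hi) < 0), collapse = ", "))

  mat_objs <- lapply(split(mats, mats$material), function(df) {
    material(df$material[1], df$symbol, df$mass_fraction,
             density = df$ref_density_g_cm3[1])
  })
  missing <- setdiff(seg$material, names(mat_objs))
  if (length(missing))
    stop("segments reference undefined material(s): ",
         paste(missing, collapse = ", "))

  structure(list(segments = seg, materials = mat_objs,
                 hu_min = min(seg$hu_low), hu_max = max(seg$hu_high)),
            class = "hu_calibration")
}

#' Default stoichiometric HU calibration
#'
#' The packaged table follows the stoichiometric segmentation approach of
#' Schneider-style CT calibrations: 24 materials of fixed elemental
#' composition over 41 HU intervals covering \[-1000, 3500\], with a
#' continuous linear density scaling inside each interval. The packaged
#' compositions are a synthetic reconstruction (tissue compositions from
#' standard reference-tissue tables; the skeletal series as
#' marrow-to-cortical-bone blends), not a copy of any published table;
#' facility-specific calibrations can replace it via
#' [read_hu_calibration()].
#'
#' @return An `hu_calibration`.
#' @examples
#' cal <- build_default_calibration()
#' nrow(cal$segments)              # 41
#' length(cal$materials)           # 24
#' @export
build_default_calibration <- function() {
  read_hu_calibration(
    system.file("extdata", "hu_segments.csv", package = "iondose"),
    system.file("extdata", "hu_materials.csv", package = "iondose"))
}

#' Look up material and density for HU values
#'
#' HU values outside the calibrated range are clamped to the nearest
#' bound with a warning. Interval membership is half-open
#' `[hu_low, hu_high)`; the last interval includes its upper edge.
#'
#' @param hu numeric vector of Hounsfield units.
#' @param calibration an `hu_calibration`.
#' @return data.frame with columns `material` (id) and `density` (g/cm^3).
#' @export
material_at <- function(hu, calibration) {
  stopifnot(inherits(calibration, "hu_calibration"))
  if (any(!is.finite(hu))) stop("non-finite HU value(s)")
  out_lo <- hu < calibration$hu_min
  out_hi <- hu > calibration$hu_max
  if (any(out_lo | out_hi)) {
    warning(sum(out_lo | out_hi), " HU value(s) outside [",
            calibration$hu_min, ", ", calibration$hu_max,
            "] clamped to the nearest bound")
    hu <- pmin(pmax(hu, calibration$hu_min), calibration$hu_max)
  }
  seg <- calibration$segments
  idx <- findInterval(hu, c(seg$hu_low, calibration$hu_max),
                      rightmost.closed = TRUE)
  ctr <- (seg$hu_low[idx] + seg$hu_high[idx]) / 2
  data.frame(material = seg$material[idx],
             density = seg$nominal_density[idx] +
                       seg$density_slope[idx] * (hu - ctr),
             stringsAsFactors = FALSE)
}

#' Build a voxel phantom from a HU grid
#'
#' Maps every voxel through [material_at()] and stores, per voxel, the
#' material index and a density scale factor relative to the material's
#' reference density. The same scale multiplies the electronic and the
#' nuclear interaction densities during transport.
#'
#' @param hu_grid 3D array of HU values.
#' @param spacing voxel spacing in mm (scalar or length-3).
#' @param calibration an `hu_calibration`, default [build_default_calibration()].
#' @return A `voxel_phantom` (see [voxel_phantom()]).
#' @export
phantom_from_hu <- function(hu_grid, spacing, calibration = build_default_calibration()) {
  if (length(dim(hu_grid)) != 3L) stop("hu_grid must be a 3D array")
  bad <- which(!is.finite(hu_grid))
  if (length(bad))
    stop("non-finite HU at linear indices: ",
         paste(utils::head(bad, 10), collapse = ", "))
  m <- material_at(as.numeric(hu_grid), calibration)
  mat_names <- names(calibration$materials)
  mat_idx <- match(m$material, mat_names)
  ref_density <- vapply(calibration$materials, function(x) x$density, 0.0)
  scale <- m$density / ref_density[mat_idx]
  scale[scale <= 0] <- 1e-9  # density_scale must stay positive
  voxel_phantom(array(mat_idx, dim = dim(hu_grid)),
                array(scale, dim = dim(hu_grid)),
                calibration$materials, spacing)
}
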