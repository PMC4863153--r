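#' Linear-quadratic coefficient table for one species
#'
#' Radiobiological input for the mixed-field bookkeeping: cell-survival
#' LQ coefficients alpha(E) and beta(E) of a particle species as a
#' function of kinetic energy per nucleon. Interpolation is log-linear in
#' energy; outside the grid the edge values are used (with a warning), so
#' interpolated values never leave the tabulated range
#' (monotone-preserving).
#'
#' @param species label, e.g. `"carbon"`.
#' @param energy strictly increasing energy grid, MeV/u.
#' @param alpha Gy^-1 (>= 0).
#' @param beta Gy^-2 (>= 0).
#' @return object of class `lq_table`.
#' @export
lq_table <- function(species, energy, alpha, beta) {
  stopifnot(length(energy) == length(alpha), length(energy) == length(beta),
            all(diff(energy) > 0), all(alpha >= 0), all(beta >= 0))
  structure(list(species = species, energy = energy, alpha = alpha,
                 beta = beta), class = "lq_table")
}

#' @rdname lq_table
#' @param path CSV with columns `species`, `E_MeV_u`, `alpha_Gy^-1` (or
#'   `alpha`), `beta_Gy^-2` (or `beta`).
#' @export
read_lq_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  al <- df[["alpha_Gy^-1"]] %||% df[["alpha"]]
  be <- df[["beta_Gy^-2"]] %||% df[["beta"]]
  lq_table(df$species[1], df$E_MeV_u, al, be)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname lq_table
#' @param table an `lq_table`.
#' @export
write_lq_table <- function(table, path) {
  utils::write.csv(
    data.frame(species = table$species, E_MeV_u = table$energy,
               `alpha_Gy^-1` = table$alpha, `beta_Gy^-2` = table$beta,
               check.names = FALSE),
    path, row.names = FALSE)
  invisible(path)
}

#' Interpolate LQ coefficients at energies
#'
#' @param table an [lq_table()].
#' @param E energies, MeV/u.
#' @param warn warn when clamping outside the tabulated range.
#' @return list with vectors `alpha`, `beta`.
#' @export
lq_interp <- function(table, E, warn = FALSE) {
  if (warn && (any(E < table$energy[1]) || any(E > utils::tail(table$energy, 1))))
    warning("LQ coefficients clamped to the tabulated energy range")
  le <- log(pmin(pmax(E, table$energy[1]), utils::tail(table$energy, 1)))
  lg <- log(table$energy)
  list(alpha = stats::approx(lg, table$alpha, le, rule = 2)$y,
       beta = stats::approx(lg, table$beta, le, rule = 2)$y)
}

#' Photon reference radiosensitivity
#'
#' Reference photon LQ parameters; the default is the representative cell
#' line with alpha/beta = 2 Gy (alpha = 0.1 Gy^-1, beta = 0.05 Gy^-2).
#'
#' @param alpha_ph Gy^-1 (> 0).
#' @param beta_ph Gy^-2 (> 0).
#' @return list with `alpha_ph`, `beta_ph`.
#' @export
photon_reference <- function(alpha_ph = 0.1, beta_ph = 0.05) {
  stopifnot(alpha_ph > 0, beta_ph > 0)
  list(alpha_ph = alpha_ph, beta_ph = beta_ph)
}

#' Mixed-field accumulator
#'
#' Per-voxel running sums of dose, dose x alpha and dose x beta over all
#' particles depositing dose, the bookkeeping behind the dose-weighted
#' averages
#' \deqn{\bar\alpha_j = \frac{\sum_i \Delta d_{i,j}\,\alpha_{i,j}}
#'  {\sum_i \Delta d_{i,j}}}
#' (and identically for beta). Sums are plain commutative additions, so
#' the result is independent of deposit order.
#'
#' @param n_voxels number of voxels tracked.
#' @param tables named list of [lq_table()] objects keyed by species.
#' @return object of class `mixed_field_accumulator`.
#' @export
mixed_field_accumulator <- function(n_voxels, tables) {
  if (inherits(tables, "lq_table")) {
    tables <- stats::setNames(list(tables), tables$species)
  }
  structure(list(sum_d = numeric(n_voxels), sum_da = numeric(n_voxels),
                 sum_db = numeric(n_voxels), tables = tables),
            class = "mixed_field_accumulator")
}

#' Add a dose deposit to the accumulator
#'
#' @param acc a [mixed_field_accumulator()].
#' @param voxel voxel index (1-based).
#' @param dose_i deposited dose, Gy (>= 0).
#' @param species species label (must exist in the accumulator's tables).
#' @param E kinetic energy of the depositing particle, MeV/u.
#' @return the updated accumulator.
#' @export
accumulate <- function(acc, voxel, dose_i, species, E) {
  stopifnot(inherits(acc, "mixed_field_accumulator"), all(dose_i >= 0))
  tab <- acc$tables[[species]]
  if (is.null(tab)) stop("no LQ table for species '", species, "'")
  lq <- lq_interp(tab, E)
  acc$sum_d[voxel] <- acc$sum_d[voxel] + dose_i
  acc$sum_da[voxel] <- acc$sum_da[voxel] + dose_i * lq$alpha
  acc$sum_db[voxel] <- acc$sum_db[voxel] + dose_i * lq$beta
  acc
}

#' Dose-weighted average LQ coefficients
#'
#' Ratio of the accumulated sums. Voxels with zero dose return `NA`
#' (a defined null, never propagating NaN arithmetic).
#'
#' @param acc a [mixed_field_accumulator()] or the `mixed_field` element
#'   of a `dose_grid`.
#' @param voxel optional voxel indices (default: all).
#' @return numeric vector of alpha-bar (Gy^-1) / beta-bar (Gy^-2).
#' @export
alpha_bar <- function(acc, voxel = NULL) {
  d <- acc$sum_d; da <- acc$sum_da
  if (!is.null(voxel)) { d <- d[voxel]; da <- da[voxel] }
  out <- rep(NA_real_, length(d))
  pos <- which(d > 0)
  out[pos] <- da[pos] / d[pos]
  out
}

#' @rdname alpha_bar
#' @export
beta_bar <- function(acc, voxel = NULL) {
  d <- acc$sum_d; db <- acc$sum_db
  if (!is.null(voxel)) { d <- d[voxel]; db <- db[voxel] }
  out <- rep(NA_real_, length(d))
  pos <- which(d > 0)
  out[pos] <- db[pos] / d[pos]
  out
}

#' RBE-weighted dose from mixed-field LQ averages
#'
#' The biological effect of the mixed field is
#' \eqn{\epsilon = \bar\alpha D + \bar\beta D^2}; the RBE-weighted dose is
#' the photon dose producing the same effect, from inverting the photon
#' LQ curve:
#' \deqn{D_{RBE} = \sqrt{\Big(\frac{\alpha_{ph}}{2\beta_{ph}}\Big)^2 +
#'   \frac{\epsilon}{\beta_{ph}}} - \frac{\alpha_{ph}}{2\beta_{ph}}.}
#' When \eqn{(\bar\alpha, \bar\beta)} equal the photon reference,
#' \eqn{D_{RBE} = D} identically.
#'
#' @param D absorbed dose, Gy (>= 0; vectorized).
#' @param abar,bbar mixed-field averages (vectorized).
#' @param ref a [photon_reference()].
#' @return RBE-weighted dose in Gy (RBE).
#' @export
rbe_weighted_dose <- function(D, abar, bbar, ref = photon_reference()) {
  stopifnot(all(D >= 0, na.rm = TRUE))
  eff <- abar * D + bbar * D^2
  if (any(eff < 0, na.rm = TRUE)) stop("negative biological effect")
  h <- ref$alpha_ph / (2 * ref$beta_ph)
  sqrt(h^2 + eff / ref$beta_ph) - h
}

#' @rdname rbe_weighted_dose
#' @return `rbe()` returns the ratio D_RBE / D (NA at zero dose).
#' @export
rbe <- function(D, abar, bbar, ref = photon_reference()) {
  drbe <- rbe_weighted_dose(D, abar, bbar, ref)
  ifelse(D > 0, drbe / D, NA_real_)
}

#' Constant clinical proton RBE
#'
#' Applies the constant factor 1.1 recommended for proton therapy: every
#' voxel of the input dose distribution is multiplied by exactly 1.1.
#'
#' @param dose numeric array / vector of absorbed dose, or a `dose_grid`.
#' @return the same structure with dose scaled by 1.1.
#' @export
proton_clinical_rbe <- function(dose) {
  if (inherits(dose, "dose_grid")) {
    dose$dose <- dose$dose * 1.1
    dose$energy <- dose$energy * 1.1
    return(dose)
  }
  dose * 1.1
}

# Gy per MeV/g
.gy_per_mev_g <- 1.602176634e-10

#' Extract an SOBP component from a simulated dose grid
#'
#' Collapses a mixed-field simulation to per-depth-slice profiles of
#' absorbed dose and the LQ sums, in Gy per primary, for use in
#' [optimize_sobp()].
#'
#' @param grid a `dose_grid` simulated with an `lq_table`.
#' @return list with `energy` (MeV/u), `depth_mm`, `d`, `da`, `db`
#'   (Gy per primary per slice, where the slice dose is the
#'   transverse-mass-weighted mean).
#' @export
sobp_component <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  if (is.null(grid$mixed_field))
    stop("simulate with an lq_table to build an SOBP component")
  ph <- grid$phantom
  nz <- ph$shape[3]
  ntr <- prod(ph$shape[1:2])
  # slice dose = total slice energy / slice mass (Gy per primary)
  rho <- vapply(ph$materials, function(m) m$density, 0.0)[ph$material_index] *
    ph$density_scale
  dim(rho) <- ph$shape
  mass <- rho * prod(ph$spacing / 10)
  wsum <- function(a) apply(a * mass, 3, sum) / apply(mass, 3, sum)
  list(energy = grid$beam$nominal_energy,
       depth_mm = (seq_len(nz) - 0.5) * ph$spacing[3],
       d = wsum(grid$mixed_field$sum_d) * .gy_per_mev_g,
       da = wsum(grid$mixed_field$sum_da) * .gy_per_mev_g,
       db = wsum(grid$mixed_field$sum_db) * .gy_per_mev_g)
}

#' Optimize pencil-beam weights for a flat RBE-weighted SOBP
#'
#' Finds non-negative weights (primaries per component) so that the
#' RBE-weighted dose of the mixed field is flat at `prescription` over the
#' target depth interval. The optimizer alternates two deterministic
#' steps: (1) with the current weights, compute the per-depth
#' \eqn{\bar\alpha,\bar\beta} and convert the prescribed photon-equivalent
#' effect into the physical dose \eqn{D^*(z)} that would produce it;
#' (2) update the weights toward \eqn{D^*} by multiplicative
#' image-space (ISRA-type) non-negative least-squares iterations. With
#' energy-independent coefficients equal to the photon reference this
#' reduces to plain non-negative least squares on the physical dose.
#'
#' @param components list of components from [sobp_component()] (all on
#'   the same depth grid).
#' @param target numeric length-2, target depth interval in mm.
#' @param prescription prescribed RBE-weighted dose, Gy (RBE).
#' @param ref a [photon_reference()].
#' @param max_outer,max_inner,tol iteration controls.
#' @return list with `weights` (primaries per component), `depth_mm`,
#'   `dose` (Gy), `d_rbe` (Gy (RBE)), `alpha_bar`, `beta_bar` profiles,
#'   `target`, `mean_deviation` and `max_deviation` (fractions of the
#'   prescription over the target grid points).
#' @export
optimize_sobp <- function(components, target, prescription,
                          ref = photon_reference(),
                          max_outer = 60, max_inner = 200, tol = 1e-12) {
  stopifnot(length(components) >= 1, length(target) == 2, prescription > 0)
  depth <- components[[1]]$depth_mm
  for (cc in components)
    if (!isTRUE(all.equal(cc$depth_mm, depth)))
      stop("components must share one depth grid")
  peaks <- vapply(components, function(cc) depth[which.max(cc$d)], 0.0)
  if (target[2] > max(peaks) + 2 * (depth[2] - depth[1]))
    stop("infeasible prescription: target extends to ", target[2],
         " mm but the deepest component peaks at ", max(peaks), " mm")

  sel <- which(depth >= target[1] & depth <= target[2])
  if (!length(sel)) stop("target interval contains no depth grid points")
  M <- vapply(components, function(cc) cc$d[sel], numeric(length(sel)))
  Ma <- vapply(components, function(cc) cc$da[sel], numeric(length(sel)))
  Mb <- vapply(components, function(cc) cc$db[sel], numeric(length(sel)))
  M <- cbind(M); Ma <- cbind(Ma); Mb <- cbind(Mb)

  eff_p <- ref$alpha_ph * prescription + ref$beta_ph * prescription^2
  K <- ncol(M)
  w <- rep(prescription / (K * mean(M[M > 0])), K)

  for (outer in seq_len(max_outer)) {
    D <- as.numeric(M %*% w)
    A <- as.numeric(Ma %*% w)
    B <- as.numeric(Mb %*% w)
    ab <- ifelse(D > 0, A / D, ref$alpha_ph)
    bb <- ifelse(D > 0, B / D, ref$beta_ph)
    # physical dose giving the prescribed effect with current alpha/beta
    Dstar <- ifelse(bb > 0,
                    (-ab + sqrt(ab^2 + 4 * bb * eff_p)) / (2 * bb),
                    eff_p / pmax(ab, 1e-12))
    w_old <- w
    MtD <- as.numeric(crossprod(M, Dstar))
    for (inner in seq_len(max_inner)) {
      denom <- as.numeric(crossprod(M, M %*% w))
      w_new <- w * MtD / pmax(denom, 1e-300)
      if (max(abs(w_new - w)) <= tol * max(abs(w), 1e-300)) { w <- w_new; break }
      w <- w_new
    }
    if (max(abs(w - w_old)) <= 1e-9 * max(abs(w))) break
  }

  # final profiles over the full depth axis
  Df <- as.numeric(vapply(components, function(cc) cc$d, numeric(length(depth))) %*% w)
  Af <- as.numeric(vapply(components, function(cc) cc$da, numeric(length(depth))) %*% w)
  Bf <- as.numeric(vapply(components, function(cc) cc$db, numeric(length(depth))) %*% w)
  abf <- ifelse(Df > 0, Af / Df, NA_real_)
  bbf <- ifelse(Df > 0, Bf / Df, NA_real_)
  drbe <- ifelse(Df > 0, rbe_weighted_dose(pmax(Df, 0), ifelse(is.na(abf), 0, abf),
                                           ifelse(is.na(bbf), 0, bbf), ref), 0)
  dev <- (drbe[sel] - prescription) / prescription
  list(weights = w, depth_mm = depth, dose = Df, d_rbe = drbe,
       alpha_bar = abf, beta_bar = bbf, target = target,
       prescription = prescription,
       mean_deviation = mean(dev), max_deviation = max(abs(dev)))
}
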