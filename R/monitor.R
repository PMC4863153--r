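#' Reaction cross-section table for beta+ emitter production
#'
#' Energy-dependent inelastic production cross section of one positron
#' emitter on one target nuclide, e.g. 16O(p,x)15O or 12C(p,x)11C, the two
#' dominant channels for PET monitoring of proton therapy. Cross sections
#' are zero below the reaction threshold.
#'
#' @param reaction label, e.g. `"16O(p,x)15O"`.
#' @param product isotope label, e.g. `"15O"`.
#' @param half_life seconds.
#' @param target_Z,target_A target nuclide (matched against phantom
#'   material compositions).
#' @param energy strictly increasing grid, MeV.
#' @param sigma cross sections, mb (>= 0).
#' @return object of class `xs_table`.
#' @export
xs_table <- function(reaction, product, half_life, target_Z, target_A,
                     energy, sigma) {
  stopifnot(all(diff(energy) > 0), all(sigma >= 0), half_life > 0)
  structure(list(reaction = reaction, product = product,
                 half_life = half_life, target_Z = target_Z,
                 target_A = target_A, energy = energy, sigma = sigma),
            class = "xs_table")
}

#' @rdname xs_table
#' @param path CSV with columns `E_MeV`, `sigma_mb` plus header columns
#'   `reaction`, `product`, `half_life_s`, `target_Z`, `target_A`.
#' @export
read_xs_table <- function(path) {
  df <- utils::read.csv(path)
  xs_table(df$reaction[1], df$product[1], df$half_life_s[1],
           df$target_Z[1], df$target_A[1], df$E_MeV, df$sigma_mb)
}

#' @rdname xs_table
#' @param table an `xs_table`.
#' @export
write_xs_table <- function(table, path) {
  utils::write.csv(data.frame(reaction = table$reaction,
                              product = table$product,
                              half_life_s = table$half_life,
                              target_Z = table$target_Z,
                              target_A = table$target_A,
                              E_MeV = table$energy, sigma_mb = table$sigma),
                   path, row.names = FALSE)
  invisible(path)
}

.xs_interp <- function(table, E) {
  out <- stats::approx(table$energy, table$sigma, E, rule = 2)$y
  out[E < table$energy[1]] <- 0  # below tabulated threshold
  out
}

#' Beta+ emitter production map
#'
#' Folds the scored per-depth fluence spectra with reaction cross sections
#' and target-nuclide number densities:
#' production(voxel, isotope) = sum over energy bins of
#' fluence(E) x sigma(E) x n_target, linear in fluence, cross section and
#' target density. The per-depth production is distributed over the voxels
#' of each slice proportionally to the deposited dose.
#'
#' @param grid a `dose_grid` from [run_simulation()].
#' @param xs_tables list of [xs_table()] objects.
#' @return object of class `emitter_map`: list with `production`
#'   (named list of 3D arrays, decays pending per cm^3 per primary),
#'   `depth_profile` (matrix nz x isotopes, per primary), `half_lives`,
#'   `phantom`.
#' @export
emitter_production <- function(grid, xs_tables) {
  stopifnot(inherits(grid, "dose_grid"))
  if (inherits(xs_tables, "xs_table")) xs_tables <- list(xs_tables)
  ph <- grid$phantom
  const <- physical_constants()
  edges <- grid$fluence_edges
  Emid <- sqrt(edges[-1] * edges[-length(edges)])
  nz <- ph$shape[3]
  vol <- prod(ph$spacing / 10)

  # per-slice, per-element target number density (voxel-volume weighted)
  mats <- ph$materials
  prof <- list(); hl <- numeric(0)
  for (tb in xs_tables) {
    # number density of the target nuclide per material (1/cm^3)
    n_per_mat <- vapply(mats, function(m) {
      row <- m$elements$Z == tb$target_Z
      if (!any(row)) return(0.0)
      m$density * const$avogadro * sum(m$elements$w[row] / m$elements$A[row])
    }, 0.0)
    nvox <- array(n_per_mat[ph$material_index] * ph$density_scale,
                  dim = ph$shape)
    n_slice <- apply(nvox, 3, mean)
    if (all(n_slice == 0))
      warning("reaction ", tb$reaction, ": target Z=", tb$target_Z,
              " absent everywhere in the phantom")
    sig <- .xs_interp(tb, Emid) * 1e-27   # mb -> cm^2
    # fluence is track length (cm) per primary per slice/energy bin;
    # production per slice = sum_E L(E) sigma(E) n_target / voxel volume
    prod_slice <- as.numeric(grid$fluence %*% sig) * n_slice
    # distribute across the slice proportionally to deposited dose
    arr <- array(0, dim = ph$shape)
    for (k in seq_len(nz)) {
      sl <- grid$energy[, , k]
      tot <- sum(sl)
      w <- if (tot > 0) sl / tot else array(0, dim = dim(sl))
      arr[, , k] <- prod_slice[k] * w / vol
    }
    key <- tb$product
    if (is.null(prof[[key]])) {
      prof[[key]] <- arr
      hl[key] <- tb$half_life
    } else prof[[key]] <- prof[[key]] + arr
  }
  depth_profile <- vapply(prof, function(a) apply(a, 3, sum) * vol,
                          numeric(nz))
  structure(list(production = prof, depth_profile = depth_profile,
                 half_lives = hl, phantom = ph), class = "emitter_map")
}

#' Expected decays in an acquisition window
#'
#' For each isotope the number of decays between `t_start` and
#' `t_start + t_acq` after (instantaneous) irradiation is
#' \eqn{N (e^{-\lambda t_{start}} - e^{-\lambda (t_{start}+t_{acq})})}
#' with \eqn{\lambda = \ln 2 / T_{1/2}}; an optional uniform metabolic
#' washout rate is added to \eqn{\lambda}.
#'
#' @param map an [emitter_production()] result.
#' @param t_start delay before acquisition, s.
#' @param t_acq acquisition duration, s (may be `Inf`).
#' @param washout_rate additional decay constant, 1/s.
#' @return an `emitter_map` with `production` scaled to expected decays in
#'   the window.
#' @export
activity_in_window <- function(map, t_start, t_acq, washout_rate = 0) {
  stopifnot(t_start >= 0, t_acq >= 0, washout_rate >= 0)
  out <- map
  for (iso in names(map$production)) {
    lam <- log(2) / map$half_lives[[iso]] + washout_rate
    f <- exp(-lam * t_start) - exp(-lam * (t_start + t_acq))
    out$production[[iso]] <- map$production[[iso]] * f
    out$depth_profile[, iso] <- map$depth_profile[, iso] * f
  }
  out
}

#' PET ring detector
#'
#' Geometric ring of perfect-absorber crystals: radius, axial extent,
#' azimuthal module segmentation and the coincidence scoring options
#' (energy window, energy resolution, time resolution, dead time, minimum
#' scoring time). `opening_angle` spans 0 (no detectors) to 180 degrees
#' (complete ring); a partial ring is modeled as two opposing arcs of that
#' angular half-width (dual-head geometry).
#'
#' @param radius mm (> 0).
#' @param axial_extent mm, full axial length of the ring.
#' @param n_modules azimuthal modules (crystal id granularity).
#' @param opening_angle degrees in \[0, 180\].
#' @param energy_window keV, length-2 `(E_low, E_high)`.
#' @param energy_resolution_fwhm fractional FWHM at `resolution_ref_energy`.
#' @param resolution_ref_energy keV.
#' @param time_resolution coincidence window, ns.
#' @param dead_time per-module dead time, ns.
#' @param min_scoring_time s, events before it are discarded.
#' @return object of class `ring_detector`.
#' @export
ring_detector <- function(radius = 300, axial_extent = 200, n_modules = 48,
                          opening_angle = 180,
                          energy_window = c(350, 650),
                          energy_resolution_fwhm = 0.07,
                          resolution_ref_energy = 662,
                          time_resolution = 5, dead_time = 0,
                          min_scoring_time = 0) {
  stopifnot(radius > 0, axial_extent > 0, opening_angle >= 0,
            opening_angle <= 180, energy_window[1] < energy_window[2])
  structure(list(radius = radius, axial_extent = axial_extent,
                 n_modules = as.integer(n_modules),
                 opening_angle = opening_angle,
                 energy_window = energy_window,
                 energy_resolution_fwhm = energy_resolution_fwhm,
                 resolution_ref_energy = resolution_ref_energy,
                 time_resolution = time_resolution, dead_time = dead_time,
                 min_scoring_time = min_scoring_time),
            class = "ring_detector")
}

#' Simulate coincidence detection of annihilation photon pairs
#'
#' Each decay emits two back-to-back 511 keV photons in an isotropic
#' random direction (optional Gaussian acollinearity jitter). An event is
#' accepted when both photons geometrically intersect the ring surface
#' within the axial extent and the covered azimuthal arcs, both smeared
#' energies fall inside the energy window, the arrival-time difference is
#' within the time resolution, the decay time exceeds the minimum scoring
#' time, and neither struck module is dead.
#'
#' @param positions n x 3 matrix of decay positions, mm (ring axis = z,
#'   centered at the origin).
#' @param times decay times, s (default 0).
#' @param detector a [ring_detector()].
#' @param acollinearity_fwhm degrees; 0 disables the jitter.
#' @return data.frame of accepted events: hit coordinates `x1,y1,z1,
#'   x2,y2,z2` (mm), `e1`, `e2` (keV), `t` (s), module ids.
#' @export
detect_coincidences <- function(positions, detector, times = NULL,
                                acollinearity_fwhm = 0) {
  positions <- rbind(positions)
  n <- nrow(positions)
  if (is.null(times)) times <- rep(0, n)
  det <- detector
  if (det$opening_angle <= 0 || n == 0)
    return(data.frame(x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), z2 = numeric(0),
                      e1 = numeric(0), e2 = numeric(0), t = numeric(0),
                      module1 = integer(0), module2 = integer(0)))

  # isotropic directions
  u <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  dir1 <- cbind(s * cos(phi), s * sin(phi), u)
  dir2 <- -dir1
  if (acollinearity_fwhm > 0) {
    sd_rad <- acollinearity_fwhm * pi / 180 / 2.3548
    # jitter the second photon direction by small Gaussian angles
    t1 <- stats::rnorm(n, 0, sd_rad); t2 <- stats::rnorm(n, 0, sd_rad)
    a <- cbind(-dir2[, 2], dir2[, 1], 0)
    an <- sqrt(rowSums(a^2)); an[an < 1e-9] <- 1
    a <- a / an
    b <- cbind(dir2[, 2] * a[, 3] - dir2[, 3] * a[, 2],
               dir2[, 3] * a[, 1] - dir2[, 1] * a[, 3],
               dir2[, 1] * a[, 2] - dir2[, 2] * a[, 1])
    dir2 <- dir2 + t1 * a + t2 * b
    dir2 <- dir2 / sqrt(rowSums(dir2^2))
  }

  hit <- function(p, d) {
    # intersect ray p + t d with cylinder x^2+y^2 = R^2, t > 0
    A <- d[, 1]^2 + d[, 2]^2
    B <- 2 * (p[, 1] * d[, 1] + p[, 2] * d[, 2])
    C <- p[, 1]^2 + p[, 2]^2 - det$radius^2
    disc <- B^2 - 4 * A * C
    tt <- ifelse(A > 1e-12 & disc >= 0, (-B + sqrt(pmax(disc, 0))) / (2 * A),
                 NA_real_)
    tt[tt <= 0] <- NA_real_
    x <- p[, 1] + tt * d[, 1]; y <- p[, 2] + tt * d[, 2]
    z <- p[, 3] + tt * d[, 3]
    ok <- !is.na(tt) & abs(z) <= det$axial_extent / 2
    # azimuthal coverage: two opposing arcs of half-width opening_angle
    az <- atan2(y, x) * 180 / pi
    cov <- (abs(az) <= det$opening_angle / 2) |
           (abs(abs(az) - 180) <= det$opening_angle / 2)
    ok <- ok & cov
    list(ok = ok, x = x, y = y, z = z, path = tt,
         module = (floor((az + 180) / 360 * det$n_modules) %% det$n_modules) + 1L)
  }
  h1 <- hit(positions, dir1)
  h2 <- hit(positions, dir2)
  ok <- h1$ok & h2$ok & times >= det$min_scoring_time

  # energy smearing: 511 keV with Gaussian resolution (sqrt(E) scaling)
  fwhm511 <- det$energy_resolution_fwhm * det$resolution_ref_energy *
    sqrt(511 / det$resolution_ref_energy)
  sdE <- fwhm511 / 2.3548
  e1 <- stats::rnorm(n, 511, sdE)
  e2 <- stats::rnorm(n, 511, sdE)
  ok <- ok & e1 >= det$energy_window[1] & e1 <= det$energy_window[2] &
             e2 >= det$energy_window[1] & e2 <= det$energy_window[2]

  # time difference (path-length difference plus detector jitter)
  dt_ns <- abs(h1$path - h2$path) / 10 / .c_cm_per_ns +
    abs(stats::rnorm(n, 0, det$time_resolution / 2.3548 / sqrt(2)))
  ok <- ok & dt_ns <= det$time_resolution
  ok[is.na(ok)] <- FALSE

  ev <- data.frame(x1 = h1$x[ok], y1 = h1$y[ok], z1 = h1$z[ok],
                   x2 = h2$x[ok], y2 = h2$y[ok], z2 = h2$z[ok],
                   e1 = e1[ok], e2 = e2[ok], t = times[ok],
                   module1 = h1$module[ok], module2 = h2$module[ok])
  if (det$dead_time > 0 && nrow(ev) > 1) {
    ev <- ev[order(ev$t), ]
    last_seen <- new.env()
    keep <- logical(nrow(ev))
    for (i in seq_len(nrow(ev))) {
      k1 <- as.character(ev$module1[i]); k2 <- as.character(ev$module2[i])
      t1 <- mget(k1, envir = last_seen, ifnotfound = -Inf)[[1]]
      t2 <- mget(k2, envir = last_seen, ifnotfound = -Inf)[[1]]
      dead_s <- det$dead_time * 1e-9
      keep[i] <- (ev$t[i] - t1 >= dead_s) && (ev$t[i] - t2 >= dead_s)
      if (keep[i]) {
        assign(k1, ev$t[i], envir = last_seen)
        assign(k2, ev$t[i], envir = last_seen)
      }
    }
    ev <- ev[keep, ]
  }
  ev
}

#' Bin coincidence events into a sinogram
#'
#' Each line of response (LOR) is projected onto the transaxial plane and
#' parameterized by its azimuth `phi` in \[0, 180) degrees and signed
#' radial offset `s` (mm, distance of the LOR from the scanner axis).
#' Counts are conserved: LORs falling outside the radial range are
#' accumulated in an overflow tally.
#'
#' @param events data.frame from [detect_coincidences()].
#' @param n_radial,n_angular bin counts.
#' @param s_max radial range, mm (default: detector-independent, from data
#'   or 1.05 x max |s|).
#' @return object of class `sinogram`: `counts` (n_radial x n_angular
#'   integer matrix), `s_edges`, `phi_edges` (degrees), `overflow`.
#' @export
bin_sinogram <- function(events, n_radial = 64, n_angular = 90, s_max = NULL) {
  dx <- events$x2 - events$x1; dy <- events$y2 - events$y1
  L <- sqrt(dx^2 + dy^2)
  ok <- L > 1e-9
  # normal angle of the LOR in [0, pi)
  phi <- atan2(dy, dx) + pi / 2
  phi <- phi %% pi
  s <- events$x1 * cos(phi) + events$y1 * sin(phi)
  if (is.null(s_max)) s_max <- max(1.05 * max(abs(s[ok]), 0), 1)
  s_edges <- seq(-s_max, s_max, length.out = n_radial + 1)
  phi_edges <- seq(0, 180, length.out = n_angular + 1)
  counts <- matrix(0L, n_radial, n_angular)
  overflow <- sum(!ok)
  si <- findInterval(s[ok], s_edges, rightmost.closed = TRUE)
  pi_ <- findInterval(phi[ok] * 180 / pi, phi_edges, rightmost.closed = TRUE)
  inr <- si >= 1 & si <= n_radial & pi_ >= 1 & pi_ <= n_angular
  overflow <- overflow + sum(!inr)
  for (ii in which(inr)) counts[si[ii], pi_[ii]] <- counts[si[ii], pi_[ii]] + 1L
  structure(list(counts = counts, s_edges = s_edges, phi_edges = phi_edges,
                 overflow = overflow), class = "sinogram")
}

#' Convolve a spectrum with the detector energy resolution
#'
#' Gaussian smearing with FWHM = `frac * E_ref` at the reference energy,
#' scaled with sqrt(E) by convention (an energy-independent fractional
#' resolution is available via `sqrt_scaling = FALSE`). The smearing
#' matrix rows are renormalized so the spectrum integral is preserved to
#' 1e-9.
#'
#' @param energy bin centers, keV.
#' @param counts spectrum values.
#' @param detector a [ring_detector()] (uses its resolution fields).
#' @param sqrt_scaling logical.
#' @return smeared counts (same length).
#' @export
convolve_energy_resolution <- function(energy, counts, detector,
                                       sqrt_scaling = TRUE) {
  stopifnot(length(energy) == length(counts))
  frac <- detector$energy_resolution_fwhm
  eref <- detector$resolution_ref_energy
  fwhm <- if (sqrt_scaling) frac * eref * sqrt(pmax(energy, 0) / eref)
          else frac * energy
  if (all(fwhm == 0)) return(counts)
  sd <- fwhm / 2.3548
  out <- numeric(length(counts))
  for (i in seq_along(counts)) {
    if (counts[i] == 0) next
    if (sd[i] == 0) { out[i] <- out[i] + counts[i]; next }
    k <- stats::dnorm(energy, energy[i], sd[i])
    ks <- sum(k)
    if (ks == 0) { out[i] <- out[i] + counts[i]; next }
    out <- out + counts[i] * k / ks
  }
  out
}

#' Prompt-signal depth profile with energy gating
#'
#' Histograms prompt photons above a low-energy threshold (the standard
#' noise-rejection gate is 2 MeV) over depth, per primary, with an
#' optional constant background offset subtraction.
#'
#' @param depth photon production depths, mm.
#' @param photon_energy photon energies, MeV (same length).
#' @param energy_threshold MeV; photons below it are discarded.
#' @param breaks depth bin edges, mm.
#' @param n_primaries normalization.
#' @param background constant offset subtracted from each bin (after
#'   normalization); negative bins are kept (no clipping), mirroring plain
#'   background-subtracted data.
#' @return data.frame with `depth_mm` (bin centers) and `yield`.
#' @export
prompt_depth_profile <- function(depth, photon_energy, energy_threshold = 2,
                                 breaks = NULL, n_primaries = 1,
                                 background = 0) {
  keep <- photon_energy >= energy_threshold
  if (is.null(breaks))
    breaks <- seq(0, max(depth, 1) * 1.05, length.out = 51)
  h <- graphics::hist(depth[keep], breaks = breaks, plot = FALSE)
  data.frame(depth_mm = h$mids, yield = h$counts / n_primaries - background)
}
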