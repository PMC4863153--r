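# small shared simulation for production tests
sim_for_monitor <- local({
  ph <- water_column_phantom(180, 1)
  beam <- beam_spec(proton, 150, n_primaries = 4000)
  quiet(run_simulation(beam, ph, transport_config(rng_seed = 61)))
})

test_that("emitter production is linear and vanishes with zero cross section", {
  xs0 <- xs_table("16O(p,x)15O", "15O", 122.24, 8, 16,
                  energy = c(0, 250), sigma = c(0, 0))
  em0 <- emitter_production(sim_for_monitor, xs0)
  expect_equal(sum(em0$depth_profile), 0)
  xs1 <- fixture_xs_table("16O(p,x)15O")
  em1 <- emitter_production(sim_for_monitor, xs1)
  expect_gt(sum(em1$depth_profile), 0)
  # doubling sigma doubles production (linearity)
  xs2 <- xs1; xs2$sigma <- 2 * xs1$sigma
  em2 <- emitter_production(sim_for_monitor, xs2)
  expect_equal(sum(em2$depth_profile), 2 * sum(em1$depth_profile),
               tolerance = 1e-12)
  # a reaction on a target absent from water warns
  xs_ca <- xs_table("40Ca(p,x)39Ca", "39Ca", 1, 20, 40,
                    energy = c(0, 250), sigma = c(10, 10))
  expect_warning(emitter_production(sim_for_monitor, xs_ca), "absent")
})

test_that("box cross section produces emitters only in the matching depth window", {
  # sigma nonzero only for E in [50, 100]: production confined to the
  # depths where the slowing-down energy crosses that window
  xs_box <- xs_table("16O(p,x)15O", "15O", 122.24, 8, 16,
                     energy = c(0, 49.99, 50, 100, 100.01, 250),
                     sigma = c(0, 0, 50, 50, 0, 0))
  em <- emitter_production(sim_for_monitor, xs_box)
  prof <- em$depth_profile[, "15O"]
  z <- (seq_along(prof) - 0.5)
  r0 <- quiet(csda_range(150, proton, water)) * 10
  z_hi <- r0 - quiet(csda_range(100, proton, water)) * 10  # E = 100 here
  z_lo <- r0 - quiet(csda_range(50, proton, water)) * 10   # E = 50 here
  occupied <- range(z[prof > 0.02 * max(prof)])
  expect_equal(occupied[1], z_hi, tolerance = 0.05)
  expect_equal(occupied[2], z_lo, tolerance = 0.05)
})

test_that("decay window counting follows the exponential closed forms", {
  # synthetic two-isotope map (water carries no carbon, so the 11C channel
  # is exercised on a hand-built production map)
  mk <- array(1, dim = c(1, 1, 5))
  em <- structure(list(
    production = list("15O" = mk, "11C" = 2 * mk),
    depth_profile = cbind("15O" = rep(1, 5), "11C" = rep(2, 5)),
    half_lives = c("15O" = 122.24, "11C" = 1221.8)), class = "emitter_map")
  n0 <- sum(em$depth_profile[, "15O"])
  # all decays with no delay and infinite acquisition
  all_dec <- activity_in_window(em, 0, Inf)
  expect_equal(sum(all_dec$depth_profile[, "15O"]), n0, tolerance = 1e-9)
  # one half-life delay: half the decays remain
  half <- activity_in_window(em, 122.24, Inf)
  expect_equal(sum(half$depth_profile[, "15O"]) / n0, 0.5, tolerance = 1e-9)
  # mixed two-isotope window, hand-evaluated double exponential
  t0 <- 120; tacq <- 300
  w <- activity_in_window(em, t0, tacq)
  for (iso in c("15O", "11C")) {
    lam <- log(2) / em$half_lives[[iso]]
    f <- exp(-lam * t0) - exp(-lam * (t0 + tacq))
    expect_equal(sum(w$depth_profile[, iso]) / sum(em$depth_profile[, iso]),
                 f, tolerance = 1e-9)
  }
  # washout adds to the decay constant
  wo <- activity_in_window(em, 60, Inf, washout_rate = 0.01)
  expect_lt(sum(wo$depth_profile[, "15O"]),
            sum(activity_in_window(em, 60, Inf)$depth_profile[, "15O"]))
})

test_that("central point source acceptance matches the solid-angle formula", {
  det <- ring_detector(radius = 100, axial_extent = 400, opening_angle = 180,
                       energy_window = c(300, 700), time_resolution = 10)
  set.seed(71)
  n <- 2e4
  ev <- detect_coincidences(matrix(0, n, 3), det)
  h <- det$axial_extent / 2
  acc_analytic <- h / sqrt(h^2 + det$radius^2)
  expect_equal(nrow(ev) / n, acc_analytic, tolerance = 0.02)
})

test_that("coincidence gating contracts are exact", {
  set.seed(72)
  pos <- matrix(0, 500, 3)
  # energy window excluding 511 keV at (near) zero resolution
  det_bad_win <- ring_detector(radius = 100, axial_extent = 400,
                               energy_window = c(100, 300),
                               energy_resolution_fwhm = 1e-9)
  expect_identical(nrow(detect_coincidences(pos, det_bad_win)), 0L)
  # no detectors at zero opening angle
  det_closed <- ring_detector(radius = 100, axial_extent = 400,
                              opening_angle = 0)
  expect_identical(nrow(detect_coincidences(pos, det_closed)), 0L)
  # acceptance shrinks monotonically with the opening angle
  accs <- vapply(c(180, 90, 30), function(oa) {
    set.seed(73)
    nrow(detect_coincidences(matrix(0, 5000, 3),
                             ring_detector(radius = 100, axial_extent = 400,
                                           opening_angle = oa,
                                           energy_window = c(300, 700))))
  }, 0L)
  expect_true(all(diff(accs) < 0))
  # events before the minimum scoring time are discarded
  det_min <- ring_detector(radius = 100, axial_extent = 400,
                           energy_window = c(300, 700),
                           min_scoring_time = 10)
  set.seed(74)
  ev <- detect_coincidences(matrix(0, 500, 3), det_min,
                            times = rep(c(5, 15), 250))
  expect_true(all(ev$t >= 10))
})

test_that("sinogram conserves counts and recovers a point-source sinusoid", {
  det <- ring_detector(radius = 100, axial_extent = 400,
                       energy_window = c(300, 700))
  set.seed(75)
  src <- cbind(30, 0, 0)[rep(1, 20000), ]
  ev <- detect_coincidences(src, det)
  sg <- bin_sinogram(ev, n_radial = 50, n_angular = 36, s_max = 50)
  expect_identical(sum(sg$counts) + sg$overflow, nrow(ev))
  expect_true(all(sg$counts >= 0))
  # locus s(phi) = r sin(phi - phi0): fitted amplitude within one bin of 30
  phi_c <- (sg$phi_edges[-1] + sg$phi_edges[-length(sg$phi_edges)]) / 2
  s_c <- (sg$s_edges[-1] + sg$s_edges[-length(sg$s_edges)]) / 2
  mean_s <- apply(sg$counts, 2, function(col)
    if (sum(col) > 0) sum(col * s_c) / sum(col) else NA_real_)
  amp <- max(abs(mean_s), na.rm = TRUE)
  bin_w <- diff(sg$s_edges)[1]
  expect_lt(abs(amp - 30), bin_w)
  # source on the axis: everything in the central radial bins
  set.seed(76)
  ev0 <- detect_coincidences(matrix(0, 5000, 3), det)
  sg0 <- bin_sinogram(ev0, n_radial = 51, n_angular = 36, s_max = 50)
  occupied <- which(rowSums(sg0$counts) > 0)
  expect_lte(max(abs(occupied - 26)), 1)
})

test_that("energy-resolution convolution preserves the integral and the FWHM", {
  det <- ring_detector(energy_resolution_fwhm = 0.07,
                       resolution_ref_energy = 662)
  E <- seq(400, 900, by = 1)
  spec <- numeric(length(E)); spec[E == 662] <- 1000
  # zero-width resolution: identity
  det0 <- ring_detector(energy_resolution_fwhm = 0)
  expect_identical(convolve_energy_resolution(E, spec, det0), spec)
  out <- convolve_energy_resolution(E, spec, det)
  expect_equal(sum(out), sum(spec), tolerance = 1e-9)
  # FWHM of the smeared 662 keV line from the second moment: 7% +- 0.2 pp
  w <- out / sum(out)
  mu <- sum(w * E)
  fwhm_frac <- 2.3548 * sqrt(sum(w * (E - mu)^2)) / 662
  expect_lt(abs(fwhm_frac - 0.07), 0.002)
})

test_that("prompt profiles honor the energy gate and track the Bragg peak", {
  # toy prompt-photon field: yield proportional to the primary fluence
  cv <- depth_dose(sim_for_monitor)
  surv <- sim_for_monitor$crossings
  z <- cv$depth_mm
  set.seed(78)
  n_ph <- 20000
  depth <- sample(z, n_ph, replace = TRUE, prob = pmax(surv, 0))
  e_ph <- stats::runif(n_ph, 1, 7)
  # threshold above all energies: empty profile
  p0 <- prompt_depth_profile(depth, e_ph, energy_threshold = 10,
                             breaks = seq(0, 200, 4))
  expect_equal(sum(p0$yield), 0)
  # zero threshold: every photon counted
  p1 <- prompt_depth_profile(depth, e_ph, energy_threshold = 0,
                             breaks = seq(0, 200, 4), n_primaries = 1)
  expect_equal(sum(p1$yield), n_ph)
  # with the standard 2 MeV gate the falloff sits at the fluence edge,
  # within 2 mm of the Bragg peak
  p2 <- prompt_depth_profile(depth, e_ph, energy_threshold = 2,
                             breaks = seq(0, 200, 1))
  half <- 0.5 * stats::median(p2$yield[p2$depth_mm < 100])
  fall <- max(p2$depth_mm[p2$yield > half])
  expect_lt(abs(fall - bragg_peak_position(cv)), 2.5)
  # constant background subtraction shifts every bin
  p3 <- prompt_depth_profile(depth, e_ph, energy_threshold = 2,
                             breaks = seq(0, 200, 1), background = 1)
  expect_equal(p3$yield, p2$yield - 1, tolerance = 1e-12)
})
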