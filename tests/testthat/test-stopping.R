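test_that("relativistic kinematics invert and behave in limits", {
  st <- kinematics_from_energy(938.27208816, proton)   # gamma = 2 exactly
  expect_equal(st$gamma, 2, tolerance = 1e-12)
  expect_equal(st$beta, sqrt(3) / 2, tolerance = 1e-12)
  E <- c(0.5, 10, 150, 400)
  st <- kinematics_from_energy(E, carbon)
  expect_equal(energy_from_kinematics(st, carbon), E, tolerance = 1e-10)
  expect_true(all(diff(st$beta) > 0))                  # monotone in E
  expect_lt(kinematics_from_energy(1e-6, proton)$beta, 1e-3)
  expect_error(kinematics_from_energy(-1, proton), "positive")
})

test_that("Tmax keeps all kinematic terms and matches the frozen hand value", {
  # independent scalar evaluation at 200 MeV with published m_e, M_p
  st <- kinematics_from_energy(200, proton)
  expect_equal(tmax(st, proton), 0.4814929666, tolerance = 1e-9)
  # beta -> 0 limit
  st0 <- kinematics_from_energy(1e-8, proton)
  expect_lt(tmax(st0, proton), 1e-9)
  # M -> infinity: denominator -> 1
  heavy <- projectile_spec("heavy", 1, 1e12, 1)
  sth <- kinematics_from_energy(200 / 1e12 * 938.27208816, proton)
  me <- physical_constants()$electron_mass_energy
  expect_equal(tmax(sth, heavy) / (2 * me * sth$beta^2 * sth$gamma^2), 1,
               tolerance = 1e-3)
})

test_that("effective charge: bare for light ions, Barkas-type for heavy", {
  st <- kinematics_from_energy(c(0.1, 10, 400), proton)
  expect_equal(effective_charge(proton, st), c(1, 1, 1))
  stc <- kinematics_from_energy(c(0.02, 1, 400), carbon)
  z <- effective_charge(carbon, stc)
  expect_true(all(diff(z) > 0))          # monotone non-decreasing in beta
  expect_lt(z[1], 2)                     # strong neutralization at low beta
  expect_equal(z[3], 6, tolerance = 1e-3)  # full stripping
})

test_that("density correction vanishes at low beta*gamma and follows 2ln(bg)", {
  st <- list(beta = 0.0995, gamma = 1 / sqrt(1 - 0.0995^2))
  bg <- st$beta * st$gamma  # ~0.1 < x0 threshold
  expect_equal(density_correction(list(beta = bg, gamma = 1), water), 0)
  bgs <- 10^seq(-0.5, 3, length.out = 40)
  d <- density_correction(list(beta = bgs, gamma = 1), water)
  expect_true(all(diff(d) >= 0))
  # asymptotic slope: delta(10 bg) - delta(bg) = 2 ln 10 at bg = 1000
  d2 <- density_correction(list(beta = c(1000, 10000), gamma = 1), water)
  expect_equal(diff(d2) / (2 * log(10)), 1, tolerance = 0.01)
})

test_that("shell correction is small at high energy and larger at low", {
  st_hi <- kinematics_from_energy(1000, proton)
  expect_lt(abs(shell_correction(st_hi, water)), 1e-3)
  st_lo <- kinematics_from_energy(5, proton)
  st_mid <- kinematics_from_energy(100, proton)
  expect_gt(abs(shell_correction(st_lo, water)),
            abs(shell_correction(st_mid, water)))
  # continuity in E
  E <- seq(5, 500, length.out = 200)
  cz <- shell_correction(kinematics_from_energy(E, proton), water)
  expect_lt(max(abs(diff(cz))), 0.02)
  expect_warning(shell_correction(kinematics_from_energy(0.2, proton), water),
                 "clamped")
})

test_that("Barkas and Bloch terms obey their limits", {
  st_hi <- kinematics_from_energy(900, proton)
  bb <- barkas_bloch_terms(proton, st_hi, water)
  lead <- log(2 * 0.511 * st_hi$beta^2 * tmax(st_hi, proton) /
                ((78e-6)^2 * (1 - st_hi$beta^2)))
  expect_lt(abs(2 * 1 * bb$L1 + 2 * 1 * bb$L2), 0.01 * lead)  # Born limit
  # Bloch closed-form limit L2(y -> 0) -> 0
  st <- kinematics_from_energy(c(5, 50, 900), proton)
  L2 <- barkas_bloch_terms(proton, st, water)$L2
  expect_lt(abs(L2[3]), abs(L2[1]))
  expect_lt(abs(L2[3]), 1e-3)
  # Barkas term is odd in z: flipping the charge sign flips 2 z L1
  expect_equal(2 * (-1) * bb$L1, -(2 * 1 * bb$L1))
})

test_that("Mott correction toggles, grows with z, vanishes in the Born limit", {
  st <- kinematics_from_energy(50, carbon)
  expect_equal(mott_correction(carbon, st, enabled = FALSE), 0)
  stp <- kinematics_from_energy(50, proton)
  expect_gt(mott_correction(carbon, st, enabled = TRUE),
            mott_correction(proton, stp, enabled = TRUE))
  st_fast <- kinematics_from_energy(900, proton)
  expect_lt(mott_correction(proton, st_fast, enabled = TRUE), 0.01)
})

test_that("full stopping assembly equals an independent transcription to 1e-10", {
  # literal re-assembly of the bracket and prefactor, written separately
  transcribe <- function(E, prj, mat, opt = stopping_options()) {
    cst <- physical_constants()
    st <- kinematics_from_energy(E, prj)
    zeff <- effective_charge(prj, st, k = opt$barkas_k)
    Tm <- tmax(st, prj)
    I <- mat$I_eV * 1e-6
    bb <- barkas_bloch_terms(prj, st, mat, F0 = opt$barkas_F0)
    mott_on <- if (is.null(opt$mott)) prj$z >= 3 else opt$mott
    br <- log(2 * cst$electron_mass_energy * st$beta^2 * Tm /
                (I^2 * (1 - st$beta^2))) - 2 * st$beta^2 +
      2 * zeff * bb$L1 + 2 * zeff^2 * bb$L2 +
      mott_correction(prj, st, enabled = mott_on, c_M = opt$mott_c) -
      2 * shell_correction(st, mat) - density_correction(st, mat)
    2 * pi * mat$electron_density * cst$classical_electron_radius^2 *
      cst$electron_mass_energy * zeff^2 / st$beta^2 * br / mat$density
  }
  E <- exp(seq(log(2), log(900), length.out = 50))
  for (mat in list(water, material_bone())) {
    for (prj in list(proton, carbon)) {
      got <- quiet(electronic_stopping_power(E, prj, mat))
      ref <- quiet(transcribe(E, prj, mat))
      expect_equal(got, ref, tolerance = 1e-10)
    }
  }
})

test_that("with corrections off the carbon/proton ratio is the prefactor scaling", {
  opt <- stopping_options(density = FALSE, shell = FALSE, barkas = FALSE,
                          bloch = FALSE, mott = FALSE, effective_charge = FALSE)
  E <- c(50, 150, 400)
  r <- electronic_stopping_power(E, carbon, water, opt) /
       electronic_stopping_power(E, proton, water, opt)
  # (z_C/z_p)^2 at fixed beta; the residual <1% offset is the projectile
  # mass entering Tmax, which is kept in full
  expect_equal(r, rep(36, 3), tolerance = 0.01)
})

test_that("stopping is linear in electron density", {
  w2 <- material("water_rho2", c("H", "O"), c(0.111894, 0.888106),
                 density = 2, I_eV = 78,
                 sternheimer = water$sternheimer)
  # mass stopping x rho doubles when n_e doubles (same I)
  s1 <- electronic_stopping_power(100, proton, water) * 1
  s2 <- electronic_stopping_power(100, proton, w2) * 2
  expect_equal(s2 / s1, 2, tolerance = 1e-9)
})

test_that("stopping has a single maximum over the operating domain", {
  E <- exp(seq(log(0.01), log(1000), length.out = 400))
  for (prj in list(proton, carbon)) {
    S <- quiet(electronic_stopping_power(E, prj, water))
    expect_true(all(S > 0))
    i <- which.max(S)
    expect_true(all(diff(S[1:i]) > 0))
    expect_true(all(diff(S[i:length(S)]) < 0))
  }
  expect_error(electronic_stopping_power(2000, proton, water), "domain")
})

test_that("proton stopping in water agrees with reference tabulations to 2%", {
  # regression guard: ICRU-49-style unrestricted proton values in water
  # (MeV cm^2/g) at I = 78 eV equivalence level
  refs <- data.frame(E = c(1, 5, 10, 50, 100, 150, 200, 250),
                     S = c(260.8, 79.11, 45.67, 12.45, 7.289, 5.445,
                           4.492, 3.911))
  got <- quiet(electronic_stopping_power(refs$E, proton, water))
  expect_true(all(abs(got / refs$S - 1) < 0.02))
})

test_that("restricted stopping honors the threshold contracts", {
  expect_error(restricted_stopping_power(100, proton, water, 5e-4), "1 keV")
  # threshold above Tmax: equal to the unrestricted value
  expect_equal(restricted_stopping_power(100, proton, water, 10),
               electronic_stopping_power(100, proton, water), tolerance = 1e-12)
  # restricted <= unrestricted for all thresholds
  for (tc in c(0.001, 0.01, 0.1, 1)) {
    expect_lte(restricted_stopping_power(100, proton, water, tc),
               electronic_stopping_power(100, proton, water))
  }
})

test_that("restricted loss plus delta-ray energy flux equals unrestricted", {
  E <- 150; tc <- 0.05
  st <- kinematics_from_energy(E, proton)
  Tm <- tmax(st, proton)
  cst <- physical_constants()
  pref <- 2 * pi * water$electron_density * cst$classical_electron_radius^2 *
    cst$electron_mass_energy / st$beta^2 / water$density
  # energy carried by delta rays: integral of T dsigma/dT over [tc, Tmax]
  flux <- stats::integrate(function(Tt) pref * (1 / Tt) *
                             (1 - st$beta^2 * Tt / Tm), tc, Tm,
                           rel.tol = 1e-10)$value
  diff_S <- electronic_stopping_power(E, proton, water) -
    restricted_stopping_power(E, proton, water, tc)
  expect_equal(diff_S, flux, tolerance = 1e-6)
})

test_that("CSDA range is monotone and matches brute-force quadrature", {
  expect_equal(csda_range(0, proton, water), 0)
  r <- quiet(csda_range(c(50, 100, 150, 200), proton, water))
  expect_true(all(diff(r) > 0))
  # fixed-step trapezoid oracle at 1e5 points
  E <- seq(0.01, 150, length.out = 1e5)
  f <- quiet(1 / electronic_stopping_power(E, proton, water))
  trap <- sum((f[-1] + f[-length(f)]) / 2 * diff(E)) +
    2 * 0.01 / quiet(electronic_stopping_power(0.01, proton, water))
  expect_equal(r[3], trap, tolerance = 1e-4)
})

test_that("stopping table export round-trips through CSV", {
  tab <- quiet(stopping_table(proton, water, E_max = 200,
                              points_per_decade = 40))
  expect_true(all(diff(tab$range_g_cm2) > 0))
  # table range column agrees with the adaptive quadrature
  r150 <- quiet(csda_range(150, proton, water))
  i <- which.min(abs(tab$E_MeV_u - 150))
  expect_equal(stats::approx(tab$E_MeV_u, tab$range_g_cm2, 150)$y, r150,
               tolerance = 1e-3)
  path <- file.path(tempdir(), "stopping.csv")
  write_stopping_table(tab, path)
  tab2 <- utils::read.csv(path)
  expect_equal(tab2$S_el, tab$S_el, tolerance = 1e-12)
})
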