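test_that("thermal-lens contrast is a Lorentzian with the pump Rayleigh half-width", {
  sc <- ref_scene(sigma = 0.065, dz = 3)
  zRh <- rayleigh_range(sc$pump)
  # peak value against independent hand arithmetic (SI)
  i0 <- 2 * (6.6e-3 / 0.025) / (pi * 25e-12)
  peak_expected <- 0.065e-12 * i0 / (4 * pi * 0.0262 * 0.25e-6) * (-9e-7)
  expect_equal(delta_n(sc, 3), peak_expected, tolerance = 1e-12)
  expect_lt(delta_n(sc, 3), 0)  # air: dn/dT < 0
  expect_equal(delta_n(sc, 3 + zRh), peak_expected / 2, tolerance = 1e-12)
  expect_equal(delta_n(sc, 3 - zRh), peak_expected / 2, tolerance = 1e-12)
})

test_that("curvature term obeys the waist and Rayleigh-range identities", {
  probe <- gaussian_beam(0.633, 0.53, 1.0003)
  zR <- rayleigh_range(probe)
  k <- 2 * pi * 1.0003 / 0.633
  expect_equal(curvature_term(probe, 0), complex(real = 1 / 0.53^2),
               tolerance = 1e-14)
  zeta <- curvature_term(probe, zR)
  expect_equal(Re(zeta), 1 / (2 * 0.53^2), tolerance = 1e-12)
  expect_equal(Im(zeta), k / (4 * zR), tolerance = 1e-12)
  z <- c(0.3, 1, 7)
  expect_equal(curvature_term(probe, -z), Conj(curvature_term(probe, z)),
               tolerance = 1e-14)
  # Re(1/zeta) is the (nearly) z-independent far-field constant 2 zR / k;
  # exact only up to the vacuum-wavelength convention used for zR (n0 = 1.0003)
  expect_equal(Re(1 / curvature_term(probe, 5)), 2 * zR / k, tolerance = 1e-3)
})

test_that("null absorber gives an exactly zero signal", {
  sc0 <- ref_scene(sigma = 0)
  det <- ref_det()
  expect_identical(phi_theta(sc0, c(0, 10, 25), 2), c(0, 0, 0))
  expect_identical(phi_total(sc0, det, c(-3, 0, 3)), c(0, 0, 0))
  expect_identical(axial_scan(sc0, det, seq(-2, 2, by = 0.5))$phi, rep(0, 9))
})

test_that("on-axis reduction: theta = 0 collapses to the gamma-factor expression", {
  sc <- ref_scene()
  z <- 1.3
  nu <- sc$bead_radius * delta_n(sc, z) * 2 * pi / 0.633
  zeta <- curvature_term(sc$probe, z)
  manual <- exp(2 * nu * Arg(zeta)) * gamma1i_mod2(nu) - 1
  expect_equal(phi_theta(sc, 0, z), manual, tolerance = 1e-12)
})

test_that("closed form matches the numerical diffraction oracle within 1%", {
  sc <- ref_scene()
  for (th in c(5, 15, 25)) for (z in c(-5, -1, 1, 5)) {
    cf <- phi_theta(sc, th, z)
    orc <- diffraction_oracle(sc, th, z)
    expect_lt(abs(cf - orc) / abs(cf), 0.01)
  }
})

test_that("oracle without the thermal phase gives zero and the on-axis sign flips across the focus", {
  sc <- ref_scene()
  expect_equal(as.numeric(diffraction_oracle(sc, 10, 2, include_lens = FALSE)), 0,
               tolerance = 1e-12)
  before <- as.numeric(diffraction_oracle(sc, 0, -1))
  after <- as.numeric(diffraction_oracle(sc, 0, 1))
  expect_lt(before * after, 0)
})

test_that("small-perturbation linearity: doubling sigma doubles the signal", {
  det <- ref_det()
  z <- 1.8
  p1 <- phi_total(ref_scene(sigma = 0.01), det, z)
  p2 <- phi_total(ref_scene(sigma = 0.02), det, z)
  expect_rel_equal(p2 / p1, 2, 0.005)
})

test_that("lobes are symmetric at zero offset in the perturbative regime", {
  det <- ref_det()
  sc <- ref_scene(sigma = 0.0065)   # a tenth of the reference cross section
  pk_pos <- optimize(function(z) -abs(phi_total(sc, det, z)), c(0.5, 4))
  pk_neg <- optimize(function(z) -abs(phi_total(sc, det, z)), c(-4, -0.5))
  ratio <- pk_neg$objective / pk_pos$objective
  expect_lt(abs(ratio - 1), 0.01)
  expect_lt(abs(pk_pos$minimum + pk_neg$minimum), 0.1)
})

test_that("angular quadrature is stable under node doubling", {
  sc <- ref_scene(); det <- ref_det()
  z <- c(-4, 1, 9)
  a <- phi_total(sc, det, z, rel_tol = 1e-8)
  b <- phi_total(sc, det, z, rel_tol = 1e-11)
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-6)
})

test_that("axial scan lobe positions are stable under grid refinement", {
  sc <- ref_scene(); det <- ref_det()
  coarse <- lobe_analysis(axial_scan(sc, det, seq(-10, 10, by = 0.5)))
  fine <- lobe_analysis(axial_scan(sc, det, seq(-10, 10, by = 0.25)))
  expect_equal(coarse$n_lobes, 2L)
  expect_equal(fine$n_lobes, 2L)
  expect_lt(max(abs(sort(coarse$lobe_positions) - sort(fine$lobe_positions))), 0.5)
})

test_that("lobe analysis counts signed lobes and handles degenerate input", {
  z <- seq(-5, 5, by = 0.1)
  gauss <- data.frame(z = z, phi = exp(-z^2))
  expect_equal(lobe_analysis(gauss)$n_lobes, 1L)
  zero <- data.frame(z = z, phi = rep(0, length(z)))
  expect_equal(lobe_analysis(zero)$n_lobes, 0L)
  disp <- data.frame(z = z, phi = z * exp(-z^2))   # dispersion shape
  rep2 <- lobe_analysis(disp)
  expect_equal(rep2$n_lobes, 2L)
  expect_equal(rep2$amplitude_ratio, 1, tolerance = 1e-9)
  sc <- ref_scene(); det <- ref_det()
  t1 <- lobe_analysis(axial_scan(sc, det, seq(-15, 15, by = 0.25)))
  expect_equal(t1$n_lobes, 2L)
  expect_gt(t1$amplitude_ratio, 0.95)
})

test_that("two-lobe threshold is monotone in the criterion and independent of sigma", {
  det <- ref_det()
  args <- list(detection = det, dz_range = c(0, 22), dz_step = 2,
               reference = "best_alignment", z_range = c(-20, 20),
               z_step = 0.5, refine = 0.5, rel_tol = 1e-6)
  t_strict <- do.call(two_lobe_threshold,
                      c(list(ref_scene(sigma = 0.02)), args, criterion = 0.35))
  t_loose <- do.call(two_lobe_threshold,
                     c(list(ref_scene(sigma = 0.02)), args, criterion = 0.25))
  expect_gte(as.numeric(t_loose), as.numeric(t_strict))
  # within the small-perturbation regime the lobe geometry, and with it the
  # threshold, does not depend on sigma (signal is linear in sigma there)
  t_sigma10 <- do.call(two_lobe_threshold,
                       c(list(ref_scene(sigma = 0.2)), args, criterion = 0.35))
  expect_lt(abs(as.numeric(t_sigma10) - as.numeric(t_strict)), 0.51)
})
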