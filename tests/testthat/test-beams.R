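test_that("Rayleigh range follows pi w0^2 / lambda and scales quadratically", {
  b <- gaussian_beam(wavelength = 6.895, waist = 5.0)
  expect_equal(rayleigh_range(b), pi * 25 / 6.895, tolerance = 1e-12)
  b2 <- gaussian_beam(6.895, 10.0)
  expect_equal(rayleigh_range(b2) / rayleigh_range(b), 4, tolerance = 1e-12)
  expect_error(gaussian_beam(6.895, 0), "waist")
  expect_error(gaussian_beam(-1, 5), "wavelength")
})

test_that("beam radius and curvature satisfy the Rayleigh-range identities", {
  b <- gaussian_beam(0.633, 0.53, 1.0003)
  zR <- rayleigh_range(b)
  at0 <- beam_radius_and_curvature(b, 0)
  expect_equal(at0$radius, 0.53)
  expect_identical(at0$curvature, Inf)
  expect_identical(at0$inverse_curvature, 0)
  atR <- beam_radius_and_curvature(b, zR)
  expect_equal(atR$radius, 0.53 * sqrt(2), tolerance = 1e-14)
  expect_equal(atR$curvature, 2 * zR, tolerance = 1e-14)
  atmR <- beam_radius_and_curvature(b, -zR)
  expect_equal(atmR$curvature, -2 * zR, tolerance = 1e-14)
})

test_that("peak pump intensity follows 2 P_avg / (beta pi w0^2)", {
  drv <- pump_drive(6.6, 0.025, 50)
  pump <- gaussian_beam(6.895, 5.0)
  expect_equal(peak_intensity(drv, pump),
               2 * (6.6e-3 / 0.025) / (pi * (5e-6)^2), tolerance = 1e-12)
  # CW limit: duty cycle 1 means peak = average power
  expect_equal(peak_intensity(pump_drive(6.6, 1, 50), pump),
               2 * 6.6e-3 / (pi * 25e-12), tolerance = 1e-12)
  # halving the waist quadruples the intensity
  expect_equal(peak_intensity(drv, gaussian_beam(6.895, 2.5)) /
                 peak_intensity(drv, pump), 4, tolerance = 1e-12)
  expect_error(pump_drive(6.6, 0, 50), "duty_cycle")
})

test_that("thermal diffusion length matches hand arithmetic and scales as f^-1/2", {
  air <- medium_spec(0.0262, 1006, 1.204)
  # sqrt(2 kappa / (Cp rho 2 pi f)) for air at 50 kHz, in um
  expect_equal(thermal_diffusion_length(air, 50),
               sqrt(2 * 0.0262 / (1006 * 1.204 * 2 * pi * 5e4)) * 1e6,
               tolerance = 1e-12)
  water <- medium_spec(0.6, 4184, 998)
  expect_equal(thermal_diffusion_length(water, 50),
               sqrt(2 * 0.6 / (4184 * 998 * 2 * pi * 5e4)) * 1e6,
               tolerance = 1e-12)
  f <- c(5, 20, 80, 320)
  r <- thermal_diffusion_length(air, f)
  expect_equal(r[-1] / r[-4], rep(0.5, 3), tolerance = 1e-12)
  expect_error(thermal_diffusion_length(air, 0), "modulation_frequency")
  expect_error(medium_spec(0, 1006, 1.204), "kappa")
})

test_that("waist/FWHM conversion uses the intensity convention and round-trips", {
  expect_equal(waist_from_fwhm(sqrt(2 * log(2))), 1, tolerance = 1e-14)
  w <- c(0.2, 0.53, 1.7)
  expect_equal(waist_from_fwhm(fwhm_from_waist(w)), w, tolerance = 1e-12)
  # instrument value: 624 nm FWHM corresponds to the 0.53 um waist
  expect_equal(waist_from_fwhm(0.624), 0.53, tolerance = 1e-2)
  expect_error(waist_from_fwhm(0), "fwhm")
})

test_that("steady-state check compares diffusion length with the probe spot", {
  air <- medium_spec()
  chk <- steady_state_check(air, 50, 0.53)
  expect_true(chk$ok)
  expect_gt(chk$ratio, 20)
  # strict inequality at the boundary
  at1 <- steady_state_check(air, 50, chk$diffusion_length)
  expect_false(at1$ok)
  expect_equal(at1$ratio, 1)
  # very fast modulation shrinks the diffusion length below the spot
  expect_false(steady_state_check(air, 5e7, 0.53)$ok)
})
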