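test_that("field components vanish appropriately at the origin", {
  obj <- objective(0.55)
  fc <- field_components(obj, 0.633, 0, 0)
  expect_equal(Mod(fc$e1[1, 1]), 0, tolerance = 1e-15)
  expect_equal(Mod(fc$e2[1, 1]), 0, tolerance = 1e-15)
  expect_gt(Re(fc$e0[1, 1]), 0)
  expect_equal(Im(fc$e0[1, 1]), 0, tolerance = 1e-12)
})

test_that("paraxial limit: e1 and e2 become negligible against e0 as NA shrinks", {
  ratios <- vapply(c(0.2, 0.05), function(na) {
    obj <- objective(na)
    r <- seq(0, 0.61 * 0.633 / na, length.out = 9)  # within the first Airy ring
    fc <- field_components(obj, 0.633, r, 0)
    max(Mod(fc$e1), Mod(fc$e2)) / max(Mod(fc$e0))
  }, 0)
  # the ratio shrinks linearly with NA (here: 4x smaller NA)
  expect_lt(ratios[2], ratios[1] / 3)
  expect_lt(ratios[2], 0.01)
})

test_that("field integrals agree with a dense fixed-step Riemann-sum oracle", {
  obj <- objective(0.5, theta_min = 21, apodization = "sqrt_cosine")
  k <- 2 * pi / 0.633
  riemann_e0 <- function(r, z, n = 2e5) {
    th <- seq(obj$theta_min_rad, obj$alpha, length.out = n)
    h <- th[2] - th[1]
    f <- sqrt(cos(th)) * (1 + cos(th)) * besselJ(k * r * sin(th), 0) *
      exp(-1i * k * z * cos(th)) * sin(th)
    h * (sum(f) - (f[1] + f[n]) / 2)
  }
  for (pt in list(c(0.2, 0), c(0.5, 1.5), c(0, -2))) {
    fc <- field_components(obj, 0.633, pt[1], pt[2])
    expect_lt(Mod(fc$e0[1, 1] - riemann_e0(pt[1], pt[2])) / Mod(fc$e0[1, 1]), 1e-6)
  }
})

test_that("intensity PSF peaks on axis and is even in z", {
  obj <- objective(0.55)
  r <- seq(0, 1.5, length.out = 301)
  g <- intensity_psf(obj, 0.633, r, 0)
  expect_equal(which.max(g$values[, 1]), 1L)
  expect_equal(max(g$values), 1)
  z <- seq(-4, 4, length.out = 321)
  gz <- intensity_psf(obj, 0.633, 0, z)
  v <- gz$values[1, ]
  expect_lt(max(abs(v - rev(v))), 1e-9)
})

test_that("low-NA single-arm radial FWHM approaches the Airy width 0.51 lambda/NA", {
  obj <- objective(0.1, apodization = "uniform")
  r <- seq(0, 8, length.out = 1601)
  g <- intensity_psf(obj, 0.633, r, 0)
  f <- fwhm_of_profile(radial_profile(g))
  expect_rel_equal(f, 0.51 * 0.633 / 0.1, 0.02)
})

test_that("confocal PSF of identical arms is the squared single-arm PSF", {
  obj <- objective(0.55)
  r <- seq(0, 1, length.out = 101)
  single <- intensity_psf(obj, 0.633, r, 0)
  conf <- confocal_psf(obj, obj, 0.633, r, 0)
  expect_equal(conf$values, single$values^2 / max(single$values^2),
               tolerance = 1e-10)
})

test_that("quadrature is stable under tightening the tolerance", {
  obj <- objective(0.5, theta_min = 21)
  r <- seq(0, 1, length.out = 41)
  a <- field_components(obj, 0.633, r, 0.7, rel_tol = 1e-8)
  b <- field_components(obj, 0.633, r, 0.7, rel_tol = 1e-11)
  expect_lt(max(Mod(a$e0 - b$e0)) / max(Mod(b$e0)), 1e-6)
})

test_that("confocal radial FWHM decreases monotonically with NA", {
  f <- vapply(c(0.3, 0.4, 0.5, 0.6), function(na) {
    obj <- objective(na)
    r <- seq(0, 3, length.out = 1201)
    fwhm_of_profile(radial_profile(confocal_psf(obj, obj, 0.633, r, 0)))
  }, 0)
  expect_true(all(diff(f) < 0))
})

test_that("an annular collection arm never shortens the axial FWHM", {
  ill <- objective(0.5)
  z <- seq(0, 8, length.out = 1201)
  axial_fwhm <- function(col) {
    g <- confocal_psf(ill, col, 0.633, 0, z)
    p <- axial_profile(g)
    full <- line_profile(c(-rev(z[-1]), z), c(rev(p$intensity[-1]), p$intensity))
    fwhm_of_profile(full)
  }
  expect_gte(axial_fwhm(objective(0.5, theta_min = 21)),
             axial_fwhm(objective(0.5)))
})

test_that("fwhm_of_profile handles exact shapes and reports missing crossings", {
  x <- seq(-6, 6, by = 0.005)
  expect_equal(fwhm_of_profile(line_profile(x, exp(-x^2 / 2))),
               2 * sqrt(2 * log(2)), tolerance = 1e-5)
  rect <- ifelse(abs(x) <= 1.5, 1, 0)
  expect_equal(fwhm_of_profile(line_profile(x, rect)), 3, tolerance = 0.01)
  expect_error(fwhm_of_profile(line_profile(x, x)), "left|right")
})
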