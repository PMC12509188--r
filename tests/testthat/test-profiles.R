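test_that("rotation search recovers synthetic tilts and conserves intensity", {
  img <- gaussian_image(81, 81, fwhm_fast = 0.3, fwhm_slow = 1.2)
  grid <- seq(-6, 6, by = 0.1)
  aligned <- rotation_align(img, grid)
  expect_lt(abs(aligned$angle), 0.11)
  tilted <- img
  tilted$pixel_values <- thermopsf:::rotate_bilinear(img$pixel_values, 3)
  rec <- rotation_align(tilted, grid)
  expect_lt(abs(rec$angle + 3), 0.2)
  # mass conservation of the interpolation
  expect_lt(abs(sum(rec$image$pixel_values) - sum(tilted$pixel_values)) /
              sum(tilted$pixel_values), 0.01)
  # idempotence: a second pass finds (close to) zero
  again <- rotation_align(rec$image, grid)
  expect_lt(abs(again$angle), 0.2 + 1e-9)
  expect_error(rotation_align(scan_image(matrix(1, 5, 5), 1, 1)), "flat")
})

test_that("central line profiles average around the maximum with physical coordinates", {
  img <- gaussian_image(41, 41, pitch = 0.05)
  p1 <- central_line_profile(img, "fast", n_lines = 1)
  expect_equal(p1$intensity, img$pixel_values[21, ], tolerance = 1e-14)
  expect_equal(diff(p1$coordinate), rep(0.05, 40), tolerance = 1e-12)
  # separable noiseless image: 3-line mean has the same shape up to scale
  p3 <- central_line_profile(img, "fast", n_lines = 3)
  expect_lt(max(abs(p3$intensity / max(p3$intensity) -
                      p1$intensity / max(p1$intensity))), 1e-6)
  # variance reduction on noisy data (Monte-Carlo over seeds)
  set.seed(42)
  truth <- img$pixel_values[21, ]
  err1 <- err3 <- numeric(60)
  for (s in 1:60) {
    noisy <- img
    noisy$pixel_values <- img$pixel_values +
      matrix(rnorm(41 * 41, 0, 0.05), 41, 41)
    err1[s] <- mean((central_line_profile(noisy, "fast", 1)$intensity - truth)^2)
    err3[s] <- mean((central_line_profile(noisy, "fast", 3)$intensity - truth)^2)
  }
  expect_lt(mean(err3), mean(err1))
  # border maximum is flagged in metadata
  edge <- matrix(0, 11, 11); edge[1, 6] <- 1
  pe <- central_line_profile(scan_image(edge + 0.01, 1, 1), "fast", 3)
  expect_match(attr(pe, "metadata")$border_maximum, "border")
})

test_that("Gaussian fits recover exact profiles and are scale-equivariant", {
  x <- seq(-2, 2, by = 0.02)
  y <- 3.2 * exp(-4 * log(2) * (x - 0.13)^2 / 0.42^2) + 0.7
  fit <- fit_gaussian(line_profile(x, y))
  expect_equal(fit$fwhm, 0.42, tolerance = 1e-9)
  expect_equal(fit$center, 0.13, tolerance = 1e-9)
  fit_scaled <- fit_gaussian(line_profile(x, 10 * y))
  expect_equal(fit_scaled$amplitude, 10 * fit$amplitude, tolerance = 1e-9)
  expect_equal(fit_scaled$fwhm, fit$fwhm, tolerance = 1e-9)
  expect_equal(fit_scaled$center, fit$center, tolerance = 1e-9)
  expect_error(fit_gaussian(line_profile(x, rep(1, length(x)))), "peak")
})

test_that("Gaussian fits on noisy profiles recover the width on average", {
  x <- seq(-2, 2, by = 0.02)
  clean <- exp(-4 * log(2) * x^2 / 0.42^2)
  set.seed(7)
  fw <- vapply(1:100, function(s) {
    fit_gaussian(line_profile(x, clean + rnorm(length(x), 0, 0.05)))$fwhm
  }, 0)
  expect_rel_equal(mean(fw), 0.42, 0.02)
})

test_that("beam ellipticity is the width ratio", {
  expect_equal(round(beam_ellipticity(1.049, 1.059), 2), 0.99)
  expect_equal(beam_ellipticity(2, 2), 1)
  expect_equal(beam_ellipticity(1.059, 1.049),
               1 / beam_ellipticity(1.049, 1.059), tolerance = 1e-14)
  expect_error(beam_ellipticity(0, 1), "widths")
})
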