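# shared fixtures: reference instrument scene and small synthetic images

ref_scene <- function(sigma = 0.065, dz = 0) table1_scene(sigma, dz)
ref_det <- function() table1_detection()

# separable Gaussian bead image (rows = slow axis)
gaussian_image <- function(nr = 61, nc = 61, pitch = 0.05,
                           fwhm_fast = 0.46, fwhm_slow = 0.46, offset = 0) {
  fr <- (seq_len(nr) - (nr + 1) / 2) * pitch
  fc <- (seq_len(nc) - (nc + 1) / 2) * pitch
  v <- outer(exp(-4 * log(2) * fr^2 / fwhm_slow^2),
             exp(-4 * log(2) * fc^2 / fwhm_fast^2)) + offset
  scan_image(v, pitch, pitch)
}

expect_rel_equal <- function(actual, expected, rel) {
  expect_lt(abs(actual - expected), rel * abs(expected))
}
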