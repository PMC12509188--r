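#' Noise specification for synthetic images
#'
#' @param relative_sd Additive Gaussian noise standard deviation as a
#'   fraction of the image peak amplitude (>= 0).
#' @param seed Integer RNG seed; generation is a pure function of
#'   (parameters, seed).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(relative_sd = 0, seed = 1L) {
  stopifnot(is.numeric(relative_sd), relative_sd >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(relative_sd = relative_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

# run code with a local RNG state seeded from `seed`
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic axial (xz) photothermal scan image
#'
#' Emulates an xz z-scan of a single bead: the outer product of the model
#' amplitude \eqn{|\Phi_{tot}(z)|} (slow axis, rows) with a radial Gaussian
#' envelope of the given FWHM (fast axis, columns), optionally rotated to
#' emulate sample tilt, plus additive Gaussian noise.  Deterministic given
#' the noise seed.  The separable structure approximates the measured xz
#' images of sub-wavelength beads; it carries none of the instrument's
#' drift or ambient-light artifacts.
#'
#' @param scene A [thermal_scene()].
#' @param detection A [detection_geometry()].
#' @param z_grid Monotone axial grid (um), becomes the slow axis.
#' @param x_grid Monotone lateral grid (um), becomes the fast axis; must be
#'   uniformly spaced (pixel pitch).
#' @param radial_width FWHM of the radial envelope (um).
#' @param tilt Rotation applied to the noiseless image (degrees).
#' @param noise A [noise_spec()].
#' @return A [scan_image()] with axes labels `c("x", "z")`.
#' @export
make_axial_image <- function(scene, detection, z_grid, x_grid, radial_width,
                             tilt = 0, noise = noise_spec()) {
  stopifnot(!is.unsorted(z_grid, strictly = TRUE),
            !is.unsorted(x_grid, strictly = TRUE),
            radial_width > 0, inherits(noise, "noise_spec"))
  dzp <- diff(z_grid); dxp <- diff(x_grid)
  stopifnot(max(abs(dzp - dzp[1])) < 1e-9, max(abs(dxp - dxp[1])) < 1e-9)
  sig <- abs(phi_total(scene, detection, z_grid))
  env <- exp(-4 * log(2) * x_grid^2 / radial_width^2)
  img <- outer(sig, env)                 # rows = z (slow), cols = x (fast)
  if (tilt != 0) img <- rotate_bilinear(img, tilt, fill = 0)
  if (noise$relative_sd > 0) {
    img <- img + with_local_seed(noise$seed,
      matrix(stats::rnorm(length(img), 0, noise$relative_sd * max(img)),
             nrow(img), ncol(img)))
  }
  img <- img - min(img)                  # scan_image requires nonnegative values
  scan_image(img, pixel_pitch_fast = dxp[1], pixel_pitch_slow = dzp[1],
             axes_labels = c("x", "z"))
}

#' Synthetic radial (xy) bead image
#'
#' A radially symmetric Gaussian spot of the given FWHM sampled on a
#' square pixel grid, plus additive Gaussian noise; emulates an xy
#' photothermal or Raman image of a single bead.
#'
#' @param fwhm Spot FWHM (um).
#' @param pixel_pitch Pixel pitch (um).
#' @param extent Image side length (um); must be at least `3 * fwhm`.
#' @param noise A [noise_spec()].
#' @return A [scan_image()] with axes labels `c("x", "y")`.
#' @export
make_radial_image <- function(fwhm, pixel_pitch, extent, noise = noise_spec()) {
  stopifnot(fwhm > 0, pixel_pitch > 0, extent >= 3 * fwhm,
            inherits(noise, "noise_spec"))
  n <- max(3L, floor(extent / pixel_pitch) + 1L)
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_pitch
  r2 <- outer(ax^2, ax^2, `+`)
  img <- exp(-4 * log(2) * r2 / fwhm^2)
  if (noise$relative_sd > 0) {
    img <- img + with_local_seed(noise$seed,
      matrix(stats::rnorm(length(img), 0, noise$relative_sd), n, n))
    img <- img - min(img)
  }
  scan_image(img, pixel_pitch, pixel_pitch, axes_labels = c("x", "y"))
}
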