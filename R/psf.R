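#' Vectorial focal-field components of a high-NA objective
#'
#' Evaluates the three diffraction integrals over the aperture angle
#' \eqn{\theta'} that give the focal field of an aplanatic objective
#' illuminated with x-polarised light:
#' \deqn{e_0 = \int_{\theta_{min}}^{\alpha} P(\theta')(1+\cos\theta')
#'   J_0(k r \sin\theta') e^{-i k z \cos\theta'} \sin\theta'\, d\theta'}
#' \deqn{e_1 = \int P(\theta') J_1(k r \sin\theta')
#'   e^{-i k z \cos\theta'} \sin^2\theta'\, d\theta'}
#' \deqn{e_2 = \int P(\theta')(1-\cos\theta') J_2(k r \sin\theta')
#'   e^{-i k z \cos\theta'} \sin\theta'\, d\theta'}
#' with \eqn{k = 2\pi n/\lambda}.  \eqn{J_0, J_1, J_2} are Bessel functions
#' of the first kind; at \eqn{r=0} both \eqn{e_1} and \eqn{e_2} vanish.
#' Gauss-Legendre quadrature with node doubling is used until the result is
#' stable to `rel_tol`.
#'
#' @param obj An [objective()].
#' @param wavelength Vacuum wavelength (um).
#' @param r Radial image-plane coordinate(s) (um, >= 0).
#' @param z Axial coordinate(s) (um); `z > 0` is the propagation direction.
#' @param rel_tol Relative quadrature tolerance (default 1e-8).
#' @return A list with complex matrices `e0`, `e1`, `e2` of dimension
#'   `length(r)` x `length(z)`, plus `r`, `z` and the achieved tolerance
#'   `achieved_tol`.
#' @export
field_components <- function(obj, wavelength, r, z, rel_tol = 1e-8) {
  stopifnot(inherits(obj, "objective_spec"),
            is.numeric(wavelength), wavelength > 0,
            is.numeric(r), all(is.finite(r)), all(r >= 0),
            is.numeric(z), all(is.finite(z)))
  k <- 2 * pi * obj$medium_index / wavelength
  eval_n <- function(nn) {
    gl <- pracma::gaussLegendre(nn, obj$theta_min_rad, obj$alpha)
    th <- gl$x
    wts <- gl$w * apodization_values(obj, th) * sin(th)
    st <- sin(th); ct <- cos(th)
    # phase factor over z for each node: nn x nz
    phase <- exp(-1i * k * outer(ct, z))
    j0 <- besselJ(outer(r, k * st), 0)        # nr x nn
    j1 <- besselJ(outer(r, k * st), 1)
    j2 <- besselJ(outer(r, k * st), 2)
    e0 <- (j0 %*% ((1 + ct) * wts * phase))
    e1 <- (j1 %*% (st * wts * phase))
    e2 <- (j2 %*% ((1 - ct) * wts * phase))
    list(e0 = e0, e1 = e1, e2 = e2)
  }
  nn <- 64L
  prev <- eval_n(nn)
  repeat {
    nn <- nn * 2L
    cur <- eval_n(nn)
    scale <- max(abs(cur$e0))
    d <- max(abs(cur$e0 - prev$e0), abs(cur$e1 - prev$e1), abs(cur$e2 - prev$e2))
    if (d <= rel_tol * scale || nn >= 4096L) break
    prev <- cur
  }
  if (d > rel_tol * scale)
    warning(sprintf("field_components: quadrature reached %d nodes with relative change %.2e (requested %.0e)",
                    nn, d / scale, rel_tol))
  c(cur, list(r = r, z = z, achieved_tol = d / scale))
}

#' Intensity point spread function of a single arm
#'
#' Forms the intensity map \eqn{I(r, z) \propto |e_0|^2} (default) or the
#' full vectorial sum \eqn{|e_0|^2 + 2|e_1|^2 + |e_2|^2} on an `(r, z)`
#' grid, peak-normalised to 1.  The map is radially symmetric by
#' construction (the low-NA/e0 form exactly, the vectorial sum in the
#' azimuth-averaged sense).
#'
#' @inheritParams field_components
#' @param component `"e0"` (default) or `"vectorial"`.
#' @return An object of class `intensity_grid` with fields `r_axis`,
#'   `z_axis` (um) and `values` (matrix, peak 1).
#' @export
intensity_psf <- function(obj, wavelength, r, z, component = c("e0", "vectorial"),
                          rel_tol = 1e-8) {
  component <- match.arg(component)
  fc <- field_components(obj, wavelength, r, z, rel_tol = rel_tol)
  v <- if (component == "e0") abs(fc$e0)^2 else
    abs(fc$e0)^2 + 2 * abs(fc$e1)^2 + abs(fc$e2)^2
  intensity_grid(r, z, v / max(v))
}

#' Confocal point spread function
#'
#' Pointwise product of the illumination- and collection-arm intensity
#' PSFs, renormalised to peak 1.  For a confocal reflection setup the two
#' arms are identical and the confocal PSF is the square of the single-arm
#' PSF.
#'
#' @param illumination,collection [objective()] specifications of the two arms.
#' @inheritParams intensity_psf
#' @return An `intensity_grid`.
#' @examples
#' r <- seq(0, 1, length.out = 201)
#' raman <- confocal_psf(objective(0.55), objective(0.55), 0.633, r, 0)
#' @export
confocal_psf <- function(illumination, collection, wavelength, r, z,
                         component = c("e0", "vectorial"), rel_tol = 1e-8) {
  component <- match.arg(component)
  a <- intensity_psf(illumination, wavelength, r, z, component, rel_tol)
  b <- intensity_psf(collection, wavelength, r, z, component, rel_tol)
  v <- a$values * b$values
  intensity_grid(r, z, v / max(v))
}

#' @rdname intensity_grid
#' @export
intensity_grid <- function(r_axis, z_axis, values) {
  values <- as.matrix(values)
  stopifnot(all(r_axis >= 0), !is.unsorted(r_axis), !is.unsorted(z_axis),
            nrow(values) == length(r_axis), ncol(values) == length(z_axis),
            all(values >= 0))
  structure(list(r_axis = r_axis, z_axis = z_axis, values = values),
            class = "intensity_grid")
}

#' Sampled intensity grid
#'
#' Container for a nonnegative intensity map sampled on a radial half-line
#' `r >= 0` and an axial axis `z`; `values` is peak-normalised where
#' produced by [intensity_psf()]/[confocal_psf()].
#'
#' @param r_axis,z_axis Monotone axes (um); `r_axis >= 0`.
#' @param values Nonnegative matrix `length(r_axis)` x `length(z_axis)`.
#' @name intensity_grid
NULL

#' Extract line profiles from an intensity grid
#'
#' `radial_profile()` mirrors the `r >= 0` half-line about the axis to give
#' a full symmetric profile at the `z` plane nearest `at`;
#' `axial_profile()` returns the on-axis profile at the `r` sample nearest
#' `at` (default the axis, `r = 0`).
#'
#' @param grid An `intensity_grid`.
#' @param at Coordinate of the fixed axis (um).
#' @return A [line_profile()].
#' @export
radial_profile <- function(grid, at = 0) {
  stopifnot(inherits(grid, "intensity_grid"))
  j <- which.min(abs(grid$z_axis - at))
  v <- grid$values[, j]
  r <- grid$r_axis
  if (r[1] == 0) {
    line_profile(c(-rev(r[-1]), r), c(rev(v[-1]), v))
  } else {
    line_profile(c(-rev(r), r), c(rev(v), v))
  }
}

#' @rdname radial_profile
#' @export
axial_profile <- function(grid, at = 0) {
  stopifnot(inherits(grid, "intensity_grid"))
  i <- which.min(abs(grid$r_axis - at))
  line_profile(grid$z_axis, grid$values[i, ])
}

#' Full width at half maximum of a sampled profile
#'
#' Locates the half-maximum crossings on either side of the unique global
#' maximum by local linear interpolation and returns their distance.
#'
#' @param profile A [line_profile()] (or anything with `coordinate` and
#'   `intensity` fields).
#' @return FWHM in the units of the profile coordinate.
#' @examples
#' x <- seq(-5, 5, by = 0.01)
#' fwhm_of_profile(line_profile(x, exp(-x^2 / 2)))  # 2 sqrt(2 log 2) = 2.3548
#' @export
fwhm_of_profile <- function(profile) {
  x <- profile$coordinate
  y <- profile$intensity
  stopifnot(length(x) == length(y), length(x) >= 5)
  ymax <- max(y)
  ymin <- min(y)
  if (!(ymax > ymin)) stop("fwhm_of_profile: profile is constant")
  half <- (ymax + ymin) / 2
  im <- which.max(y)
  left_idx <- which(y[seq_len(im)] <= half)
  if (length(left_idx) == 0)
    stop("fwhm_of_profile: no half-maximum crossing on the left side")
  i <- max(left_idx)
  xl <- x[i] + (half - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
  right_rel <- which(y[im:length(y)] <= half)
  if (length(right_rel) == 0)
    stop("fwhm_of_profile: no half-maximum crossing on the right side")
  j <- im - 1L + min(right_rel)
  xr <- x[j - 1] + (half - y[j - 1]) * (x[j] - x[j - 1]) / (y[j] - y[j - 1])
  xr - xl
}

#' Theoretical resolution of a confocal system
#'
#' Convenience wrapper computing the radial (at `z = 0`) and axial (at
#' `r = 0`) FWHM of the confocal PSF of two arms.  The grids are chosen
#' automatically from the wavelength and numerical apertures.
#'
#' @inheritParams confocal_psf
#' @return A list with `radial_fwhm` and `axial_fwhm` (um).
#' @export
confocal_resolution <- function(illumination, collection, wavelength,
                                component = c("e0", "vectorial"), rel_tol = 1e-8) {
  component <- match.arg(component)
  na_min <- min(illumination$numerical_aperture, collection$numerical_aperture)
  r <- seq(0, 2.5 * wavelength / na_min, length.out = 1501)
  z <- seq(0, 12 * wavelength / na_min^2, length.out = 2001)
  rad <- confocal_psf(illumination, collection, wavelength, r, 0, component, rel_tol)
  # axial: compute half-line z >= 0 and mirror (profile is even in z)
  axi <- confocal_psf(illumination, collection, wavelength, 0, z, component, rel_tol)
  zp <- axial_profile(axi)
  zfull <- line_profile(c(-rev(z[-1]), z),
                        c(rev(zp$intensity[-1]), zp$intensity))
  list(radial_fwhm = fwhm_of_profile(radial_profile(rad)),
       axial_fwhm = fwhm_of_profile(zfull))
}
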