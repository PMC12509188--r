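#' One-dimensional line profile
#'
#' The common currency between PSF models, scan images, fits and files: a
#' sampled intensity along a strictly increasing physical coordinate.
#'
#' @param coordinate Strictly increasing numeric vector (um), length >= 5.
#' @param intensity Numeric vector of the same length.
#' @param metadata Optional list carried along (e.g. extraction warnings).
#' @return An object of class `line_profile` (a data frame with columns
#'   `coordinate`, `intensity`).
#' @export
line_profile <- function(coordinate, intensity, metadata = list()) {
  stopifnot(is.numeric(coordinate), is.numeric(intensity),
            length(coordinate) == length(intensity), length(coordinate) >= 5,
            all(is.finite(coordinate)))
  if (is.unsorted(coordinate, strictly = TRUE))
    stop("line_profile: 'coordinate' must be strictly increasing")
  structure(data.frame(coordinate = coordinate, intensity = intensity),
            metadata = metadata,
            class = c("line_profile", "data.frame"))
}

#' Two-dimensional scan image
#'
#' A raster scan with physical pixel pitches.  Rows are the slow axis
#' (e.g. `z` in an xz scan), columns the fast axis; the coordinate origin
#' is at the image centre.
#'
#' @param pixel_values Numeric matrix (>= 3 rows and columns), nonnegative.
#' @param pixel_pitch_fast,pixel_pitch_slow Pixel pitches (um), > 0.
#' @param axes_labels Character length-2, fast then slow axis label.
#' @return An object of class `scan_image`.
#' @export
scan_image <- function(pixel_values, pixel_pitch_fast, pixel_pitch_slow,
                       axes_labels = c("x", "z")) {
  pixel_values <- as.matrix(pixel_values)
  stopifnot(is.numeric(pixel_values), nrow(pixel_values) >= 3,
            ncol(pixel_values) >= 3, all(is.finite(pixel_values)),
            pixel_pitch_fast > 0, pixel_pitch_slow > 0,
            length(axes_labels) == 2L)
  structure(list(pixel_values = pixel_values,
                 pixel_pitch_fast = pixel_pitch_fast,
                 pixel_pitch_slow = pixel_pitch_slow,
                 axes_labels = axes_labels),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("Scan image: %d x %d px (%s/%s), pitch %g x %g um\n",
              nrow(x$pixel_values), ncol(x$pixel_values),
              x$axes_labels[2], x$axes_labels[1],
              x$pixel_pitch_slow, x$pixel_pitch_fast))
  invisible(x)
}

# physical coordinates of pixel centres, origin at the image centre
image_axes <- function(image) {
  nr <- nrow(image$pixel_values); nc <- ncol(image$pixel_values)
  list(fast = (seq_len(nc) - (nc + 1) / 2) * image$pixel_pitch_fast,
       slow = (seq_len(nr) - (nr + 1) / 2) * image$pixel_pitch_slow)
}

# inverse-mapped bilinear rotation about the intensity centroid,
# out-of-frame samples filled with the image minimum
rotate_bilinear <- function(values, angle_deg, fill = min(values)) {
  nr <- nrow(values); nc <- ncol(values)
  tot <- sum(values)
  ri <- seq_len(nr); ci <- seq_len(nc)
  cr <- if (tot > 0) sum(ri * rowSums(values)) / tot else (nr + 1) / 2
  cc <- if (tot > 0) sum(ci * colSums(values)) / tot else (nc + 1) / 2
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  # output pixel (i, j) samples input at the point rotated by -angle
  I <- matrix(ri, nr, nc) - cr
  J <- matrix(ci, nr, nc, byrow = TRUE) - cc
  src_i <- co * I + si * J + cr
  src_j <- -si * I + co * J + cc
  i0 <- floor(src_i); j0 <- floor(src_j)
  fi <- src_i - i0; fj <- src_j - j0
  val_at <- function(ii, jj) {
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    out <- matrix(fill, nr, nc)
    out[ok] <- values[cbind(ii[ok], jj[ok])]
    out
  }
  v <- (1 - fi) * (1 - fj) * val_at(i0, j0) +
    (1 - fi) * fj * val_at(i0, j0 + 1) +
    fi * (1 - fj) * val_at(i0 + 1, j0) +
    fi * fj * val_at(i0 + 1, j0 + 1)
  v
}

#' Tilt-correction by rotation search
#'
#' Searches a grid of rotation angles for the one that maximises the peak
#' of the column-summed intensity (i.e. aligns the feature with the
#' vertical axis), and returns the image rotated by that angle.  Rotation
#' uses bilinear interpolation about the intensity centroid; pixels mapped
#' from outside the frame are filled with the image minimum so the
#' background offset is not biased.
#'
#' @param image A [scan_image()].
#' @param angle_grid Candidate rotation angles in degrees (default
#'   `seq(-15, 15, by = 0.1)`).
#' @return A list with `image` (the rotated [scan_image()]) and `angle`
#'   (degrees, the applied rotation).
#' @export
rotation_align <- function(image, angle_grid = seq(-15, 15, by = 0.1)) {
  stopifnot(inherits(image, "scan_image"), is.numeric(angle_grid))
  v <- image$pixel_values
  if (max(v) == min(v)) stop("rotation_align: image is flat")
  score <- vapply(angle_grid,
                  function(a) max(colSums(rotate_bilinear(v, a))), 0)
  best <- angle_grid[which.max(score)]
  out <- image
  out$pixel_values <- rotate_bilinear(v, best)
  list(image = out, angle = best)
}

#' Mean central line profile of a scan image
#'
#' Takes the mean of `n_lines` adjacent rows or columns straddling the
#' image's global maximum and returns it with physical coordinates from
#' the pixel pitch (origin at the image centre).  A maximum on the image
#' border is recorded as a warning in the profile metadata.
#'
#' @param image A [scan_image()].
#' @param axis `"fast"` to profile along the fast axis (averaging rows) or
#'   `"slow"` to profile along the slow axis (averaging columns).
#' @param n_lines Odd number of lines to average (default 3).
#' @return A [line_profile()].
#' @export
central_line_profile <- function(image, axis = c("fast", "slow"), n_lines = 3L) {
  axis <- match.arg(axis)
  stopifnot(inherits(image, "scan_image"), n_lines >= 1, n_lines %% 2 == 1)
  v <- image$pixel_values
  ij <- which(v == max(v), arr.ind = TRUE)[1, ]
  axes <- image_axes(image)
  meta <- list()
  half <- (n_lines - 1L) %/% 2L
  if (axis == "fast") {
    if (n_lines > nrow(v)) stop("central_line_profile: n_lines exceeds image extent")
    ctr <- ij[["row"]]
    if (ctr %in% c(1L, nrow(v)))
      meta$border_maximum <- "global maximum lies on the image border"
    rows <- pmin(pmax(ctr + (-half):half, 1L), nrow(v))
    prof <- colMeans(v[rows, , drop = FALSE])
    line_profile(axes$fast, prof, metadata = meta)
  } else {
    if (n_lines > ncol(v)) stop("central_line_profile: n_lines exceeds image extent")
    ctr <- ij[["col"]]
    if (ctr %in% c(1L, ncol(v)))
      meta$border_maximum <- "global maximum lies on the image border"
    cols <- pmin(pmax(ctr + (-half):half, 1L), ncol(v))
    prof <- rowMeans(v[, cols, drop = FALSE])
    line_profile(axes$slow, prof, metadata = meta)
  }
}

#' Gaussian fit of a line profile
#'
#' Nonlinear least squares fit of
#' \eqn{A \exp(-4 \ln 2 (x - c)^2 / w^2) + b} (so `w` is directly the
#' FWHM), with starting values amplitude = max - min, centre = argmax,
#' width = direct half-maximum width, offset = min.  Parameter standard
#' deviations come from the fit covariance.
#'
#' @param profile A [line_profile()].
#' @return An object of class `gaussian_fit`: list with `amplitude`,
#'   `center`, `fwhm`, `offset`, matching `*_sd` entries, `residual_sd`
#'   and the `fit` object.
#' @export
fit_gaussian <- function(profile) {
  x <- profile$coordinate; y <- profile$intensity
  off0 <- min(y); amp0 <- max(y) - off0
  if (amp0 <= 0) stop("fit_gaussian: profile has no discernible peak")
  c0 <- x[which.max(y)]
  w0 <- tryCatch(fwhm_of_profile(profile), error = function(e) NA_real_)
  if (!is.finite(w0)) w0 <- diff(range(x)) / 4
  model <- function(p) p[1] * exp(-4 * log(2) * (x - p[2])^2 / p[3]^2) + p[4]
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(A = amp0, cc = c0, w = w0, b = off0),
                       fn = function(p) model(p) - y,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  fail <- function(why)
    stop(sprintf(paste0("fit_gaussian: %s; initial guesses were A=%.4g, ",
                        "center=%.4g, fwhm=%.4g, offset=%.4g"),
                 why, amp0, c0, w0, off0))
  if (is.null(fit) || !(fit$info %in% 1:3)) fail("fit did not converge")
  cf <- fit$par
  if (!is.finite(cf[["w"]]) || abs(cf[["w"]]) < .Machine$double.eps)
    fail("converged to a degenerate width")
  if (cf[["A"]] <= 0) fail("converged to a nonpositive amplitude")
  dof <- max(length(y) - 4L, 1L)
  s2 <- sum(fit$fvec^2) / dof
  covm <- tryCatch(s2 * solve(fit$hessian / 2),
                   error = function(e) matrix(NA_real_, 4, 4))
  se <- suppressWarnings(sqrt(abs(diag(covm))))
  names(se) <- names(cf)
  structure(list(amplitude = unname(cf[["A"]]), center = unname(cf[["cc"]]),
                 fwhm = abs(unname(cf[["w"]])), offset = unname(cf[["b"]]),
                 amplitude_sd = unname(se[["A"]]), center_sd = unname(se[["cc"]]),
                 fwhm_sd = unname(se[["w"]]), offset_sd = unname(se[["b"]]),
                 residual_sd = sqrt(s2), fit = fit),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian fit: fwhm = %.4g +/- %.2g, center = %.4g +/- %.2g, amplitude = %.4g, offset = %.4g\n",
              x$fwhm, x$fwhm_sd, x$center, x$center_sd, x$amplitude, x$offset))
  invisible(x)
}

#' Beam ellipticity from two orthogonal widths
#'
#' \eqn{\epsilon = D_x / D_y}; 1 is a perfectly circular beam.
#'
#' @param width_x,width_y Second-moment beam widths in the two directions
#'   (same units), > 0.
#' @return Dimensionless ellipticity.
#' @examples
#' beam_ellipticity(1.049, 1.059)  # 0.99
#' @export
beam_ellipticity <- function(width_x, width_y) {
  stopifnot(is.numeric(width_x), is.numeric(width_y))
  if (any(width_x <= 0) || any(width_y <= 0))
    stop("beam_ellipticity: widths must be > 0")
  width_x / width_y
}
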