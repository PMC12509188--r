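#' Objective specification for one arm of a confocal microscope
#'
#' Aperture geometry and apodization of a focusing or collection objective.
#' The maximum aperture angle is \eqn{\alpha = \arcsin(NA / n)}.  A
#' reflective (Schwarzschild) objective whose secondary mirror obscures the
#' central cone is described by a nonzero minimum aperture angle
#' `theta_min`.
#'
#' Apodization models for the pupil function \eqn{P(\theta')}:
#' \describe{
#'   \item{`"sqrt_cosine"`}{\eqn{\sqrt{\cos\theta'}} — the aplanatic
#'     (Abbe-sine-condition) energy-conservation factor; the default.}
#'   \item{`"cosine"`}{\eqn{\cos\theta'}.}
#'   \item{`"uniform"`}{\eqn{1} (no apodization).}
#' }
#'
#' @param numerical_aperture Numerical aperture, with `0 < NA < n`.
#' @param theta_min Minimum aperture angle in degrees (0 for an
#'   unobstructed objective); must satisfy `0 <= theta_min < alpha`.
#' @param medium_index Refractive index of the immersion/ambient medium.
#' @param apodization One of `"sqrt_cosine"`, `"cosine"`, `"uniform"`.
#' @return An object of class `objective_spec` with the angles stored in
#'   radians (`alpha`, `theta_min_rad`) alongside the inputs.
#' @examples
#' objective(0.55)                      # Raman arm
#' objective(0.5, theta_min = 21)       # reflective collection arm
#' @export
objective <- function(numerical_aperture, theta_min = 0, medium_index = 1,
                      apodization = c("sqrt_cosine", "cosine", "uniform")) {
  apodization <- match.arg(apodization)
  stopifnot(is.numeric(numerical_aperture), length(numerical_aperture) == 1L,
            is.numeric(theta_min), length(theta_min) == 1L,
            is.numeric(medium_index), length(medium_index) == 1L)
  if (medium_index < 1) stop("objective: 'medium_index' must be >= 1")
  if (numerical_aperture <= 0 || numerical_aperture >= medium_index)
    stop("objective: require 0 < NA < medium_index so that alpha = asin(NA/n) exists")
  alpha <- asin(numerical_aperture / medium_index)
  theta_min_rad <- theta_min * pi / 180
  if (theta_min < 0 || theta_min_rad >= alpha)
    stop(sprintf("objective: 'theta_min' must lie in [0, %.2f) degrees", alpha * 180 / pi))
  structure(list(numerical_aperture = numerical_aperture,
                 theta_min = theta_min,
                 medium_index = medium_index,
                 apodization = apodization,
                 alpha = alpha,
                 theta_min_rad = theta_min_rad),
            class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  cat(sprintf("Objective: NA = %g (alpha = %.2f deg), theta_min = %g deg, n = %g, apodization = %s\n",
              x$numerical_aperture, x$alpha * 180 / pi, x$theta_min,
              x$medium_index, x$apodization))
  invisible(x)
}

# pupil apodization values at aperture angles theta (radians)
apodization_values <- function(obj, theta) {
  switch(obj$apodization,
         sqrt_cosine = sqrt(cos(theta)),
         cosine = cos(theta),
         uniform = rep(1, length(theta)))
}
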