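#' Gaussian beam specification
#'
#' Describes a TEM00 Gaussian beam by its wavelength, waist radius and the
#' refractive index of the propagation medium.  All lengths are in
#' micrometres.  The Rayleigh range \eqn{z_R = \pi \omega_0^2 / \lambda},
#' the beam radius \eqn{\omega(z)} and the wavefront curvature radius
#' \eqn{R_c(z)} follow from these three numbers.
#'
#' @param wavelength Vacuum wavelength \eqn{\lambda} (um), > 0.
#' @param waist Beam waist radius \eqn{\omega_0} (um, 1/e^2 intensity
#'   radius), > 0.
#' @param medium_index Refractive index \eqn{n_0} of the medium (>= 1).
#' @return An object of class `gaussian_beam` with fields `wavelength`,
#'   `waist`, `medium_index`.
#' @examples
#' probe <- gaussian_beam(wavelength = 0.633, waist = 0.53, medium_index = 1.0003)
#' rayleigh_range(probe)
#' @export
gaussian_beam <- function(wavelength, waist, medium_index = 1) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L, is.finite(wavelength),
            is.numeric(waist), length(waist) == 1L, is.finite(waist),
            is.numeric(medium_index), length(medium_index) == 1L)
  if (wavelength <= 0) stop("gaussian_beam: 'wavelength' must be > 0 um")
  if (waist <= 0) stop("gaussian_beam: 'waist' must be > 0 um")
  if (medium_index < 1) stop("gaussian_beam: 'medium_index' must be >= 1")
  structure(list(wavelength = wavelength, waist = waist,
                 medium_index = medium_index),
            class = "gaussian_beam")
}

#' @export
print.gaussian_beam <- function(x, ...) {
  cat(sprintf("Gaussian beam: lambda = %g um, w0 = %g um, n0 = %g, zR = %.4g um\n",
              x$wavelength, x$waist, x$medium_index, rayleigh_range(x)))
  invisible(x)
}

#' Rayleigh range of a Gaussian beam
#'
#' @param beam A [gaussian_beam()].
#' @return \eqn{z_R = \pi \omega_0^2 / \lambda} in um.
#' @export
rayleigh_range <- function(beam) {
  stopifnot(inherits(beam, "gaussian_beam"))
  pi * beam$waist^2 / beam$wavelength
}

#' Beam radius and wavefront curvature along the axis
#'
#' Returns \eqn{\omega(z) = \omega_0 \sqrt{1 + z^2/z_R^2}} together with the
#' wavefront radius of curvature \eqn{R_c(z) = z (1 + z_R^2/z^2)} and its
#' reciprocal.  At the waist (`z = 0`) the wavefront is flat: `curvature` is
#' reported as `Inf` as a display sentinel while `inverse_curvature` is
#' exactly 0, and the reciprocal is the quantity consumed by downstream
#' computations (never the infinity itself).  Negative `z` (before the
#' waist) gives a negative curvature radius (converging wavefront).
#'
#' @param beam A [gaussian_beam()].
#' @param z Axial position(s) relative to the waist (um); vectorised.
#' @return A list with numeric vectors `radius` (um), `curvature` (um,
#'   `Inf` at the waist) and `inverse_curvature` (1/um, 0 at the waist).
#' @export
beam_radius_and_curvature <- function(beam, z) {
  stopifnot(inherits(beam, "gaussian_beam"), is.numeric(z), all(is.finite(z)))
  zR <- rayleigh_range(beam)
  radius <- beam$waist * sqrt(1 + (z / zR)^2)
  inv_rc <- z / (z^2 + zR^2)
  curvature <- ifelse(z == 0, Inf, 1 / inv_rc)
  list(radius = radius, curvature = curvature, inverse_curvature = inv_rc)
}

#' Pump (heating) laser drive settings
#'
#' Average power, duty cycle and modulation frequency of the modulated pump
#' laser.  The peak power during the on-phase is
#' \eqn{P_{max} = P_{avg} / \beta}.
#'
#' @param average_power Average optical power \eqn{P_{avg}} at the sample (mW).
#' @param duty_cycle Duty cycle \eqn{\beta}, in (0, 1].
#' @param modulation_frequency Modulation frequency \eqn{f_{mod}} (kHz).
#' @return An object of class `pump_drive`.
#' @export
pump_drive <- function(average_power, duty_cycle, modulation_frequency) {
  stopifnot(is.numeric(average_power), length(average_power) == 1L,
            is.numeric(duty_cycle), length(duty_cycle) == 1L,
            is.numeric(modulation_frequency), length(modulation_frequency) == 1L)
  if (average_power < 0) stop("pump_drive: 'average_power' must be >= 0 mW")
  if (duty_cycle <= 0 || duty_cycle > 1)
    stop("pump_drive: 'duty_cycle' must be in (0, 1]")
  if (modulation_frequency <= 0)
    stop("pump_drive: 'modulation_frequency' must be > 0 kHz")
  structure(list(average_power = average_power, duty_cycle = duty_cycle,
                 modulation_frequency = modulation_frequency),
            class = "pump_drive")
}

#' Thermal and optical properties of the ambient medium
#'
#' @param thermal_conductivity \eqn{\kappa} (W m^-1 K^-1), > 0.
#' @param specific_heat \eqn{C_p} (J kg^-1 K^-1), > 0.
#' @param density \eqn{\rho} (kg m^-3), > 0.
#' @param refractive_index \eqn{n_0} (>= 1).
#' @param thermo_optic \eqn{dn/dT} (K^-1) at the probe wavelength; negative
#'   for air around 633 nm.
#' @return An object of class `medium_spec`.  Defaults describe dry air at
#'   294 K.
#' @export
medium_spec <- function(thermal_conductivity = 0.0262,
                        specific_heat = 1006,
                        density = 1.204,
                        refractive_index = 1.0003,
                        thermo_optic = -9e-7) {
  vals <- c(thermal_conductivity, specific_heat, density)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("medium_spec: kappa, C_p and rho must all be finite and > 0")
  if (refractive_index < 1) stop("medium_spec: 'refractive_index' must be >= 1")
  structure(list(thermal_conductivity = thermal_conductivity,
                 specific_heat = specific_heat, density = density,
                 refractive_index = refractive_index,
                 thermo_optic = thermo_optic),
            class = "medium_spec")
}

#' Peak intensity of the modulated pump beam
#'
#' Peak on-axis intensity at the waist,
#' \eqn{I_{0,h} = 2 P_{max} / (\pi \omega_0^2)} with
#' \eqn{P_{max} = P_{avg}/\beta}, in SI units.
#'
#' @param drive A [pump_drive()].
#' @param beam The pump [gaussian_beam()].
#' @return Intensity in W m^-2.
#' @export
peak_intensity <- function(drive, beam) {
  stopifnot(inherits(drive, "pump_drive"), inherits(beam, "gaussian_beam"))
  p_max_W <- drive$average_power * 1e-3 / drive$duty_cycle
  w0_m <- beam$waist * 1e-6
  2 * p_max_W / (pi * w0_m^2)
}

#' Thermal diffusion length at the modulation frequency
#'
#' \eqn{R_{th} = \sqrt{2\kappa / (C_p \rho \Omega)}} with the angular
#' modulation frequency \eqn{\Omega = 2\pi f_{mod}}.  This is the
#' penetration depth of the periodic temperature field; the steady-state
#' treatment of the thermal lens requires it to exceed the probe spot
#' radius.
#'
#' @param medium A [medium_spec()].
#' @param modulation_frequency Modulation frequency (kHz); vectorised.
#' @return Length(s) in um.
#' @examples
#' # dry air at 294 K, 50 kHz modulation: about 12 um
#' thermal_diffusion_length(medium_spec(), 50)
#' @export
thermal_diffusion_length <- function(medium, modulation_frequency) {
  stopifnot(inherits(medium, "medium_spec"), is.numeric(modulation_frequency))
  if (any(modulation_frequency <= 0))
    stop("thermal_diffusion_length: 'modulation_frequency' must be > 0 kHz")
  omega <- 2 * pi * modulation_frequency * 1e3
  r_m <- sqrt(2 * medium$thermal_conductivity /
                (medium$specific_heat * medium$density * omega))
  r_m * 1e6
}

#' Convert between intensity FWHM and Gaussian waist radius
#'
#' For a Gaussian intensity profile \eqn{\exp(-2 r^2/\omega_0^2)} the full
#' width at half maximum is \eqn{\sqrt{2 \ln 2}\, \omega_0}, so
#' \eqn{\omega_0 = \mathrm{fwhm} / \sqrt{2 \ln 2}}.  This intensity-profile
#' convention is used throughout the package to derive beam waists from
#' measured resolution figures.
#'
#' @param fwhm Intensity full width at half maximum (um); vectorised.
#' @return Waist radius \eqn{\omega_0} (um).
#' @seealso [fwhm_from_waist()]
#' @export
waist_from_fwhm <- function(fwhm) {
  stopifnot(is.numeric(fwhm))
  if (any(fwhm <= 0)) stop("waist_from_fwhm: 'fwhm' must be > 0")
  fwhm / sqrt(2 * log(2))
}

#' @rdname waist_from_fwhm
#' @param waist Waist radius \eqn{\omega_0} (um); vectorised.
#' @export
fwhm_from_waist <- function(waist) {
  stopifnot(is.numeric(waist))
  if (any(waist <= 0)) stop("fwhm_from_waist: 'waist' must be > 0")
  waist * sqrt(2 * log(2))
}

#' Steady-state validity check for the thermal lens
#'
#' The steady-state temperature profile assumed by the nanolens model holds
#' when the thermal diffusion length exceeds the probe spot radius.
#'
#' @param medium A [medium_spec()].
#' @param modulation_frequency Modulation frequency (kHz).
#' @param probe_spot_radius Probe beam spot radius at the sample (um).
#' @return A list with `ok` (logical, strict `R_th > spot`), `ratio`
#'   (`R_th / spot`), and `diffusion_length` (um).
#' @export
steady_state_check <- function(medium, modulation_frequency, probe_spot_radius) {
  stopifnot(is.numeric(probe_spot_radius), probe_spot_radius > 0)
  r_th <- thermal_diffusion_length(medium, modulation_frequency)
  list(ok = r_th > probe_spot_radius,
       ratio = r_th / probe_spot_radius,
       diffusion_length = r_th)
}
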