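#' Read a (subset of) TOML configuration file
#'
#' Minimal reader for the flat TOML subset used by the package
#' configuration: `[section]` headers, `key = value` pairs with numeric,
#' string, boolean or simple numeric-array values, and `#` comments.
#' Duplicate sections and duplicate keys are rejected.
#'
#' @param path Path to the file.
#' @return A named list of sections, each a named list of values.
#' @export
read_toml <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_toml: file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  strip <- function(s) {
    # remove comments (naive quote handling: '#' inside double quotes kept)
    chars <- strsplit(s, "")[[1]]
    inq <- FALSE
    for (i in seq_along(chars)) {
      if (chars[i] == '"') inq <- !inq
      if (chars[i] == "#" && !inq) return(trimws(substr(s, 1, i - 1)))
    }
    trimws(s)
  }
  parse_value <- function(v, where) {
    v <- trimws(v)
    if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
    if (v %in% c("true", "false")) return(v == "true")
    if (grepl("^\\[.*\\]$", v)) {
      parts <- trimws(strsplit(gsub("^\\[|\\]$", "", v), ",")[[1]])
      nums <- suppressWarnings(as.numeric(parts))
      if (any(is.na(nums))) stop(sprintf("read_toml: unsupported array value at %s", where))
      return(nums)
    }
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) stop(sprintf("read_toml: cannot parse value '%s' at %s", v, where))
    num
  }
  for (ln in seq_along(lines)) {
    s <- strip(lines[ln])
    if (s == "") next
    if (grepl("^\\[.+\\]$", s)) {
      section <- gsub("^\\[|\\]$", "", s)
      if (section %in% names(out))
        stop(sprintf("read_toml: duplicate section [%s] (line %d)", section, ln))
      out[[section]] <- list()
    } else if (grepl("=", s, fixed = TRUE)) {
      if (is.null(section)) stop(sprintf("read_toml: key outside any section (line %d)", ln))
      eq <- regexpr("=", s, fixed = TRUE)
      key <- trimws(substr(s, 1, eq - 1))
      val <- parse_value(substr(s, eq + 1, nchar(s)),
                         sprintf("[%s].%s (line %d)", section, key, ln))
      if (key %in% names(out[[section]]))
        stop(sprintf("read_toml: duplicate key '%s' in [%s] (line %d)", key, section, ln))
      out[[section]][[key]] <- val
    } else {
      stop(sprintf("read_toml: cannot parse line %d: '%s'", ln, s))
    }
  }
  out
}

config_known_keys <- list(
  probe_beam = c("wavelength", "waist"),
  pump_beam = c("wavelength", "wavenumber", "waist"),
  pump_drive = c("average_power", "duty_cycle", "modulation_frequency"),
  medium = c("thermal_conductivity", "specific_heat", "density",
             "refractive_index", "thermo_optic"),
  absorber = c("cross_section", "radius", "focus_offset"),
  detection = c("theta_min", "theta_max", "numerical_aperture"),
  objectives = c("raman_na", "optir_na", "optir_theta_min", "apodization",
                 "annular_collection"),
  grids = c("z_min", "z_max", "z_points", "x_min", "x_max", "x_points"),
  fit = c("normalize", "signed"),
  noise = c("relative_sd", "seed"),
  logging = c("level"))

#' Load and validate a run configuration
#'
#' Reads a TOML configuration with sections `[probe_beam]`, `[pump_beam]`,
#' `[pump_drive]`, `[medium]`, `[absorber]` and `[detection]` (plus
#' optional `[objectives]`, `[grids]`, `[fit]`, `[noise]`, `[logging]`)
#' and assembles the validated model objects.  Unknown keys are rejected
#' with a message naming the key.  The pump wavelength may be given as
#' `wavenumber` (cm^-1), converted via \eqn{\lambda = 10^4/\tilde\nu} um;
#' when both are present the explicit wavelength wins.  The collection
#' half-angle may be given as `theta_max` or derived from
#' `numerical_aperture` via \eqn{\arcsin(NA/n_0)}; if both are given they
#' must agree within 0.1 degrees.
#'
#' The bundled reference configuration is available via
#' `system.file("extdata", "table1.toml", package = "thermopsf")`.
#'
#' @param path Path to the TOML file.
#' @return A list of class `run_config` with elements `scene`
#'   ([thermal_scene()]), `detection` ([detection_geometry()]),
#'   `objectives` (list of [objective()] specs for the Raman and O-PTIR
#'   optical PSFs), and the remaining optional sections as plain lists.
#' @export
load_config <- function(path) {
  raw <- read_toml(path)
  required <- c("probe_beam", "pump_beam", "pump_drive", "medium",
                "absorber", "detection")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop(sprintf("load_config: missing section(s): %s", paste(missing, collapse = ", ")))
  unknown_sec <- setdiff(names(raw), names(config_known_keys))
  if (length(unknown_sec))
    stop(sprintf("load_config: unknown section(s): %s", paste(unknown_sec, collapse = ", ")))
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), config_known_keys[[sec]])
    if (length(bad))
      stop(sprintf("load_config: unknown key '%s' in section [%s]", bad[1], sec))
  }
  need <- function(sec, key) {
    v <- raw[[sec]][[key]]
    if (is.null(v)) stop(sprintf("load_config: missing key '%s' in section [%s]", key, sec))
    v
  }
  med <- medium_spec(thermal_conductivity = need("medium", "thermal_conductivity"),
                     specific_heat = need("medium", "specific_heat"),
                     density = need("medium", "density"),
                     refractive_index = need("medium", "refractive_index"),
                     thermo_optic = need("medium", "thermo_optic"))
  probe <- gaussian_beam(need("probe_beam", "wavelength"),
                         need("probe_beam", "waist"), med$refractive_index)
  lam_h <- raw$pump_beam$wavelength
  if (is.null(lam_h)) {
    wn <- raw$pump_beam$wavenumber
    if (is.null(wn)) stop("load_config: [pump_beam] needs 'wavelength' or 'wavenumber'")
    lam_h <- 1e4 / wn
  }
  pump <- gaussian_beam(lam_h, need("pump_beam", "waist"), 1)
  drive <- pump_drive(need("pump_drive", "average_power"),
                      need("pump_drive", "duty_cycle"),
                      need("pump_drive", "modulation_frequency"))
  dz <- raw$absorber$focus_offset
  scene <- thermal_scene(absorption_cross_section = need("absorber", "cross_section"),
                         bead_radius = need("absorber", "radius"),
                         medium = med, pump = pump, drive = drive, probe = probe,
                         focus_offset = if (is.null(dz)) 0 else dz)
  tmin <- raw$detection$theta_min
  if (is.null(tmin)) tmin <- 0
  tmax <- raw$detection$theta_max
  na_col <- raw$detection$numerical_aperture
  if (!is.null(na_col)) {
    tmax_na <- theta_max_from_na(na_col, med$refractive_index)
    if (!is.null(tmax) && abs(tmax - tmax_na) > 0.1)
      stop(sprintf("load_config: [detection] theta_max (%.2f) and numerical_aperture (-> %.2f deg) disagree by more than 0.1 deg",
                   tmax, tmax_na))
    if (is.null(tmax)) tmax <- tmax_na
  }
  if (is.null(tmax)) stop("load_config: [detection] needs 'theta_max' or 'numerical_aperture'")
  detection <- detection_geometry(tmin, tmax)
  ob <- raw$objectives
  apod <- if (!is.null(ob$apodization)) ob$apodization else "sqrt_cosine"
  raman_na <- if (!is.null(ob$raman_na)) ob$raman_na else 0.55
  optir_na <- if (!is.null(ob$optir_na)) ob$optir_na else 0.5
  optir_tmin <- if (!is.null(ob$optir_theta_min)) ob$optir_theta_min else 21
  annular <- if (!is.null(ob$annular_collection)) ob$annular_collection else TRUE
  objectives <- list(
    raman = objective(raman_na, 0, 1, apod),
    optir_illumination = objective(optir_na, 0, 1, apod),
    optir_collection = objective(optir_na, if (annular) optir_tmin else 0, 1, apod))
  structure(list(scene = scene, detection = detection, objectives = objectives,
                 grids = raw$grids, fit = raw$fit, noise = raw$noise,
                 logging = raw$logging, raw = raw),
            class = "run_config")
}
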