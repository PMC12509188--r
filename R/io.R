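#' Read and write line profiles as two-column CSV
#'
#' The on-disk format is a CSV with header `coordinate_um,intensity`.
#' Malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @return `read_profile()` returns a [line_profile()].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_profile: file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("read_profile: expected a two-column CSV (coordinate_um, intensity)")
  co <- suppressWarnings(as.numeric(df[[1]]))
  iv <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(is.na(co) | is.na(iv))
  if (length(bad))
    stop(sprintf("read_profile: non-numeric value(s) in data row(s) %s of %s",
                 paste(bad, collapse = ", "), path))
  line_profile(co, iv)
}

#' @rdname read_profile
#' @param profile A [line_profile()].
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(coordinate_um = profile$coordinate,
                   intensity = profile$intensity)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# sidecar path convention: <image>.toml next to the image file
sidecar_path <- function(path) paste0(path, ".toml")

write_sidecar <- function(image, path, scale = NULL) {
  lines <- c("[image]",
             sprintf("pixel_pitch_fast = %.12g", image$pixel_pitch_fast),
             sprintf("pixel_pitch_slow = %.12g", image$pixel_pitch_slow),
             sprintf('axes_labels = "%s"', paste(image$axes_labels, collapse = ",")))
  if (!is.null(scale)) lines <- c(lines, sprintf("value_scale = %.12g", scale))
  writeLines(lines, sidecar_path(path))
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop(sprintf(paste0("read_image: sidecar file %s not found; write one with ",
                        "an [image] section holding pixel_pitch_fast and ",
                        "pixel_pitch_slow (um) and optional axes_labels"), sp))
  raw <- readLines(sp, warn = FALSE)
  get_num <- function(key) {
    m <- grep(sprintf("^%s\\s*=", key), raw, value = TRUE)
    if (!length(m)) stop(sprintf("read_image: sidecar %s lacks key '%s'", sp, key))
    as.numeric(trimws(sub(".*=", "", m[1])))
  }
  lab <- grep("^axes_labels\\s*=", raw, value = TRUE)
  labels <- if (length(lab))
    strsplit(gsub('.*=\\s*"|"\\s*$', "", lab[1]), ",")[[1]] else c("x", "z")
  sc <- grep("^value_scale\\s*=", raw, value = TRUE)
  scale <- if (length(sc)) as.numeric(trimws(sub(".*=", "", sc[1]))) else NULL
  list(fast = get_num("pixel_pitch_fast"), slow = get_num("pixel_pitch_slow"),
       labels = labels, scale = scale)
}

#' Read and write scan images
#'
#' Images are stored either as single-page grayscale TIFF (32-bit float)
#' or as a plain CSV grid (rows = slow axis), in both cases accompanied by
#' a `<file>.toml` sidecar recording the pixel pitches in um.  TIFF sample
#' values are clamped to [0, 1] by the format, so the sidecar records a
#' `value_scale` restoring the original amplitude.
#'
#' @param path File path; format chosen by extension (`.tif`/`.tiff` or
#'   `.csv`).
#' @return `read_image()` returns a [scan_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_image: file not found: %s", path))
  sc <- read_sidecar(path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    v <- tiff::readTIFF(path)
    if (length(dim(v)) == 3L) v <- v[, , 1]
    if (!is.null(sc$scale)) v <- v * sc$scale
  } else if (ext == "csv") {
    v <- as.matrix(utils::read.csv(path, header = FALSE))
    if (!is.numeric(v)) stop(sprintf("read_image: non-numeric cells in %s", path))
    dimnames(v) <- NULL
  } else stop(sprintf("read_image: unsupported extension '%s'", ext))
  scan_image(v, sc$fast, sc$slow, sc$labels)
}

#' @rdname read_image
#' @param image A [scan_image()].
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "scan_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    v <- image$pixel_values
    scale <- max(v, 1e-300)
    tiff::writeTIFF(v / scale, path, bits.per.sample = 32)
    write_sidecar(image, path, scale = scale)
  } else if (ext == "csv") {
    utils::write.table(image$pixel_values, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    write_sidecar(image, path)
  } else stop(sprintf("write_image: unsupported extension '%s'", ext))
  invisible(path)
}

#' Write a machine-readable settings snapshot
#'
#' Every command-line subcommand writes a JSON snapshot of its effective
#' settings next to its output file (reproducibility contract).
#'
#' @param settings Named list.
#' @param out_path Output file the snapshot accompanies.
#' @return The snapshot path, invisibly.
#' @export
write_settings_snapshot <- function(settings, out_path) {
  sp <- paste0(out_path, ".settings.json")
  jsonlite::write_json(settings, sp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sp)
}
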