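#' Read and write sky images
#'
#' Reads PNG, TIFF or JPEG rasters to 8-bit `sky_image` objects (16-bit
#' TIFF sources are scaled to 8 bits by discarding the low byte, i.e. a
#' right shift; 65535 maps to 255). Writing supports lossless PNG (8-bit)
#' and TIFF (8- or 16-bit); JPEG is read-only.
#'
#' @param path file path; format inferred from the extension.
#' @param image a `sky_image` or matrix/array on the 8-bit scale.
#' @param bits 8 or 16, TIFF output depth.
#' @return `read_image` returns a `sky_image` (grayscale matrix or H x W x 3
#'   array); `write_image` returns `path` invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = {
      x <- png::readPNG(path)
      round_half_up(x * 255)
    },
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, as.is = TRUE)
      bits <- attr(x, "bits.per.sample")
      if (!is.null(bits) && bits == 16) x %/% 256L
      else if (max(x) > 255) x %/% 256L
      else x
    },
    jpg = ,
    jpeg = {
      x <- EBImage::readImage(path)
      # EBImage stores x (width) in dim 1; transpose to row/col
      d <- dim(x)
      if (length(d) == 3) {
        a <- array(0, c(d[2], d[1], d[3]))
        for (ch in seq_len(d[3])) a[, , ch] <- t(x[, , ch])
        round_half_up(a[, , 1:3, drop = FALSE] * 255)
      } else round_half_up(t(as.matrix(x)) * 255)
    },
    stop("unsupported image format: ", ext))
  if (is_rgb(px) && dim(px)[3] > 3) px <- px[, , 1:3]
  new_sky_image(px)
}

#' @rdname read_image
#' @export
write_image <- function(image, path, bits = 8) {
  px <- if (inherits(image, "sky_image")) image$pixels else image
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px / 255, path),
    tif = ,
    tiff = {
      if (bits == 16) tiff::writeTIFF((px * 257) / 65535, path,
                                      bits.per.sample = 16)
      else tiff::writeTIFF(px / 255, path, bits.per.sample = 8)
    },
    stop("unsupported output format: ", ext))
  invisible(path)
}

config_defaults <- function() {
  list(
    sky = list(band_angle_deg = 30, band_length_frac = 0.95,
               band_width_px = 20, band_peak = 0.8, gradient_ratio = 0.5,
               n_stars = 120, star_peak_range = c(0.3, 1),
               star_psf_sigma_px = 1.5, background = 0.12,
               noise_sigma = 0.02, aperture = "circular", seed = 1L,
               width = 400L, height = 400L),
    blur = list(intensity = 0.5, kernel_size = 100L, seed = 1L,
                epsilon = 0.1),
    mwoa = list(median_window = 5L, dilation_radius = 5L,
                min_object_frac = 0.001, channel_combine = "mean",
                channel_index = 1L),
    radon = list(angle_step_deg = 1, input = "gray"),
    bench = list(n_sets = 12L, frames_per_set = 72L, step_deg = 5,
                 blur_realisations_per_set = 2L, blur_intensity = 0.5,
                 blur_size = 100L, estimator = c("mwoa", "radon"),
                 master_seed = 1L, image_size = 400L,
                 mode = "digital_rotate", radon_step_deg = 1),
    log_level = "info",
    output_dir = "."
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file, checks every key against the
#' documented schema (sections `sky`, `blur`, `mwoa`, `radon`, `bench`,
#' plus `log_level` and `output_dir`), rejects unknown keys and type
#' mismatches with their full key paths, and fills unset keys with the
#' package defaults. An empty file yields all defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or `NULL` for pure
#'   defaults.
#' @return a validated configuration list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    user <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
            else if (ext == "json") jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
            else stop("config must be YAML or JSON")
    if (is.null(user)) user <- list()
  }
  errs <- character(0)
  merged <- defaults
  for (key in names(user)) {
    if (!key %in% names(defaults)) {
      errs <- c(errs, sprintf("unknown key: %s", key))
      next
    }
    if (is.list(defaults[[key]])) {
      sub <- user[[key]]
      if (!is.list(sub)) {
        errs <- c(errs, sprintf("%s: expected a mapping", key))
        next
      }
      for (sk in names(sub)) {
        pathk <- paste(key, sk, sep = ".")
        if (!sk %in% names(defaults[[key]])) {
          errs <- c(errs, sprintf("unknown key: %s", pathk))
        } else if (is.numeric(defaults[[key]][[sk]]) &&
                   !is.numeric(sub[[sk]])) {
          errs <- c(errs, sprintf("%s: expected a number, got %s", pathk,
                                  class(sub[[sk]])[1]))
        } else if (is.character(defaults[[key]][[sk]]) &&
                   !is.character(sub[[sk]])) {
          errs <- c(errs, sprintf("%s: expected a string, got %s", pathk,
                                  class(sub[[sk]])[1]))
        } else {
          merged[[key]][[sk]] <- sub[[sk]]
        }
      }
    } else {
      if (is.character(defaults[[key]]) && !is.character(user[[key]]))
        errs <- c(errs, sprintf("%s: expected a string", key))
      else merged[[key]] <- user[[key]]
    }
  }
  if (length(errs) > 0)
    stop("config errors:\n  ", paste(errs, collapse = "\n  "))
  structure(merged, class = "run_config")
}
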