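#' Parametric model of a synthetic night sky
#'
#' Describes a simulated night sky: a bright extended band (the Milky Way)
#' with a Gaussian cross-section and a linear intensity gradient along its
#' axis, a field of point-source stars, a uniform light-pollution background
#' and additive Gaussian noise. Rendering a model with [render_sky()] is
#' fully deterministic given the seed.
#'
#' All intensities are on a linear `[0, 1]` scale before 8-bit quantisation.
#' The `background` level emulates the Bortle light-pollution scale: around
#' 0.08 for a rural (Bortle 3) sky and 0.12 for a rural/suburban transition
#' (Bortle 4) sky. The along-axis gradient emulates the band's increase in
#' brightness towards the galactic core (in the southern sky, from north to
#' south).
#'
#' @param band_angle_deg axial angle of the band's major axis, degrees in
#'   `(-90, 90]`. The convention throughout the package is x = column index
#'   increasing rightward, y = -(row index), angles counterclockwise from +x.
#' @param band_length_frac band length as a fraction of the image diagonal.
#' @param band_width_px Gaussian cross-section sigma of the band, pixels.
#' @param band_peak peak band intensity in `[0, 1]`.
#' @param gradient_ratio intensity at the band's dim end divided by the
#'   intensity at its bright end, in `(0, 1]`.
#' @param n_stars number of point sources.
#' @param star_peak_range length-2 numeric, min/max star peak intensity;
#'   individual peaks are drawn log-uniformly in this range.
#' @param star_psf_sigma_px Gaussian point-spread sigma of stars, pixels.
#' @param background uniform sky background level in `[0, 1]`.
#' @param noise_sigma additive Gaussian noise sigma (intensity units).
#' @param aperture `"circular"` (default) restricts the rendered sky to the
#'   centred inscribed circle, with pixels outside it held at the
#'   background level — an upward-looking circular field of view. This also
#'   makes analytically re-rendered and digitally rotated sequences share
#'   the same visible geometry. `"square"` renders the full frame.
#' @param seed integer RNG seed fixing star positions, peaks and noise.
#' @return an object of class `sky_model`.
#' @seealso [render_sky()], [make_rotation_sequence()]
#' @examples
#' m <- sky_model(band_angle_deg = 30, seed = 1)
#' img <- render_sky(m, 128, 128)
#' @export
sky_model <- function(band_angle_deg = 30,
                      band_length_frac = 0.95,
                      band_width_px = 20,
                      band_peak = 0.8,
                      gradient_ratio = 0.5,
                      n_stars = 120,
                      star_peak_range = c(0.3, 1),
                      star_psf_sigma_px = 1.5,
                      background = 0.12,
                      noise_sigma = 0.02,
                      aperture = c("circular", "square"),
                      seed = 1L) {
  aperture <- match.arg(aperture)
  if (!is.numeric(band_angle_deg) || band_angle_deg <= -90 ||
      band_angle_deg > 90)
    stop("band_angle_deg must lie in (-90, 90]")
  if (band_width_px <= 0) stop("band_width_px must be positive")
  if (band_length_frac <= 0) stop("band_length_frac must be positive")
  for (f in c(band_peak, gradient_ratio, background))
    if (f < 0 || f > 1) stop("intensity parameters must lie in [0, 1]")
  if (gradient_ratio <= 0) stop("gradient_ratio must lie in (0, 1]")
  if (n_stars < 0) stop("n_stars must be >= 0")
  if (length(star_peak_range) != 2 || any(star_peak_range < 0) ||
      any(star_peak_range > 1) || star_peak_range[1] > star_peak_range[2])
    stop("star_peak_range must be an increasing pair in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(band_angle_deg = band_angle_deg,
                 band_length_frac = band_length_frac,
                 band_width_px = band_width_px,
                 band_peak = band_peak,
                 gradient_ratio = gradient_ratio,
                 n_stars = as.integer(n_stars),
                 star_peak_range = as.numeric(star_peak_range),
                 star_psf_sigma_px = star_psf_sigma_px,
                 background = background,
                 noise_sigma = noise_sigma,
                 aperture = aperture,
                 seed = as.integer(seed)),
            class = "sky_model")
}

#' @export
print.sky_model <- function(x, ...) {
  cat("Synthetic sky model\n")
  cat(sprintf("  band: %g deg axial, sigma %g px, peak %g, gradient %g\n",
              x$band_angle_deg, x$band_width_px, x$band_peak,
              x$gradient_ratio))
  cat(sprintf("  stars: %d in [%g, %g], psf sigma %g px\n", x$n_stars,
              x$star_peak_range[1], x$star_peak_range[2],
              x$star_psf_sigma_px))
  cat(sprintf("  background %g, noise sigma %g, seed %d\n", x$background,
              x$noise_sigma, x$seed))
  invisible(x)
}

new_sky_image <- function(pixels, gt_angle_deg = NA_real_) {
  structure(list(pixels = pixels, gt_angle_deg = gt_angle_deg),
            class = "sky_image")
}

#' @export
print.sky_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("sky_image %dx%d%s, gt angle %s deg\n", d[1], d[2],
              if (is_rgb(x$pixels)) " RGB" else "",
              format(x$gt_angle_deg)), sep = "")
  invisible(x)
}

#' @export
plot.sky_image <- function(x, ...) {
  px <- x$pixels
  if (is_rgb(px)) px <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  graphics::image(t(px)[, nrow(px):1], col = grDevices::gray.colors(256,
                  start = 0, end = 1), asp = 1, axes = FALSE,
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Render a synthetic night-sky image
#'
#' Draws the model's band as a straight Gaussian-profile ridge through the
#' image centre at `band_angle_deg`, with a linear intensity ramp along its
#' axis from `gradient_ratio * band_peak` at the dim end to `band_peak` at
#' the bright end; adds seeded Gaussian-PSF stars at uniform random
#' positions, the uniform background and Gaussian noise; clips to `[0, 1]`
#' and quantises to 8 bits. Identical models render identical images.
#'
#' @param model a [sky_model()].
#' @param width,height output dimensions in pixels (at least 64).
#' @return a `sky_image`: 8-bit grayscale pixel matrix (`height` x `width`)
#'   plus the ground-truth axial band angle in `[0, 180)`.
#' @export
render_sky <- function(model, width = 400, height = 400) {
  stopifnot(inherits(model, "sky_model"))
  if (width < 64 || height < 64) stop("width and height must be >= 64")
  H <- as.integer(height); W <- as.integer(width)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  col_x <- (seq_len(W)) - cx          # x coordinate per column
  row_y <- -((seq_len(H)) - cy)       # y coordinate per row
  a <- model$band_angle_deg * pi / 180
  # coordinates along (s) and across (d) the band axis
  s <- outer(row_y * sin(a), col_x * cos(a), "+")
  d <- outer(row_y * cos(a), -col_x * sin(a), "+")
  L <- model$band_length_frac * sqrt(H^2 + W^2)
  ramp <- model$gradient_ratio +
    (1 - model$gradient_ratio) * (s / L + 0.5)
  band <- model$band_peak * ramp * exp(-d^2 / (2 * model$band_width_px^2))
  band[abs(s) > L / 2] <- 0
  img <- band + model$background
  with_seed(model$seed, {
    if (model$n_stars > 0) {
      px <- runif(model$n_stars, 1, W)
      py <- runif(model$n_stars, 1, H)
      lo <- log(max(model$star_peak_range[1], 1e-6))
      hi <- log(max(model$star_peak_range[2], 1e-6))
      peaks <- exp(runif(model$n_stars, lo, hi))
      sg <- model$star_psf_sigma_px
      win <- ceiling(4 * sg)
      for (k in seq_len(model$n_stars)) {
        rr <- max(1, floor(py[k] - win)):min(H, ceiling(py[k] + win))
        cc <- max(1, floor(px[k] - win)):min(W, ceiling(px[k] + win))
        blob <- peaks[k] * exp(-(outer((rr - py[k])^2, (cc - px[k])^2, "+")) /
                                 (2 * sg^2))
        img[rr, cc] <- img[rr, cc] + blob
      }
    }
    if (model$noise_sigma > 0)
      img <- img + matrix(rnorm(H * W, 0, model$noise_sigma), H, W)
  })
  if (model$aperture == "circular")
    img[!circular_crop_mask(H, W)] <- model$background
  pixels <- round_half_up(clip01(img) * 255)
  new_sky_image(pixels, gt_angle_deg = model$band_angle_deg %% 180)
}

#' Build a rotation sequence of sky frames
#'
#' Emulates an observer rotating under the sky: frame `k` (0-based) carries
#' ground truth `(start_angle_deg + k * step_deg) mod 180`. With
#' `mode = "rerender"` each frame is rendered analytically at its own band
#' angle; with `mode = "digital_rotate"` frame 0 is rendered once and the
#' remaining frames are obtained by bilinear rotation about the image centre,
#' with a centred circular validity crop (pixels outside the inscribed circle
#' set to the background level) applied to every frame so rotation border
#' artefacts cannot enter the analysis.
#'
#' @param model a [sky_model()]; its `band_angle_deg` is overridden per frame.
#' @param start_angle_deg ground-truth angle of frame 0, degrees.
#' @param step_deg angular increment per frame, degrees (> 0).
#' @param n_frames number of frames (>= 1); 72 frames at 5 degrees cover a
#'   full rotation (the axial ground truth sweeps 0-180 twice).
#' @param mode `"rerender"` or `"digital_rotate"`.
#' @param width,height frame dimensions in pixels.
#' @return a `sky_sequence`: list of `sky_image` frames plus metadata.
#' @export
make_rotation_sequence <- function(model, start_angle_deg = 0, step_deg = 5,
                                   n_frames = 72,
                                   mode = c("rerender", "digital_rotate"),
                                   width = 400, height = 400) {
  stopifnot(inherits(model, "sky_model"))
  mode <- match.arg(mode)
  if (step_deg <= 0) stop("step_deg must be > 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  gts <- (start_angle_deg + (seq_len(n_frames) - 1) * step_deg) %% 180
  frames <- vector("list", n_frames)
  if (mode == "rerender") {
    for (k in seq_len(n_frames)) {
      mk <- model
      mk$band_angle_deg <- wrap_axial(gts[k])
      frames[[k]] <- render_sky(mk, width, height)
      frames[[k]]$gt_angle_deg <- gts[k]
    }
  } else {
    m0 <- model
    m0$band_angle_deg <- wrap_axial(start_angle_deg)
    base <- render_sky(m0, width, height)
    bg <- round_half_up(model$background * 255)
    crop <- circular_crop_mask(height, width)
    for (k in seq_len(n_frames)) {
      delta <- (k - 1) * step_deg
      px <- if (delta == 0) base$pixels else
        rotate_bilinear_cpp(base$pixels, delta, bg)
      px[!crop] <- bg
      frames[[k]] <- new_sky_image(round_half_up(px), gts[k])
    }
  }
  structure(list(frames = frames, gt_angle_deg = gts, mode = mode,
                 step_deg = step_deg, start_angle_deg = start_angle_deg,
                 model = model),
            class = "sky_sequence")
}

circular_crop_mask <- function(H, W) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r2 <- (min(H, W) / 2)^2
  outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, "+") <= r2
}

#' @export
print.sky_sequence <- function(x, ...) {
  cat(sprintf("sky_sequence: %d frames, step %g deg, mode %s, start %g deg\n",
              length(x$frames), x$step_deg, x$mode, x$start_angle_deg))
  invisible(x)
}

#' Write a rotation sequence to disk
#'
#' Writes each frame as an 8-bit PNG plus a sidecar JSON file listing frame
#' filenames and ground-truth angles.
#'
#' @param seq a `sky_sequence`.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return invisibly, the sidecar path.
#' @export
write_sequence <- function(seq, dir, prefix = "frame") {
  stopifnot(inherits(seq, "sky_sequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%03d.png", prefix, seq_along(seq$frames) - 1L)
  for (k in seq_along(seq$frames))
    write_image(seq$frames[[k]], file.path(dir, files[k]))
  sidecar <- file.path(dir, paste0(prefix, "_index.json"))
  jsonlite::write_json(
    list(frames = data.frame(file = files, gt_angle_deg = seq$gt_angle_deg),
         step_deg = seq$step_deg, mode = seq$mode),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
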