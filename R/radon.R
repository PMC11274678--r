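#' Radon transform of an image
#'
#' Line-integral projections of a non-negative image over a grid of
#' projection angles covering `[0, 180)`. Each pixel's intensity is
#' deposited, with linear interpolation, into offset bins along the
#' projection axis `t = x cos(phi) + y sin(phi)` (package axis convention:
#' x = column, y = -row). A thin straight feature oriented at angle `alpha`
#' concentrates its mass into a single offset bin when `phi = alpha + 90`,
#' so the sinogram's global maximum marks the dominant linear structure.
#'
#' @param gray grayscale `sky_image` or matrix.
#' @param angle_step_deg projection-angle spacing in degrees; must divide
#'   180.
#' @return an object of class `sinogram`: `values` (offset x angle matrix)
#'   and `angle_grid_deg`.
#' @export
radon_transform <- function(gray, angle_step_deg = 1) {
  px <- if (inherits(gray, "sky_image")) gray$pixels else gray
  if (is_rgb(px)) stop("radon_transform expects a grayscale image")
  if (angle_step_deg <= 0 || abs(180 / angle_step_deg -
                                 round(180 / angle_step_deg)) > 1e-9)
    stop("angle_step_deg must divide 180")
  angles <- seq(0, 180 - angle_step_deg, by = angle_step_deg)
  values <- radon_cpp(px, angles)
  structure(list(values = values, angle_grid_deg = angles),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("sinogram: %d offsets x %d angles (step %g deg)\n",
              nrow(x$values), length(x$angle_grid_deg),
              diff(x$angle_grid_deg[1:2])))
  invisible(x)
}

#' Orientation from the Radon-transform maximum
#'
#' Baseline estimator: preprocesses the frame to grayscale (same median
#' filtering and channel combination as the moment pipeline), computes the
#' sinogram, and returns the orientation whose projection column contains
#' the global maximum. The projection angle `phi` of the maximising column
#' corresponds to a feature orientation of `phi - 90` degrees (lines
#' project to a point when viewed side-on); ties are broken towards the
#' smallest projection angle. Optionally the binary Otsu mask can be fed to
#' the transform instead of the grayscale image.
#'
#' @param image a `sky_image`, matrix or RGB array.
#' @param angle_step_deg angle grid spacing, degrees (default 1).
#' @param params a [mwoa_params()] used for preprocessing.
#' @param input `"gray"` (default) to transform the preprocessed image,
#'   `"mask"` to transform the binary Otsu mask.
#' @param preprocessed set to `TRUE` when `image` is already the output of
#'   [preprocess()].
#' @return axial orientation in degrees `(-90, 90]`.
#' @examples
#' img <- render_sky(sky_model(band_angle_deg = 40, seed = 2), 128, 128)
#' radon_angle(img)
#' @export
radon_angle <- function(image, angle_step_deg = 1, params = mwoa_params(),
                        input = c("gray", "mask"), preprocessed = FALSE) {
  input <- match.arg(input)
  g <- if (preprocessed) image else preprocess(image, params)
  px <- g$pixels
  if (max(px) == min(px)) stop("degenerate input: constant image")
  if (input == "mask") {
    ot <- otsu_threshold(g)
    px <- build_mask(g, ot, params)$mask * 1
  }
  # circular support: outside the inscribed circle the projection chord
  # length varies with angle (longest on the frame diagonals), which biases
  # the argmax towards 45 degrees on background-dominated skies; zeroing
  # that region is the standard sinogram convention
  px <- px * circular_crop_mask(nrow(px), ncol(px))
  sino <- radon_transform(px, angle_step_deg)
  j <- (which.max(sino$values) - 1) %/% nrow(sino$values) + 1
  wrap_axial(sino$angle_grid_deg[j] - 90)
}
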