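#' Parameters of the Milky Way orientation pipeline
#'
#' Tunables of the detection pipeline ([mwoa_angle()]): the median-filter
#' window applied per channel, the disc radius used to dilate the Otsu mask,
#' the minimum object area kept (as a fraction of the image area), and how
#' RGB channels are combined into the grayscale image that is thresholded.
#'
#' @param median_window odd median-filter window size, pixels (>= 3).
#' @param dilation_radius radius of the flat disc structuring element (>= 1).
#' @param min_object_frac minimum object area as a fraction of the image
#'   area, in `[0, 0.1]`.
#' @param channel_combine `"mean"` (unweighted channel mean) or
#'   `"single_channel"` (use `channel_index`).
#' @param channel_index which channel to keep when
#'   `channel_combine = "single_channel"`.
#' @return an object of class `mwoa_params`.
#' @export
mwoa_params <- function(median_window = 5L, dilation_radius = 5L,
                        min_object_frac = 0.001,
                        channel_combine = c("mean", "single_channel"),
                        channel_index = 1L) {
  channel_combine <- match.arg(channel_combine)
  if (median_window < 3 || median_window %% 2 == 0)
    stop("median_window must be odd and >= 3")
  if (dilation_radius < 1) stop("dilation_radius must be >= 1")
  if (min_object_frac < 0 || min_object_frac > 0.1)
    stop("min_object_frac must lie in [0, 0.1]")
  structure(list(median_window = as.integer(median_window),
                 dilation_radius = as.integer(dilation_radius),
                 min_object_frac = min_object_frac,
                 channel_combine = channel_combine,
                 channel_index = as.integer(channel_index)),
            class = "mwoa_params")
}

# Median filter with symmetric-reflect borders on 8-bit data. EBImage's
# constant-time median filter is exact for intensities of the form k/255
# (it quantises to 2^16 - 1 = 255 * 257 levels).
median_filter_8bit <- function(px, window) {
  r <- (window - 1L) %/% 2L
  H <- nrow(px); W <- ncol(px)
  ridx <- c(r:1, 1:H, H:(H - r + 1))
  cidx <- c(r:1, 1:W, W:(W - r + 1))
  padded <- px[ridx, cidx] / 255
  out <- EBImage::medianFilter(padded, r) * 255
  round_half_up(out[r + seq_len(H), r + seq_len(W)])
}

#' Filter and combine channels into a grayscale frame
#'
#' Median-filters each channel of an 8-bit image with reflected borders,
#' then combines RGB channels (default: unweighted mean, rounded half up).
#' Grayscale input is filtered and passed through.
#'
#' @param image a `sky_image` or raw matrix / H x W x 3 array (8-bit scale).
#' @param params a [mwoa_params()].
#' @return a grayscale `sky_image`.
#' @export
preprocess <- function(image, params = mwoa_params()) {
  px <- if (inherits(image, "sky_image")) image$pixels else image
  gt <- if (inherits(image, "sky_image")) image$gt_angle_deg else NA_real_
  if (is_rgb(px)) {
    f <- lapply(1:3, function(ch)
      median_filter_8bit(px[, , ch], params$median_window))
    g <- if (params$channel_combine == "mean")
      round_half_up((f[[1]] + f[[2]] + f[[3]]) / 3)
    else f[[params$channel_index]]
  } else {
    g <- median_filter_8bit(px, params$median_window)
  }
  new_sky_image(g, gt)
}

#' Otsu statistics from a grey-level histogram
#'
#' Histogram-level entry point used by [otsu_threshold()]: takes the
#' per-level pixel counts directly (levels `0 .. length(counts) - 1`).
#'
#' @param counts integer vector of per-level pixel counts (length 256 for
#'   8-bit data).
#' @return an `otsu_computation`, see [otsu_threshold()].
#' @export
otsu_from_counts <- function(counts) {
  L <- length(counts)
  N <- sum(counts)
  p <- counts / N
  lv <- seq_len(L) - 1
  omega0 <- cumsum(p)
  omega1 <- 1 - omega0
  mu_cum <- cumsum(lv * p)
  mu_total <- mu_cum[L]
  mu0 <- mu_cum / omega0
  mu1 <- (mu_total - mu_cum) / omega1
  # thresholds where both classes are non-empty
  n_cum <- cumsum(counts)
  valid <- n_cum > 0 & n_cum < N
  bcv <- rep(NA_real_, L)
  bcv[valid] <- omega0[valid] * (mu0[valid] - mu_total)^2 +
    omega1[valid] * (mu1[valid] - mu_total)^2
  if (!any(valid))
    stop("degenerate input: constant image has no Otsu threshold")
  threshold <- as.integer(lv[which.max(bcv)])  # smallest t at the maximum
  structure(list(levels = L, counts = counts, total = N, probs = p,
                 omega0 = omega0, omega1 = omega1, mu0 = mu0, mu1 = mu1,
                 mu_total = mu_total, bcv = bcv, threshold = threshold),
            class = "otsu_computation")
}

#' Otsu threshold by between-class variance maximisation
#'
#' Builds the 256-level histogram of an 8-bit grayscale image and, for every
#' threshold `t` splitting the levels into classes `C0 = {0..t}` and
#' `C1 = {t+1..255}` with both classes non-empty, evaluates the between-class
#' variance `omega0*(mu0 - muT)^2 + omega1*(mu1 - muT)^2`. The selected
#' threshold is the smallest `t` attaining the maximum; the binarisation rule
#' downstream is `pixel > t`.
#'
#' @param gray a grayscale `sky_image` or matrix with values in 0..255.
#' @return an object of class `otsu_computation` holding the histogram,
#'   class probabilities and means per threshold, the between-class variance
#'   curve and the selected `threshold`.
#' @export
otsu_threshold <- function(gray) {
  px <- if (inherits(gray, "sky_image")) gray$pixels else gray
  if (is_rgb(px)) stop("otsu_threshold expects a grayscale image")
  counts <- tabulate(as.integer(px) + 1L, nbins = 256L)
  otsu_from_counts(counts)
}

#' @export
print.otsu_computation <- function(x, ...) {
  cat(sprintf("Otsu threshold: t = %d (between-class variance %.4g)\n",
              x$threshold, max(x$bcv, na.rm = TRUE)))
  invisible(x)
}

#' Binary Milky Way mask from a thresholded frame
#'
#' Thresholds the grayscale frame at the Otsu level (`pixel > t`), dilates
#' the result with a flat Euclidean disc, removes 8-connected components
#' whose area falls below `min_object_frac * H * W`, and returns the
#' resulting mask with its component labelling.
#'
#' @param gray grayscale `sky_image` or matrix (0..255).
#' @param otsu an [otsu_threshold()] result (or a bare threshold number).
#' @param params a [mwoa_params()].
#' @return an object of class `binary_mask`: logical `mask`, integer
#'   `labels`, component `areas`, and `n_components`.
#' @export
build_mask <- function(gray, otsu, params = mwoa_params()) {
  px <- if (inherits(gray, "sky_image")) gray$pixels else gray
  t <- if (inherits(otsu, "otsu_computation")) otsu$threshold else otsu
  mask <- (px > t) * 1
  if (!any(mask > 0)) stop("no object: all pixels at or below threshold")
  dil <- EBImage::dilate(mask, disc_brush(params$dilation_radius))
  lab <- label8_cpp(matrix(as.integer(dil > 0), nrow(dil), ncol(dil)))
  areas <- tabulate(lab[lab > 0])
  min_area <- params$min_object_frac * nrow(px) * ncol(px)
  keep <- which(areas >= min_area)
  if (length(keep) == 0) stop("no object: all components below minimum area")
  drop <- !(lab %in% c(0L, keep))
  lab[drop] <- 0L
  # renumber kept components densely, preserving order
  lab <- array(match(lab, c(0L, keep)) - 1L, dim = dim(lab))
  structure(list(mask = lab > 0, labels = lab, areas = areas[keep],
                 n_components = length(keep)),
            class = "binary_mask")
}

#' Region orientation from normalised second central moments
#'
#' Computes the centroid of the largest 8-connected foreground component and
#' its normalised second central moments `mu_xx = sum(x^2)/N + 1/12`,
#' `mu_yy = sum(y^2)/N + 1/12`, `mu_xy = sum(x y)/N`, where x and y are
#' pixel coordinates relative to the centroid (x = column, y = -row) and
#' 1/12 is the second moment of a unit pixel. The major-axis angle follows
#' from the branch rule
#' \deqn{num = \mu_{yy} - \mu_{xx} + \sqrt{(\mu_{yy}-\mu_{xx})^2 +
#'   4\mu_{xy}^2},\; den = 2\mu_{xy} \quad (\mu_{yy} > \mu_{xx})}
#' \deqn{num = 2\mu_{xy},\; den = \mu_{xx} - \mu_{yy} +
#'   \sqrt{(\mu_{xx}-\mu_{yy})^2 + 4\mu_{xy}^2} \quad (otherwise)}
#' with `orientation = (180/pi) * atan(num/den)` in `(-90, 90]`; a perfectly
#' circular region (`num = den = 0`) returns 0.
#'
#' @param mask a [build_mask()] result, or a logical/0-1 matrix.
#' @return an object of class `region_moments`.
#' @export
region_orientation <- function(mask) {
  if (inherits(mask, "binary_mask")) {
    lab <- mask$labels
  } else {
    m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
    lab <- label8_cpp(m)
  }
  if (!any(lab > 0)) stop("no object: empty mask")
  areas <- tabulate(lab[lab > 0])
  biggest <- which.max(areas)
  idx <- which(lab == biggest, arr.ind = TRUE)
  n <- nrow(idx)
  x <- idx[, 2]
  y <- -idx[, 1]
  cx <- mean(x); cy <- mean(y)
  xc <- x - cx; yc <- y - cy
  mu_xx <- sum(xc^2) / n + 1 / 12
  mu_yy <- sum(yc^2) / n + 1 / 12
  mu_xy <- sum(xc * yc) / n
  if (mu_yy > mu_xx) {
    num <- mu_yy - mu_xx + sqrt((mu_yy - mu_xx)^2 + 4 * mu_xy^2)
    den <- 2 * mu_xy
  } else {
    num <- 2 * mu_xy
    den <- mu_xx - mu_yy + sqrt((mu_xx - mu_yy)^2 + 4 * mu_xy^2)
  }
  orientation <- if (num == 0 && den == 0) 0 else atan2(num, den) * 180 / pi
  orientation <- wrap_axial(orientation)
  structure(list(n_pixels = n, centroid_x = cx, centroid_y = cy,
                 mu_xx = mu_xx, mu_yy = mu_yy, mu_xy = mu_xy,
                 num = num, den = den, orientation_deg = orientation),
            class = "region_moments")
}

#' @export
print.region_moments <- function(x, ...) {
  cat(sprintf("region_moments: %d px, centroid (%.2f, %.2f), orientation %.3f deg\n",
              x$n_pixels, x$centroid_x, x$centroid_y, x$orientation_deg))
  invisible(x)
}

#' Milky Way orientation of a frame
#'
#' The full detection-and-orientation pipeline: per-channel median
#' filtering and channel combination ([preprocess()]), Otsu thresholding
#' ([otsu_threshold()]), mask construction by dilation and small-object
#' removal ([build_mask()]), and major-axis orientation of the dominant
#' component from its normalised second central moments
#' ([region_orientation()]).
#'
#' @param image a `sky_image`, matrix or H x W x 3 array (8-bit scale).
#' @param params a [mwoa_params()].
#' @param preprocessed set to `TRUE` when `image` is already the output of
#'   [preprocess()] (avoids filtering twice when several estimators share a
#'   frame).
#' @return `mwoa_angle` returns the axial orientation in degrees
#'   `(-90, 90]`; `mwoa_estimate` additionally returns the threshold, mask
#'   pixel count and moment details.
#' @examples
#' img <- render_sky(sky_model(band_angle_deg = 40, seed = 2), 128, 128)
#' mwoa_angle(img)
#' @export
mwoa_angle <- function(image, params = mwoa_params(), preprocessed = FALSE) {
  mwoa_estimate(image, params, preprocessed)$angle_deg
}

#' @rdname mwoa_angle
#' @export
mwoa_estimate <- function(image, params = mwoa_params(),
                          preprocessed = FALSE) {
  g <- if (preprocessed) image else preprocess(image, params)
  ot <- otsu_threshold(g)
  mask <- build_mask(g, ot, params)
  mom <- region_orientation(mask)
  list(angle_deg = mom$orientation_deg, threshold = ot$threshold,
       n_mask_pixels = sum(mask$mask), n_components = mask$n_components,
       moments = mom)
}
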