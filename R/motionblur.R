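#' Specification of a random-walk motion-blur kernel
#'
#' Parameters of the stochastic point-spread-function generator. A blur
#' trajectory is a random walk whose total length budget, step lengths and
#' per-step turning angles are all governed by a single dimensionless
#' `intensity` in `[0, 1]`:
#'
#' * path budget: `(U(0,1) + U(0, intensity^2)) * diagonal * 0.75`
#' * step length: `Beta(1, 30) * (1 - intensity + epsilon) * diagonal`
#' * maximum turning angle: `U(0, intensity * pi)` radians
#' * per-step turning angle: `Triangular(0, intensity * angle_max,
#'   angle_max + epsilon)` with an independent random sign
#'
#' where `diagonal = kernel_size * sqrt(2)` and `epsilon = 0.1` is a small
#' constant for numerical stability. Low intensity gives short, nearly
#' straight trails; high intensity gives long, strongly meandering ones.
#'
#' @param intensity blur intensity in `[0, 1]`.
#' @param kernel_size side length of the square kernel, pixels (>= 3).
#' @param seed integer RNG seed.
#' @param epsilon numerical-stability constant (default 0.1).
#' @return an object of class `blur_spec` (with the derived `diagonal`).
#' @seealso [sample_blur_path()], [make_blur_kernel()]
#' @export
blur_spec <- function(intensity, kernel_size = 100L, seed = 1L,
                      epsilon = 0.1) {
  if (!is.numeric(intensity) || intensity < 0 || intensity > 1)
    stop("intensity must lie in [0, 1]")
  if (kernel_size < 3) stop("kernel_size must be >= 3")
  structure(list(intensity = intensity,
                 kernel_size = as.integer(kernel_size),
                 diagonal = kernel_size * sqrt(2),
                 epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "blur_spec")
}

#' Sample a random motion-blur trajectory
#'
#' Draws the path budget, step lengths and signed turning angles described in
#' [blur_spec()] and accumulates them into a 2-D polyline. Steps are drawn
#' until their cumulative length reaches the budget, so the realised path
#' length exceeds `path_max` by at most one step. Headings accumulate from a
#' uniform random initial heading. Deterministic for a fixed seed.
#'
#' @param spec a [blur_spec()].
#' @return an object of class `blur_path` with fields `path_max`, `steps`,
#'   `angle_max`, `angles` (signed, radians), and `vertices`
#'   (`length(steps) + 1` rows of x/y positions in pixels).
#' @export
sample_blur_path <- function(spec) {
  stopifnot(inherits(spec, "blur_spec"))
  with_seed(spec$seed, {
    intensity <- spec$intensity
    eps <- spec$epsilon
    diag_ <- spec$diagonal
    path_max <- (runif(1) + runif(1, 0, intensity^2)) * diag_ * 0.75
    steps <- numeric(0)
    total <- 0
    while (total < path_max) {
      st <- rbeta(1, 1, 30) * (1 - intensity + eps) * diag_
      steps <- c(steps, st)
      total <- total + st
    }
    angle_max <- runif(1, 0, intensity * pi)
    n <- length(steps)
    angles <- numeric(0)
    headings <- numeric(0)
    if (n > 0) {
      angles <- rtri(n, 0, intensity * angle_max, angle_max + eps) *
        sample(c(-1, 1), n, replace = TRUE)
      heading0 <- runif(1, 0, 2 * pi)
      headings <- heading0 + cumsum(angles)
    }
    vertices <- cbind(x = c(0, cumsum(steps * cos(headings))),
                      y = c(0, cumsum(steps * sin(headings))))
    structure(list(path_max = path_max, steps = steps,
                   angle_max = angle_max, angles = angles,
                   vertices = vertices, spec = spec),
              class = "blur_path")
  })
}

#' Rasterise a blur trajectory into a normalised kernel
#'
#' Translates the path so its bounding-box centre coincides with the kernel's
#' geometric centre, then deposits mass along each segment by supersampling
#' (at least 8 sample points per pixel of length, each bilinearly split over
#' the 4 neighbouring pixels). Samples falling outside the kernel are
#' discarded before the matrix is normalised to unit sum.
#'
#' @param path a [sample_blur_path()] result.
#' @param kernel_size side length of the square kernel, pixels.
#' @return an object of class `blur_kernel`: a non-negative
#'   `kernel_size x kernel_size` matrix `weights` summing to 1.
#' @export
rasterize_kernel <- function(path, kernel_size) {
  stopifnot(inherits(path, "blur_path"))
  k <- as.integer(kernel_size)
  v <- path$vertices
  if (nrow(v) < 1) stop("empty path")
  centre <- (k + 1) / 2
  # bounding-box centre -> kernel centre
  sx <- centre - (min(v[, "x"]) + max(v[, "x"])) / 2
  sy <- centre - (min(v[, "y"]) + max(v[, "y"])) / 2
  xs <- v[, "x"] + sx
  ys <- v[, "y"] + sy
  W <- matrix(0, k, k)
  deposit <- function(px, py, w) {
    # bilinear splat; x maps to columns, y to rows (top row = 1)
    c0 <- floor(px); r0 <- floor(py)
    fc <- px - c0; fr <- py - r0
    for (dd in list(c(0, 0, (1 - fr) * (1 - fc)),
                    c(0, 1, (1 - fr) * fc),
                    c(1, 0, fr * (1 - fc)),
                    c(1, 1, fr * fc))) {
      rr <- r0 + dd[[1]]; cc <- c0 + dd[[2]]
      keep <- rr >= 1 & rr <= k & cc >= 1 & cc <= k & dd[[3]] > 0
      if (any(keep)) {
        idx <- cbind(rr[keep], cc[keep])
        vals <- (w * dd[[3]])[keep]
        # accumulate (indices may repeat across samples)
        for (j in seq_along(vals)) W[idx[j, 1], idx[j, 2]] <<-
            W[idx[j, 1], idx[j, 2]] + vals[j]
      }
    }
  }
  if (nrow(v) == 1) {
    deposit(xs, ys, 1)
  } else {
    for (i in seq_len(nrow(v) - 1)) {
      len <- sqrt((xs[i + 1] - xs[i])^2 + (ys[i + 1] - ys[i])^2)
      n <- max(2L, ceiling(8 * len))
      tt <- (seq_len(n) - 0.5) / n
      deposit(xs[i] + tt * (xs[i + 1] - xs[i]),
              ys[i] + tt * (ys[i + 1] - ys[i]),
              rep(len / n, n))
    }
  }
  s <- sum(W)
  if (s <= 0) stop("degenerate kernel: entire path falls outside the kernel")
  structure(list(weights = W / s), class = "blur_kernel")
}

#' @export
print.blur_kernel <- function(x, ...) {
  k <- nrow(x$weights)
  cat(sprintf("blur_kernel %dx%d, peak %.4g, support %d px\n", k, k,
              max(x$weights), sum(x$weights > 0)))
  invisible(x)
}

#' @export
plot.blur_kernel <- function(x, ...) {
  graphics::image(t(x$weights)[, nrow(x$weights):1],
                  col = grDevices::gray.colors(256), asp = 1, axes = FALSE,
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Sample a motion-blur kernel in one call
#'
#' Convenience wrapper: [sample_blur_path()] followed by
#' [rasterize_kernel()] at the spec's `kernel_size`.
#'
#' @param spec a [blur_spec()].
#' @return a `blur_kernel`.
#' @export
make_blur_kernel <- function(spec) {
  rasterize_kernel(sample_blur_path(spec), spec$kernel_size)
}

#' Convolve an image with a blur kernel
#'
#' Per-channel 2-D convolution with symmetric-reflect border handling. Only
#' the kernel's non-zero entries are visited, so sparse trail kernels are
#' cheap even at large sizes. The ground-truth angle is propagated unchanged;
#' the output is clipped to `[0, 255]` and quantised with
#' round-half-away-from-zero.
#'
#' @param image a `sky_image` (or plain matrix / H x W x 3 array).
#' @param kernel a [blur_kernel()] (normalised).
#' @return a blurred `sky_image`.
#' @export
apply_blur <- function(image, kernel) {
  stopifnot(inherits(kernel, "blur_kernel"))
  px <- if (inherits(image, "sky_image")) image$pixels else image
  gt <- if (inherits(image, "sky_image")) image$gt_angle_deg else NA_real_
  K <- kernel$weights
  k <- nrow(K)
  dims <- dim(px)
  if (k > dims[1] || k > dims[2]) stop("kernel larger than image")
  nz <- which(K > 0, arr.ind = TRUE)
  ctr <- floor(k / 2) + 1L
  # convolution: source offset is the negated kernel offset
  dr <- -(nz[, 1] - ctr)
  dc <- -(nz[, 2] - ctr)
  w <- K[nz]
  conv1 <- function(m) shift_sum_reflect_cpp(m, as.integer(dr),
                                             as.integer(dc), w)
  out <- if (is_rgb(px)) {
    a <- array(0, dims)
    for (ch in 1:3) a[, , ch] <- conv1(px[, , ch])
    a
  } else conv1(px)
  out <- round_half_up(pmin(pmax(out, 0), 255))
  new_sky_image(out, gt)
}

#' Peak transmission of a point source through a blur kernel
#'
#' The factor by which a unit point source's peak intensity survives
#' convolution with the kernel: the kernel's maximum entry. A delta kernel
#' returns 1; a long motion trail spreads a star's light over many pixels and
#' returns a small fraction — whereas an extended band's profile is barely
#' affected. This statistic quantifies why the Milky Way remains a usable
#' orientation cue under motion blur while individual stars fade.
#'
#' @param kernel a normalised [blur_kernel()].
#' @return the maximum kernel weight, in `(0, 1]`.
#' @export
point_source_attenuation <- function(kernel) {
  stopifnot(inherits(kernel, "blur_kernel"))
  max(kernel$weights)
}

#' Read/write a blur kernel as a plain-text matrix
#'
#' Kernels are stored as whitespace-delimited text matrices so they remain
#' diffable and portable.
#'
#' @param kernel a `blur_kernel`.
#' @param path file path.
#' @return `write_kernel` returns the path invisibly; `read_kernel` a
#'   `blur_kernel`.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "blur_kernel"))
  utils::write.table(kernel$weights, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  W <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(W) <- NULL
  s <- sum(W)
  if (s <= 0 || any(W < 0)) stop("invalid kernel file")
  structure(list(weights = W / s), class = "blur_kernel")
}
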