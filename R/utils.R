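#' @useDynLib mwcompass, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rbeta rnorm runif sd
#' @importFrom utils write.csv modifyList
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds (< 2^31) from one master seed.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Round half away from zero (all image data is non-negative here).
round_half_up <- function(x) floor(x + 0.5)

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Wrap an angle to the axial range (-90, 90]
#'
#' Orientations of a line are defined modulo 180 degrees. This maps any angle
#' in degrees onto the package's axial convention `(-90, 90]`.
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles in `(-90, 90]`.
#' @export
wrap_axial <- function(deg) {
  out <- ((deg + 90) %% 180) - 90
  out[out == -90] <- 90
  out
}

# Euclidean disc structuring element of the given pixel radius
# (radius 1 is the 4-neighbour diamond).
disc_brush <- function(radius) {
  r <- as.integer(radius)
  d <- outer((-r:r)^2, (-r:r)^2, "+")
  (d <= r^2) * 1
}

# Inverse-CDF sampler for the triangular distribution on [a, b] with mode c.
rtri <- function(n, a, c, b) {
  stopifnot(a <= c, c <= b, b > a)
  u <- runif(n)
  fc <- (c - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

is_rgb <- function(pixels) length(dim(pixels)) == 3L
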