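# Independent oracles and fixture builders used across the test files.

# Brute-force between-class variance maximiser over a 256-level histogram:
# direct class sums per candidate threshold, no shared code with the package.
brute_otsu <- function(counts) {
  lv <- 0:255
  N <- sum(counts)
  muT <- sum(lv * counts) / N
  best_t <- NA_integer_
  best_bcv <- -Inf
  for (t in 0:255) {
    n0 <- sum(counts[lv <= t])
    n1 <- N - n0
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / N; w1 <- n1 / N
    mu0 <- sum(lv[lv <= t] * counts[lv <= t]) / n0
    mu1 <- sum(lv[lv > t] * counts[lv > t]) / n1
    bcv <- w0 * (mu0 - muT)^2 + w1 * (mu1 - muT)^2
    if (bcv > best_bcv + 1e-12) {  # strict: keep smallest t on ties
      best_bcv <- bcv
      best_t <- t
    }
  }
  list(threshold = best_t, bcv = best_bcv)
}

# Principal-axis angle of a pixel set from the covariance eigenvector
# (x = column, y = -row), in degrees (-90, 90].
eigen_orientation <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  x <- idx[, 2]; y <- -idx[, 1]
  C <- stats::cov(cbind(x, y)) * (length(x) - 1) / length(x)
  v <- eigen(C, symmetric = TRUE)$vectors[, 1]
  wrap_axial(atan2(v[2], v[1]) * 180 / pi)
}

# Filled ellipse mask with semi-axes a >= b at axial angle theta (degrees),
# centred in an n x n frame.
ellipse_mask <- function(n, a, b, theta_deg) {
  ct <- cos(theta_deg * pi / 180); st <- sin(theta_deg * pi / 180)
  cc <- (n + 1) / 2
  x <- outer(rep(1, n), seq_len(n) - cc)
  y <- -outer(seq_len(n) - cc, rep(1, n))
  u <- x * ct + y * st
  v <- -x * st + y * ct
  (u / a)^2 + (v / b)^2 <= 1
}

# Minimal hand-built trajectory for rasterisation tests.
path_from_vertices <- function(xy) {
  xy <- matrix(xy, ncol = 2)
  steps <- if (nrow(xy) > 1) sqrt(rowSums(diff(xy)^2)) else numeric(0)
  structure(list(path_max = NA_real_,
                 steps = steps,
                 angle_max = NA_real_, angles = numeric(0),
                 vertices = cbind(x = xy[, 1], y = xy[, 2])),
            class = "blur_path")
}

# The full rotation-under-blur benchmark is expensive; run it once per test
# session and share it between the files that score it.
benchmark_cache <- new.env(parent = emptyenv())
full_benchmark <- function() {
  if (is.null(benchmark_cache$res))
    benchmark_cache$res <- run_benchmark(bench_config(master_seed = 20260927L))
  benchmark_cache$res
}
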