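test_that("zero intensity gives a short, nearly straight path", {
  for (seed in c(1, 17, 300)) {
    p <- sample_blur_path(blur_spec(0, kernel_size = 50, seed = seed))
    expect_equal(p$angle_max, 0)
    expect_true(all(abs(p$angles) < 0.1))           # only the epsilon jitter
    expect_lte(p$path_max, 0.75 * 50 * sqrt(2))
    expect_equal(nrow(p$vertices), length(p$steps) + 1)
    # straightness: end-to-end distance close to total arc length
    chord <- sqrt(sum((p$vertices[nrow(p$vertices), ] - p$vertices[1, ])^2))
    expect_gt(chord / sum(p$steps), 0.98)
  }
})

test_that("step lengths follow the scaled Beta(1, 30) law", {
  # At intensity 1 the scale factor collapses to epsilon, so the mean step
  # is diagonal * 0.1 / 31.
  spec1 <- blur_spec(1, kernel_size = 100, seed = 1)
  steps <- unlist(lapply(1:2000, function(i)
    sample_blur_path(blur_spec(1, 100, seed = i))$steps))
  expect_gt(length(steps), 10000)
  expected <- (1 / 31) * 0.1 * spec1$diagonal
  expect_lt(abs(mean(steps) / expected - 1), 0.05)
})

test_that("path sampling is deterministic and budget-consuming", {
  sp <- blur_spec(0.6, 80, seed = 123)
  a <- sample_blur_path(sp)
  b <- sample_blur_path(sp)
  expect_identical(a, b)
  # steps stop exactly when the budget is crossed
  tot <- cumsum(a$steps)
  expect_gte(tot[length(tot)], a$path_max)
  if (length(tot) > 1) expect_lt(tot[length(tot) - 1], a$path_max)
  expect_error(blur_spec(1.5, 100), "intensity")
})

test_that("rasterised kernels are normalised point-spread functions", {
  for (seed in 1:25) {
    k <- make_blur_kernel(blur_spec(0.5, 64, seed = seed))
    expect_true(all(k$weights >= 0))
    expect_lt(abs(sum(k$weights) - 1), 1e-9)
  }
})

test_that("a single-vertex path rasterises to the identity kernel", {
  p <- path_from_vertices(cbind(0, 0))
  k <- rasterize_kernel(p, 5)
  expect_equal(k$weights[3, 3], 1)
  expect_equal(sum(k$weights), 1)
  img <- render_sky(sky_model(seed = 4, n_stars = 20), 64, 64)
  out <- apply_blur(img, k)
  expect_identical(out$pixels, img$pixels)
  expect_equal(out$gt_angle_deg, img$gt_angle_deg)
})

test_that("a straight path blurs an impulse into a uniform streak", {
  p <- path_from_vertices(cbind(c(-4.5, 4.5), c(0, 0)))  # 9 px horizontal
  k <- rasterize_kernel(p, 15)
  expect_lt(abs(max(k$weights) - 1 / 9) / (1 / 9), 0.2)
  imp <- matrix(0, 31, 31); imp[16, 16] <- 255
  out <- apply_blur(imp, k)
  streak_cols <- range(which(colSums(out$pixels) > 0))
  expect_gte(diff(streak_cols) + 1, 9)
  expect_lte(diff(streak_cols) + 1, 11)
})

test_that("normalised kernels conserve constant images and mean level", {
  k <- make_blur_kernel(blur_spec(0.5, 40, seed = 3))
  const <- matrix(77, 120, 120)
  expect_true(all(apply_blur(const, k)$pixels == 77))
  img <- render_sky(sky_model(seed = 8), 200, 200)
  out <- apply_blur(img, k)
  expect_lt(abs(mean(out$pixels) - mean(img$pixels)), 0.5)
})

test_that("kernels larger than the image are rejected", {
  k <- make_blur_kernel(blur_spec(0.2, 100, seed = 1))
  expect_error(apply_blur(matrix(0, 64, 64), k), "larger than")
})

test_that("point-source attenuation reflects the kernel's peak weight", {
  delta <- rasterize_kernel(path_from_vertices(cbind(0, 0)), 5)
  expect_equal(point_source_attenuation(delta), 1)
  line <- structure(list(weights = matrix(c(rep(0, 45), rep(0.1, 10),
                                            rep(0, 45)), 10, 10)),
                    class = "blur_kernel")
  expect_equal(point_source_attenuation(line), 0.1)
  # attenuation weakens (median) as the path budget grows
  pm <- numeric(100); att <- numeric(100)
  for (i in 1:100) {
    sp <- blur_spec(0.5, 100, seed = 4000 + i)
    pm[i] <- sample_blur_path(sp)$path_max
    att[i] <- point_source_attenuation(make_blur_kernel(sp))
  }
  terc <- cut(pm, stats::quantile(pm, c(0, 1 / 3, 2 / 3, 1)),
              include.lowest = TRUE)
  med <- tapply(att, terc, median)
  expect_true(all(diff(med) <= 0))
  expect_lt(median(att), 0.1)
})

test_that("kernels survive a plain-text round trip", {
  dir <- withr::local_tempdir()
  k <- make_blur_kernel(blur_spec(0.7, 30, seed = 9))
  path <- file.path(dir, "kernel.txt")
  write_kernel(k, path)
  k2 <- read_kernel(path)
  expect_equal(k2$weights, k$weights, tolerance = 1e-12)
})
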