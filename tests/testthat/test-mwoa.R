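test_that("median preprocessing removes impulse noise, keeps constants", {
  const <- matrix(80, 32, 32)
  expect_equal(preprocess(const)$pixels, const)
  salt <- matrix(0, 32, 32); salt[10, 10] <- 255
  expect_true(all(preprocess(salt, mwoa_params(median_window = 3))$pixels == 0))
  rgb <- array(0, c(16, 16, 3))
  rgb[, , 1] <- 10; rgb[, , 2] <- 20; rgb[, , 3] <- 33
  expect_true(all(preprocess(rgb)$pixels == 21))  # mean 21, round half up
  expect_error(mwoa_params(median_window = 4), "odd")
})

test_that("Otsu matches the exhaustive maximiser on hand-built histograms", {
  # two-level image: the variance curve plateaus between the levels and the
  # tie-break must return the smallest threshold
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  ot <- otsu_threshold(img)
  expect_equal(ot$threshold, 10)
  expect_equal(ot$threshold, brute_otsu(ot$counts)$threshold)
  plateau <- ot$bcv[11:200]  # t = 10 .. 199
  expect_true(all(abs(plateau - plateau[1]) < 1e-9))

  counts <- integer(256)
  counts[c(0, 85, 170, 255) + 1] <- 25
  px <- rep(c(0, 85, 170, 255), each = 25)
  ot2 <- otsu_threshold(matrix(px, 10, 10))
  expect_equal(ot2$threshold, brute_otsu(counts)$threshold)
})

test_that("constant images have no Otsu threshold", {
  expect_error(otsu_threshold(matrix(7, 16, 16)), "degenerate")
  expect_error(mwoa_angle(matrix(7, 64, 64)), "degenerate")
})

test_that("mask construction dilates, removes small objects, errors when empty", {
  # a 3x3 block dilated by a radius-1 disc grows into the 21-pixel diamond
  g <- matrix(0, 9, 9); g[4:6, 4:6] <- 255
  m <- build_mask(g, 100, mwoa_params(dilation_radius = 1,
                                      min_object_frac = 0))
  expect_equal(sum(m$mask), 21)
  expect_true(all(which(m$mask, arr.ind = TRUE) >= 3) &&
                all(which(m$mask, arr.ind = TRUE) <= 7))
  corners <- m$mask[cbind(c(3, 3, 7, 7), c(3, 7, 3, 7))]
  expect_true(all(!corners))

  # area filtering happens on the dilated mask (10 px minimum here): a
  # lone pixel dilates to a 5-px diamond and is removed, the block stays
  g2 <- matrix(0, 100, 100)
  g2[10:29, 10:29] <- 255       # 400 px
  g2[80, 60] <- 255             # 1 px
  m2 <- build_mask(g2, 100, mwoa_params(dilation_radius = 1,
                                        min_object_frac = 0.001))
  expect_equal(m2$n_components, 1)
  expect_false(m2$mask[80, 60])
  expect_true(m2$mask[20, 20])

  expect_error(build_mask(matrix(0, 20, 20), 100), "no object")
})

test_that("segment orientations follow the symmetry axes", {
  h <- matrix(0, 21, 21); h[11, 6:16] <- 1
  expect_equal(region_orientation(h)$orientation_deg, 0)
  v <- matrix(0, 21, 21); v[6:16, 11] <- 1
  expect_equal(region_orientation(v)$orientation_deg, 90)
  expect_error(region_orientation(matrix(0, 5, 5)), "no object")
})

test_that("moment orientation matches the covariance eigenvector oracle", {
  m <- ellipse_mask(101, 40, 10, 30)
  est <- region_orientation(m)
  expect_lt(abs(est$orientation_deg - 30), 0.2)
  expect_lt(abs(angle_error(est$orientation_deg, eigen_orientation(m))),
            1e-6)
  # the 1/12 unit-pixel term inflates both diagonal moments
  expect_gte(est$mu_xx, 1 / 12)
  expect_gte(est$mu_yy, 1 / 12)
})

test_that("orientation is invariant to translation and uniform scaling", {
  base <- ellipse_mask(201, 60, 15, -40)
  o0 <- region_orientation(base)$orientation_deg
  shifted <- matrix(FALSE, 201, 201)
  shifted[31:201, 1:171] <- base[1:171, 31:201]
  expect_lt(abs(angle_error(region_orientation(shifted)$orientation_deg, o0)),
            0.2)
  scaled <- ellipse_mask(201, 30, 7.5, -40)
  expect_lt(abs(angle_error(region_orientation(scaled)$orientation_deg, o0)),
            0.2)
})

test_that("moments use the largest component when several remain", {
  m <- matrix(FALSE, 60, 60)
  m[30, 5:55] <- TRUE                      # dominant horizontal bar
  m[5:9, 50:54] <- TRUE                    # small block
  expect_equal(region_orientation(m)$orientation_deg, 0)
})

test_that("the full pipeline recovers a clean band and tolerates blur", {
  img <- render_sky(sky_model(band_angle_deg = 40, seed = 2))
  clean <- mwoa_angle(img)
  expect_lt(abs(angle_error(clean, 40)), 1)
  blurred <- apply_blur(img, make_blur_kernel(blur_spec(0.5, 100, seed = 7)))
  expect_lt(abs(angle_error(mwoa_angle(blurred), clean)), 2)
  est <- mwoa_estimate(img)
  expect_true(est$n_mask_pixels > 0)
  expect_true(est$threshold >= 0 && est$threshold <= 255)
})
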