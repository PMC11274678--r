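test_that("a sourceless model renders a constant background frame", {
  m <- sky_model(n_stars = 0, band_peak = 0, noise_sigma = 0,
                 background = 0.1)
  img <- render_sky(m, 64, 64)
  expect_equal(unique(as.vector(img$pixels)), 26)  # round(0.1 * 255)
  expect_equal(img$gt_angle_deg, 30)
})

test_that("rendering is deterministic: equal models give identical images", {
  m <- sky_model(band_angle_deg = -12, seed = 77)
  a <- render_sky(m, 128, 128)
  b <- render_sky(m, 128, 128)
  expect_identical(a$pixels, b$pixels)
  m2 <- sky_model(band_angle_deg = -12, seed = 78)
  expect_false(identical(a$pixels, render_sky(m2, 128, 128)$pixels))
})

test_that("invalid model parameters are rejected", {
  expect_error(sky_model(band_angle_deg = 120), "band_angle_deg")
  expect_error(sky_model(band_peak = 1.2), "intensity")
  expect_error(sky_model(band_width_px = 0), "band_width_px")
  expect_error(sky_model(n_stars = -1), "n_stars")
  expect_error(render_sky(sky_model(), 32, 128), ">= 64")
})

test_that("sequence ground truth advances modulo 180", {
  m <- sky_model(n_stars = 10)
  s <- make_rotation_sequence(m, 10, 5, 35, "rerender", 64, 64)
  expect_equal(s$gt_angle_deg[35], (10 + 34 * 5) %% 180)  # wraps to 0
  expect_equal(s$gt_angle_deg[35], 0)
  s1 <- make_rotation_sequence(m, 181, 5, 1, "rerender", 64, 64)
  expect_equal(s1$gt_angle_deg, 1)
  expect_length(s1$frames, 1)
})

test_that("rerender and digital rotation agree on labels and estimates", {
  m <- sky_model(band_angle_deg = 20, seed = 5)
  a <- make_rotation_sequence(m, 20, 5, 7, "rerender", 400, 400)
  b <- make_rotation_sequence(m, 20, 5, 7, "digital_rotate", 400, 400)
  expect_identical(a$gt_angle_deg, b$gt_angle_deg)
  for (k in seq_along(a$frames)) {
    d <- angle_error(mwoa_angle(a$frames[[k]]), mwoa_angle(b$frames[[k]]))
    expect_lt(abs(d), 1)
  }
})

test_that("clean renders are recovered within a degree across seeded models", {
  set.seed(99)
  for (i in 1:50) {
    ang <- runif(1, -89.5, 90)
    img <- render_sky(sky_model(band_angle_deg = ang, seed = i), 400, 400)
    expect_lt(abs(angle_error(mwoa_angle(img), ang)), 1)
  }
})

test_that("sequences round-trip through PNG frames and a JSON sidecar", {
  dir <- withr::local_tempdir()
  m <- sky_model(n_stars = 5, noise_sigma = 0)
  s <- make_rotation_sequence(m, 40, 10, 3, "rerender", 64, 64)
  sidecar <- write_sequence(s, dir, "seq")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  expect_equal(meta$frames$gt_angle_deg, s$gt_angle_deg)
  back <- read_image(file.path(dir, meta$frames$file[2]))
  expect_equal(back$pixels, s$frames[[2]]$pixels)
})
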