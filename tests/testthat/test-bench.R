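test_that("axial error wraps into [-90, 90)", {
  expect_equal(angle_error(57, 57), 0)
  expect_equal(angle_error(179, 1), -2)
  expect_equal(angle_error(95, 0), -85)
  expect_equal(angle_error(0, 95), 85)
  e <- angle_error(runif(200, -720, 720), runif(200, -720, 720))
  expect_true(all(e >= -90 & e < 90))
})

test_that("error summaries match closed forms", {
  st <- summarize_errors(c(-1, 0, 1))
  expect_equal(st$mean_error, 0)
  expect_equal(st$median_error, 0)
  expect_equal(st$std_error, 1)
  expect_equal(st$mae, 2 / 3)
  z <- summarize_errors(rep(0, 4))
  expect_true(all(c(z$mean_error, z$std_error, z$mae, z$std_abs) == 0))
  expect_error(summarize_errors(c(NA_real_, NA_real_)), "no error")
  expect_equal(summarize_errors(c(1, NA, -1))$n_missing, 1)
})

test_that("the absolute mean of centred Gaussian errors is sigma*sqrt(2/pi)", {
  set.seed(11)
  e <- rnorm(1000, 0, 1.34)
  st <- summarize_errors(e)
  expect_lt(abs(st$mae / (1.34 * sqrt(2 / pi)) - 1), 0.1)
  expect_lt(abs(st$mean_error), 0.2)
  expect_gte(st$mae, abs(st$mean_error))
})

test_that("a small clean benchmark is accurate and self-consistent", {
  cfg <- bench_config(n_sets = 2, frames_per_set = 6, step_deg = 5,
                      blur_realisations_per_set = 0, estimator = "mwoa",
                      image_size = 200, master_seed = 4,
                      sky_args = list(n_stars = 40))
  res <- run_benchmark(cfg)
  expect_equal(nrow(res$frames), 12)
  expect_true(all(res$sets$mae < 1))
  # pooled stats equal stats recomputed from the per-frame table
  expect_equal(res$pooled$mwoa$mae, mean(abs(res$frames$err_mwoa)))
  expect_equal(res$pooled$mwoa$mean_error, mean(res$frames$err_mwoa))
  # histogram counts account for every scored frame
  expect_equal(sum(res$hist$count), sum(!is.na(res$frames$err_mwoa)))
})

test_that("benchmark outputs are byte-for-byte reproducible from the seed", {
  cfg <- bench_config(n_sets = 1, frames_per_set = 4, step_deg = 5,
                      blur_realisations_per_set = 1, blur_size = 60,
                      estimator = "mwoa", image_size = 128, master_seed = 21,
                      sky_args = list(n_stars = 30, band_width_px = 10))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_benchmark(cfg, out_dir = d1)
  run_benchmark(cfg, out_dir = d2)
  for (f in c("frames.csv", "sets.csv", "hist.csv", "pooled.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  prov <- jsonlite::read_json(file.path(d1, "provenance.json"))
  expect_equal(prov$master_seed, 21)
  expect_true(nzchar(prov$version))
})

test_that("estimator failures are excluded and counted", {
  # blank frames make every estimator fail: the run completes with all
  # frames flagged missing, and summarising them errors cleanly
  cfg <- bench_config(n_sets = 1, frames_per_set = 2,
                      blur_realisations_per_set = 0, estimator = "mwoa",
                      image_size = 100, master_seed = 5,
                      sky_args = list(band_peak = 0, n_stars = 0,
                                      noise_sigma = 0))
  expect_error(run_benchmark(cfg), "no error")
})
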