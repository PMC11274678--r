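#' Signed axial angle error
#'
#' The difference between an estimate and the ground truth of an axial
#' (modulo-180) orientation, wrapped to `[-90, 90)`:
#' `((est - gt + 90) mod 180) - 90`. Without the wrap a 179-degree estimate
#' of a 1-degree line would score 178 degrees instead of -2.
#'
#' @param est_deg,gt_deg estimate and ground truth, degrees.
#' @return signed error in `[-90, 90)`.
#' @examples
#' angle_error(179, 1)  # -2
#' @export
angle_error <- function(est_deg, gt_deg) {
  ((est_deg - gt_deg + 90) %% 180) - 90
}

#' Summary statistics of a set of angular errors
#'
#' Computes both rows of the benchmark table structure: mean / median /
#' sample standard deviation of the signed errors and of their absolute
#' values (the mean absolute value is the MAE).
#'
#' @param signed_errors numeric vector of signed axial errors, degrees;
#'   `NA` entries (failed frames) are dropped.
#' @return an object of class `error_stats` with fields `signed_errors`,
#'   `mean_error`, `median_error`, `std_error`, `mae`, `median_abs`,
#'   `std_abs`, `n`, `n_missing`.
#' @export
summarize_errors <- function(signed_errors) {
  n_missing <- sum(is.na(signed_errors))
  e <- signed_errors[!is.na(signed_errors)]
  if (length(e) == 0) stop("no error values to summarise")
  a <- abs(e)
  structure(list(signed_errors = e,
                 mean_error = mean(e),
                 median_error = median(e),
                 std_error = if (length(e) > 1) sd(e) else 0,
                 mae = mean(a),
                 median_abs = median(a),
                 std_abs = if (length(a) > 1) sd(a) else 0,
                 n = length(e), n_missing = n_missing),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, digits = 4, ...) {
  cat(sprintf("angle errors (n = %d%s):\n", x$n,
              if (x$n_missing) sprintf(", %d missing", x$n_missing) else ""))
  cat(sprintf("  signed:   mean %s  median %s  sd %s\n",
              format(x$mean_error, digits = digits),
              format(x$median_error, digits = digits),
              format(x$std_error, digits = digits)))
  cat(sprintf("  absolute: mean %s  median %s  sd %s\n",
              format(x$mae, digits = digits),
              format(x$median_abs, digits = digits),
              format(x$std_abs, digits = digits)))
  invisible(x)
}

#' Configuration of the rotation-under-blur benchmark
#'
#' Defaults mirror the synthetic evaluation protocol: 12 test sets of 72
#' frames each (864 images) advancing 5 degrees per frame, with two
#' independently seeded motion-blur realisations (intensity 0.5, 100-px
#' kernels) applied per sequence.
#'
#' @param n_sets number of test sets.
#' @param frames_per_set frames per rotation sequence.
#' @param step_deg rotation step per frame, degrees.
#' @param blur_realisations_per_set independent blur kernels per set; 0
#'   disables blurring.
#' @param blur_intensity,blur_size blur kernel parameters ([blur_spec()]).
#' @param estimator character vector, subset of `c("mwoa", "radon")`.
#' @param master_seed single integer seed from which every per-set seed,
#'   blur seed and starting angle is derived.
#' @param image_size square frame side length, pixels.
#' @param mode sequence mode, see [make_rotation_sequence()].
#' @param radon_step_deg angle grid of the Radon baseline.
#' @param params [mwoa_params()] shared by both estimators.
#' @param sky_args named list of overrides passed to [sky_model()].
#' @return an object of class `bench_config`.
#' @export
bench_config <- function(n_sets = 12L, frames_per_set = 72L, step_deg = 5,
                         blur_realisations_per_set = 2L,
                         blur_intensity = 0.5, blur_size = 100L,
                         estimator = c("mwoa", "radon"),
                         master_seed = 1L, image_size = 400L,
                         mode = "digital_rotate", radon_step_deg = 1,
                         params = mwoa_params(), sky_args = list()) {
  estimator <- match.arg(estimator, several.ok = TRUE)
  stopifnot(n_sets >= 1, frames_per_set >= 1, step_deg > 0,
            blur_realisations_per_set >= 0)
  structure(list(n_sets = as.integer(n_sets),
                 frames_per_set = as.integer(frames_per_set),
                 step_deg = step_deg,
                 blur_realisations_per_set =
                   as.integer(blur_realisations_per_set),
                 blur_intensity = blur_intensity,
                 blur_size = as.integer(blur_size),
                 estimator = estimator,
                 master_seed = as.integer(master_seed),
                 image_size = as.integer(image_size),
                 mode = mode, radon_step_deg = radon_step_deg,
                 params = params, sky_args = sky_args),
            class = "bench_config")
}

#' Run the rotation-under-blur benchmark
#'
#' For each test set, renders a seeded rotation sequence (random starting
#' angle), applies each blur realisation's kernel to every frame, runs the
#' configured estimators per frame, and scores signed axial errors against
#' the ground truth. Per-set statistics pool the realisations of that set;
#' pooled statistics and a 1-degree-bin error histogram cover all scored
#' frames. Frames on which an estimator fails are recorded as missing and
#' excluded from the statistics with a reported count. The whole run is
#' reproducible from `master_seed`.
#'
#' @param config a [bench_config()].
#' @param out_dir optional directory; when given, writes `frames.csv`,
#'   `sets.csv`, `pooled.json`, `hist.csv` and a provenance record
#'   `provenance.json` (configuration, seeds, package version).
#' @param verbose print per-set progress.
#' @return an object of class `mw_benchmark`: `frames` (one row per set x
#'   realisation x frame), `sets` (per-set stats per estimator), `pooled`
#'   (named list of `error_stats`), `hist` (1-degree bins), `config`.
#' @export
run_benchmark <- function(config = bench_config(), out_dir = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(config, "bench_config"))
  nreal <- max(1L, config$blur_realisations_per_set)
  blur_on <- config$blur_realisations_per_set > 0
  seeds <- derive_seeds(config$master_seed,
                        config$n_sets * (1L + nreal) + config$n_sets)
  set_seeds <- seeds[seq_len(config$n_sets)]
  blur_seeds <- matrix(seeds[config$n_sets + seq_len(config$n_sets * nreal)],
                       nrow = config$n_sets)
  start_angles <- with_seed(seeds[config$n_sets * (1L + nreal) + 1L],
                            runif(config$n_sets, 0, 180))
  rows <- list()
  for (s in seq_len(config$n_sets)) {
    sky <- do.call(sky_model, modifyList(
      list(band_angle_deg = wrap_axial(start_angles[s]),
           seed = set_seeds[s]),
      config$sky_args))
    seqn <- make_rotation_sequence(sky, start_angles[s], config$step_deg,
                                   config$frames_per_set, config$mode,
                                   config$image_size, config$image_size)
    for (j in seq_len(nreal)) {
      kern <- if (blur_on)
        make_blur_kernel(blur_spec(config$blur_intensity, config$blur_size,
                                   seed = blur_seeds[s, j]))
      else NULL
      for (k in seq_len(config$frames_per_set)) {
        frame <- if (blur_on) apply_blur(seqn$frames[[k]], kern)
                 else seqn$frames[[k]]
        g <- preprocess(frame, config$params)
        row <- list(set = s, realisation = j, frame = k - 1L,
                    gt = seqn$gt_angle_deg[k])
        for (est in config$estimator) {
          val <- tryCatch(
            if (est == "mwoa")
              mwoa_angle(g, config$params, preprocessed = TRUE)
            else radon_angle(g, config$radon_step_deg, config$params,
                             preprocessed = TRUE),
            error = function(e) NA_real_)
          row[[paste0("est_", est)]] <- val
          row[[paste0("err_", est)]] <-
            if (is.na(val)) NA_real_ else angle_error(val, row$gt)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
    if (verbose) message(sprintf("set %d/%d done", s, config$n_sets))
  }
  frames <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  sets <- do.call(rbind, lapply(seq_len(config$n_sets), function(s) {
    do.call(rbind, lapply(config$estimator, function(est) {
      st <- summarize_errors(frames[frames$set == s,
                                    paste0("err_", est)])
      data.frame(set = s, estimator = est, mean_error = st$mean_error,
                 median_error = st$median_error, std_error = st$std_error,
                 mae = st$mae, median_abs = st$median_abs,
                 std_abs = st$std_abs, n = st$n, n_missing = st$n_missing)
    }))
  }))
  pooled <- lapply(stats::setNames(config$estimator, config$estimator),
                   function(est) summarize_errors(frames[[paste0("err_", est)]]))
  breaks <- seq(-90.5, 90.5, by = 1)
  hist <- do.call(rbind, lapply(config$estimator, function(est) {
    e <- frames[[paste0("err_", est)]]
    h <- graphics::hist(e[!is.na(e)], breaks = breaks, plot = FALSE)
    data.frame(estimator = est, bin_centre = h$mids, count = h$counts)
  }))
  res <- structure(list(frames = frames, sets = sets, pooled = pooled,
                        hist = hist, config = config),
                   class = "mw_benchmark")
  if (!is.null(out_dir)) write_benchmark(res, out_dir)
  res
}

write_benchmark <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$frames, file.path(out_dir, "frames.csv"), row.names = FALSE)
  write.csv(res$sets, file.path(out_dir, "sets.csv"), row.names = FALSE)
  write.csv(res$hist, file.path(out_dir, "hist.csv"), row.names = FALSE)
  pooled <- lapply(res$pooled, function(st)
    st[c("mean_error", "median_error", "std_error", "mae", "median_abs",
         "std_abs", "n", "n_missing")])
  jsonlite::write_json(pooled, file.path(out_dir, "pooled.json"),
                       auto_unbox = TRUE, digits = NA)
  prov <- list(package = "mwcompass",
               version = as.character(utils::packageVersion("mwcompass")),
               timestamp = format(Sys.time(), tz = "UTC"),
               master_seed = res$config$master_seed,
               config = res$config[setdiff(names(res$config), "params")],
               params = unclass(res$config$params))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.mw_benchmark <- function(x, ...) {
  cat(sprintf("Rotation benchmark: %d sets x %d frames x %d blur realisation(s)\n",
              x$config$n_sets, x$config$frames_per_set,
              max(1L, x$config$blur_realisations_per_set)))
  for (est in x$config$estimator) {
    mae <- x$sets$mae[x$sets$estimator == est]
    cat(sprintf("  %-5s per-set MAE: min %.3f  max %.3f deg; pooled MAE %.3f deg\n",
                est, min(mae), max(mae), x$pooled[[est]]$mae))
  }
  invisible(x)
}

#' @export
plot.mw_benchmark <- function(x, estimator = x$config$estimator[1], ...) {
  h <- x$hist[x$hist$estimator == estimator, ]
  graphics::plot(h$bin_centre, h$count, type = "h", lwd = 3,
                 xlab = "signed axial error (deg)", ylab = "frames",
                 main = sprintf("error histogram (%s)", estimator), ...)
  invisible(x)
}
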