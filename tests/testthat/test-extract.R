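test_that("background subtraction removes a constant offset", {
  cfg <- small_scan()
  px <- matrix(7.5, cfg$m, cfg$n)
  img <- linescan_image(px, cfg, stimulus_onset = 50)
  out <- subtract_background(img, roi(c(1, 10), c(1, 10)))
  expect_equal(max(abs(out$pixels)), 0)
  expect_equal(attr(out, "background"), 7.5)
  # cell region + background: cell value recovered
  px2 <- px
  px2[, 21:64] <- px2[, 21:64] + 100
  img2 <- linescan_image(px2, cfg, 50)
  out2 <- subtract_background(img2, roi(c(1, 128), c(1, 20)))
  expect_equal(unique(as.vector(out2$pixels[, 21:64])), 100)
})

test_that("baseline estimation returns ROI mean and per-pixel SD", {
  cfg <- small_scan()
  img <- linescan_image(matrix(42, cfg$m, cfg$n), cfg, 50)
  b <- estimate_baseline(img, roi(c(1, 40), c(1, 64)))
  expect_equal(b$F0, 42)
  expect_equal(b$sd_raw, 0)
  set.seed(3)
  s <- 4
  imgn <- linescan_image(matrix(42 + rnorm(cfg$m * cfg$n, 0, s),
                                cfg$m, cfg$n), cfg, 50)
  bn <- estimate_baseline(imgn, roi(c(1, 40), c(1, 64)))
  n_px <- 40 * 64
  expect_lt(abs(bn$sd_raw - s), 3 * s / sqrt(2 * (n_px - 1)))
  expect_warning(estimate_baseline(img, roi(c(1, 60), c(1, 64))), "stimulus")
})

test_that("7-pixel averaging reduces white-noise SD by sqrt(7)", {
  set.seed(11)
  cfg <- scan_config("unidirectional", f = 1000, n = 15, m = 10000,
                     tp_us = 0.515)
  s <- 10
  img <- linescan_image(matrix(100 + rnorm(cfg$m * cfg$n, 0, s),
                               cfg$m, cfg$n), cfg, 1e7)
  tr <- extract_trace(img, 8, F0 = 100, half_width = 3)
  expect_equal(tr$n_avg, 7L)
  expect_lt(abs(tr$baseline_sd / (s / 100 / sqrt(7)) - 1), 0.05)
})

test_that("noise-free render/extract round trip reproduces the model at
           the centre pixel's corrected times", {
  cfg <- small_scan(m = 256L)
  p <- spike_params(t0 = 4, FM = 1.5, alpha = 0.1, tauA = 2, tauT = 5)
  img <- render_xt_image(list(list(params = p, column = 32)), cfg,
                         stimulus_onset = 50, F0 = 100, background = 0,
                         spatial_sd = Inf, noise_sd = 0)
  tm <- build_pixel_time_map(cfg)
  # exact identity for the centre pixel alone; the 7-pixel average differs
  # only at second order in the within-line time offsets
  tr0 <- extract_trace(img, 32, F0 = 100, timemap = tm,
                       correct_times = TRUE, half_width = 0L)
  expect_equal(tr0$values, evaluate_spike(p, tm$times[, 32] - 50),
               tolerance = 1e-12)
  tr <- extract_trace(img, 32, F0 = 100, timemap = tm, correct_times = TRUE)
  expect_equal(tr$values, evaluate_spike(p, tm$times[, 32] - 50),
               tolerance = 1e-5)
  # uncorrected convention assigns the line times (i-1)/f
  tru <- extract_trace(img, 32, F0 = 100, timemap = tm,
                       correct_times = FALSE)
  expect_equal(tru$times + 50, (seq_len(cfg$m) - 1) / cfg$f * 1000)
})

test_that("extraction bounds and inputs are validated", {
  cfg <- small_scan()
  img <- linescan_image(matrix(1, cfg$m, cfg$n), cfg, 50)
  expect_error(extract_trace(img, 2, F0 = 1), "window")
  expect_error(extract_trace(img, 64, F0 = 1), "window")
  expect_error(extract_trace(img, 32, F0 = -1), "F0")
  expect_error(roi(c(5, 2), c(1, 3)), "roi")
  expect_error(subtract_background(img, roi(c(1, 200), c(1, 10))),
               "outside")
})

test_that("TIFF round trip preserves the image to 16-bit precision", {
  cfg <- small_scan(m = 32L, n = 16L)
  set.seed(5)
  px <- matrix(round(runif(32 * 16, 0, 4095)), 32, 16)
  img <- linescan_image(px, cfg, 10)
  path <- withr::local_tempfile(fileext = ".tif")
  write_linescan_tiff(img, path)
  back <- read_linescan_tiff(path, cfg, 10)
  expect_equal(back$pixels, px, tolerance = 1e-6)
})
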