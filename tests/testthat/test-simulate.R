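test_that("parameter draws are reproducible and centred on the preset", {
  pre <- indicator_preset("OG5N")
  a <- draw_spike_params(pre, 5, seed = 123)
  b <- draw_spike_params(pre, 5, seed = 123)
  expect_identical(a, b)
  # zero SDs degenerate to the means
  pre0 <- pre
  pre0$param_sds[] <- 0
  d <- draw_spike_params(pre0, 3, seed = 1)
  for (x in d) expect_equal(unlist(x), unlist(pre$param_means))
  # CLT bounds on the sample means
  big <- draw_spike_params(pre, 10000, seed = 7)
  M <- do.call(rbind, lapply(big, unlist))
  mu <- unlist(pre$param_means)
  sds <- pre$param_sds[colnames(M)]
  for (nm in colnames(M)) {
    se <- sds[nm] / sqrt(nrow(M))
    # rejection sampling keeps every parameter inside its domain but can
    # shift means slightly; allow the truncation bias plus 3 SE
    expect_lt(abs(mean(M[, nm]) - mu[nm]), 3 * se + 0.05 * sds[nm])
    expect_true(all(M[, "alpha"] >= 0 & M[, "alpha"] <= 1))
    expect_true(all(M[, c("FM", "tauA", "tauT")] > 0))
  }
})

test_that("noise SD follows sigma = A / SNR", {
  expect_equal(noise_sd_for_snr(0.8, 4), 0.2)
  expect_equal(noise_sd_for_snr(0.8, 1e9), 0.8e-9)
  expect_error(noise_sd_for_snr(0.8, 0), "snr")
  expect_error(noise_sd_for_snr(0.8, -2), "snr")
  # OG-5N: sigma 0.15 at printed mean SNR 5.39 implies amplitude ~0.81
  pre <- indicator_preset("OG5N")
  expect_equal(pre$mean_amplitude, 5.39 * 0.15, tolerance = 1e-12)
  expect_equal(noise_sd_for_snr(pre$mean_amplitude, pre$mean_snr), 0.15,
               tolerance = 1e-12)
})

test_that("datasets are pure functions of their recipe and seed", {
  pre <- indicator_preset("Fluo3")
  s <- dataset_spec(3, pre, n_traces = 4, snr = 5, seed = 42)
  d1 <- make_dataset(s)
  d2 <- make_dataset(dataset_spec(3, pre, n_traces = 4, snr = 5, seed = 42))
  expect_identical(d1, d2)
  d3 <- make_dataset(dataset_spec(3, pre, n_traces = 4, snr = 5, seed = 43))
  expect_false(identical(d1[[1]]$trace$values, d3[[1]]$trace$values))
})

test_that("the three dataset types have the prescribed structure", {
  pre <- indicator_preset("OG5N")
  d1 <- make_dataset(dataset_spec(1, pre, n_traces = 3, seed = 1))
  expect_true(all(vapply(d1, function(el) inherits(el$truth, "spike_params"),
                         logical(1))))
  d2 <- make_dataset(dataset_spec(2, pre, n_traces = 3, seed = 1))
  expect_true(all(vapply(d2, function(el) is.null(el$truth), logical(1))))
  d3 <- make_dataset(dataset_spec(3, pre, n_traces = 3, snr = 2, seed = 1))
  expect_identical(d3[[1]]$truth, pre$param_means)
  expect_identical(d3[[2]]$truth, pre$param_means)
  expect_equal(attr(d3, "noise_sd"), pre$mean_amplitude / 2)
  expect_error(dataset_spec(3, pre), "snr")
  expect_error(dataset_spec(4, pre), "dataset_type")
})

test_that("noise amplitude matches the nominal sigma", {
  pre <- indicator_preset("OG5N")
  d2 <- make_dataset(dataset_spec(2, pre, n_traces = 40, seed = 5))
  allv <- unlist(lapply(d2, function(el) el$trace$values)) # 40 x 512 samples
  expect_lt(abs(sd(allv) / 0.15 - 1), 0.02)
  sds <- vapply(d2, function(el) sd(el$trace$values), numeric(1))
  expect_lt(abs(mean(sds) - 0.15), 0.005)
  # type 3: per-trace empirical SNR near the requested value
  d3 <- make_dataset(dataset_spec(3, pre, n_traces = 20, snr = 5, seed = 6))
  snr_emp <- vapply(d3, function(el)
    pre$mean_amplitude / el$trace$baseline_sd, numeric(1))
  expect_lt(abs(mean(snr_emp) - 5), 0.5)
})

test_that("type-1 spikes with zero noise are recovered exactly by fitting", {
  pre <- indicator_preset("OG5N")
  pre0 <- pre
  pre0$noise_rms_type1 <- 0
  # sigma 0 -> rnorm contributes nothing; fit must return the seeded params
  # unconstrained fit: drawn time constants may fall below the plausibility
  # bounds, which would otherwise pin them at the constraint
  d <- make_dataset(dataset_spec(1, pre0, n_traces = 3, seed = 8))
  for (el in d) {
    f <- fit_spike(el$trace, fit_settings(constrained = FALSE,
                                          init = el$truth))
    expect_equal(unlist(f$params)[names(unlist(el$truth))],
                 unlist(el$truth), tolerance = 1e-6)
  }
})

test_that("rendered images follow the pixel-time forward model", {
  cfg <- small_scan(m = 64L, n = 32L)
  # no spikes, no noise: constant background + F0
  img0 <- render_xt_image(list(), cfg, F0 = 90, background = 10)
  expect_equal(unique(as.vector(img0$pixels)), 100)
  # flat spatial profile: every column carries the course at its own t_ij
  p <- spike_params(t0 = 2, FM = 1, alpha = 0.1, tauA = 2, tauT = 4)
  img <- render_xt_image(list(list(params = p, column = 16)), cfg,
                         stimulus_onset = 20, F0 = 100, background = 0,
                         spatial_sd = Inf)
  tm <- build_pixel_time_map(cfg)
  for (j in c(1, 7, 30))
    expect_equal(img$pixels[, j],
                 100 * (1 + evaluate_spike(p, tm$times[, j] - 20)),
                 tolerance = 1e-12)
  expect_error(render_xt_image(list(list(params = p, column = 99)), cfg),
               "column")
})

test_that("dataset CSV bundles are deterministic", {
  pre <- indicator_preset("OG5N")
  d <- make_dataset(dataset_spec(2, pre, n_traces = 3, seed = 2))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_dataset_csv(d, dir1)
  write_dataset_csv(make_dataset(dataset_spec(2, pre, n_traces = 3,
                                              seed = 2)), dir2)
  expect_identical(readLines(file.path(dir1, "traces.csv")),
                   readLines(file.path(dir2, "traces.csv")))
})
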