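# Synthetic calcium-spike generator: indicator presets, the three dataset
# types (random-parameter spikes + fixed noise; pure noise; fixed-parameter
# spikes + SNR-defined noise) and a renderer of synthetic x-t images.
#
# The indicator presets are synthetic reconstructions: they are derived
# from the published aggregate statistics of experimentally calibrated
# OG-5N and Fluo-3 spike populations (trace noise of 0.15 dF/F0 RMS and a
# signal-to-noise distribution of 5.39 +/- 2.11 for OG-5N; SNR of
# 14.19 +/- 5.60 for Fluo-3) together with kinetic time constants on the
# scale reported for calcium spikes, reconciled against the published
# accuracy and acceptance-fraction aggregates of the two indicators. They
# are not a transcription of the original per-parameter calibration
# tables.

# Frozen preset table. FM is stored as the target mean peak amplitude and
# converted to the model's FM at construction (FM = A / peak factor of the
# unit-FM curve). SDs are chosen so that the drawn-amplitude CV matches the
# published SNR dispersion (2.11/5.39 for OG-5N, 5.60/14.19 for Fluo-3).
.presets <- list(
  OG5N = list(
    amplitude_mean = 5.39 * 0.15,   # mean SNR x type-1 noise RMS
    amplitude_cv   = 2.11 / 5.39,
    t0 = 4.0,  t0_sd = 0.8,
    alpha = 0.15, alpha_sd = 0.05,
    tauA = 2.5, tauA_sd = 0.8,
    tauT = 5.0, tauT_sd = 1.5,
    noise_rms_type1 = 0.15,
    mean_snr = 5.39,
    snr_grid_type3 = c(1, 1.5, 2, 3, 5, 7, 10)
  ),
  Fluo3 = list(
    amplitude_mean = 1.0,
    amplitude_cv   = 5.60 / 14.19,
    t0 = 4.0,  t0_sd = 0.8,
    alpha = 0.10, alpha_sd = 0.03,
    tauA = 3.5, tauA_sd = 1.0,
    tauT = 12.0, tauT_sd = 3.0,
    noise_rms_type1 = 1.0 / 14.19,  # amplitude / mean SNR
    mean_snr = 14.19,
    snr_grid_type3 = c(1, 1.5, 2, 3, 5, 7, 10, 15, 20)
  )
)

#' Indicator parameter preset
#'
#' Returns the synthetic spike-population preset for a calcium indicator:
#' the mean spike parameters, their population SDs, the type-1 (fixed)
#' noise RMS and the SNR grid used for the type-3 detectability datasets.
#' OG-5N is the low-affinity, low-SNR regime; Fluo-3 the high-affinity,
#' high-SNR regime.
#'
#' @param name \code{"OG5N"} or \code{"Fluo3"}.
#' @return Object of class \code{"indicator_preset"}: list with
#'   \code{name}, \code{param_means} (a \code{\link{spike_params}}),
#'   \code{param_sds} (named numeric), \code{mean_amplitude} (the peak
#'   amplitude of the mean-parameter spike, dF/F0),
#'   \code{noise_rms_type1} and \code{snr_grid_type3}.
#' @export
indicator_preset <- function(name = c("OG5N", "Fluo3")) {
  name <- match.arg(name)
  p <- .presets[[name]]
  unit <- spike_params(t0 = p$t0, FM = 1, alpha = p$alpha,
                       tauA = p$tauA, tauT = p$tauT)
  peak_factor <- compute_descriptors(unit)$A
  FM_mean <- p$amplitude_mean / peak_factor
  means <- spike_params(t0 = p$t0, FM = FM_mean, alpha = p$alpha,
                        tauA = p$tauA, tauT = p$tauT)
  sds <- c(t0 = p$t0_sd, FM = FM_mean * p$amplitude_cv,
           alpha = p$alpha_sd, tauA = p$tauA_sd, tauT = p$tauT_sd)
  structure(list(name = name, param_means = means, param_sds = sds,
                 mean_amplitude = p$amplitude_mean,
                 noise_rms_type1 = p$noise_rms_type1,
                 mean_snr = p$mean_snr,
                 snr_grid_type3 = p$snr_grid_type3),
            class = "indicator_preset")
}

#' @export
print.indicator_preset <- function(x, ...) {
  cat(sprintf("Indicator preset %s (synthetic reconstruction):\n", x$name))
  cat(sprintf("  mean amplitude %.3f dF/F0, type-1 noise RMS %.4f (mean SNR %.2f)\n",
              x$mean_amplitude, x$noise_rms_type1, x$mean_snr))
  print(x$param_means)
  invisible(x)
}

#' Draw random spike parameters around a preset
#'
#' Each of the five parameters is drawn independently from
#' \code{Normal(mean, sd)}; draws violating the parameter-domain
#' invariants (negative time constants or amplitude, alpha outside
#' \[0, 1\], negative latency) are rejected and redrawn, so no probability
#' mass accumulates at the boundaries.
#'
#' @param preset an \code{\link{indicator_preset}}.
#' @param n number of parameter sets.
#' @param seed optional integer seed for reproducibility.
#' @return List of \code{n} \code{\link{spike_params}} objects.
#' @export
draw_spike_params <- function(preset, n, seed = NULL) {
  stopifnot(inherits(preset, "indicator_preset"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  mu <- par_list_to_vec(preset$param_means)
  sd <- preset$param_sds[.par_names]
  lo <- c(t0 = 0, FM = 0, alpha = 0, tauA = 0, tauT = 0)
  hi <- c(t0 = Inf, FM = Inf, alpha = 1, tauA = Inf, tauT = Inf)
  draw_one <- function(k) {
    repeat {
      x <- stats::rnorm(1, mu[k], sd[k])
      if (x > lo[k] && x < hi[k]) return(x)
    }
  }
  lapply(seq_len(n), function(i) {
    v <- vapply(seq_along(.par_names), draw_one, numeric(1))
    names(v) <- .par_names
    spike_params(t0 = v["t0"], FM = v["FM"], alpha = v["alpha"],
                 tauA = v["tauA"], tauT = v["tauT"])
  })
}

#' Noise SD for a required signal-to-noise ratio
#'
#' \eqn{\sigma = A / SNR}, where A is the mean peak amplitude of the
#' fluorescence increase and SNR the required signal-to-noise ratio.
#'
#' @param mean_amplitude mean peak amplitude, dF/F0.
#' @param snr required SNR (> 0).
#' @return Noise SD in dF/F0 units.
#' @export
noise_sd_for_snr <- function(mean_amplitude, snr) {
  if (!is.finite(snr) || snr <= 0) stop("snr must be > 0", call. = FALSE)
  mean_amplitude / snr
}

#' Synthetic dataset recipe
#'
#' @param dataset_type 1 (random parameters + fixed noise RMS), 2 (pure
#'   noise) or 3 (fixed mean parameters + noise set by the required SNR).
#' @param preset an \code{\link{indicator_preset}}.
#' @param n_traces number of traces (1000 in the full-scale studies).
#' @param snr required SNR; mandatory for type 3, ignored otherwise.
#' @param seed integer seed; the dataset content is a pure function of the
#'   recipe and the seed.
#' @param sampling the \code{\link{scan_config}} whose corrected pixel
#'   times define the sampling grid.
#' @param stimulus_onset stimulus time, ms from the first scanned line.
#' @param column within-line position whose corrected pixel times are used.
#' @return Object of class \code{"dataset_spec"}.
#' @export
dataset_spec <- function(dataset_type, preset, n_traces = 1000L, snr = NULL,
                         seed = 1L, sampling = scan_config_preset(1000),
                         stimulus_onset = 50, column = 256L) {
  stopifnot(inherits(preset, "indicator_preset"),
            inherits(sampling, "scan_config"))
  dataset_type <- as.integer(dataset_type)
  if (!dataset_type %in% 1:3)
    stop("dataset_type must be 1, 2 or 3", call. = FALSE)
  if (dataset_type == 3L && is.null(snr))
    stop("type-3 datasets require snr", call. = FALSE)
  if (column < 1L || column > sampling$n)
    stop("column outside the scan line", call. = FALSE)
  structure(list(dataset_type = dataset_type, preset = preset,
                 n_traces = as.integer(n_traces), snr = snr,
                 seed = as.integer(seed), sampling = sampling,
                 stimulus_onset = stimulus_onset,
                 column = as.integer(column)),
            class = "dataset_spec")
}

#' Generate a synthetic dataset
#'
#' Builds the traces prescribed by a \code{\link{dataset_spec}}. Traces are
#' sampled at the corrected acquisition times of the configured scan
#' (centre-pixel times at \code{spec$column}), expressed relative to the
#' stimulus onset. Noise is white Gaussian (R's Mersenne-twister stream),
#' with SD equal to the preset type-1 RMS (types 1 and 2) or to
#' \code{\link{noise_sd_for_snr}} of the required SNR (type 3). Each
#' trace's \code{baseline_sd} is the empirical SD of its pre-stimulus
#' samples.
#'
#' @param spec a \code{\link{dataset_spec}}.
#' @return List of length \code{n_traces}; each element is a list with
#'   \code{trace} (a \code{\link{fluo_trace}}) and \code{truth} (the
#'   seeded \code{\link{spike_params}}, or \code{NULL} for pure noise).
#'   The recipe is attached as attribute \code{"spec"} and the noise SD as
#'   \code{"noise_sd"}.
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  set.seed(spec$seed)
  tm <- build_pixel_time_map(spec$sampling)
  times <- tm$times[, spec$column] - spec$stimulus_onset
  ns <- length(times)

  sigma <- switch(spec$dataset_type,
                  spec$preset$noise_rms_type1,
                  spec$preset$noise_rms_type1,
                  noise_sd_for_snr(spec$preset$mean_amplitude, spec$snr))

  truths <- switch(spec$dataset_type,
                   draw_spike_params(spec$preset, spec$n_traces),
                   vector("list", spec$n_traces),
                   rep(list(spec$preset$param_means), spec$n_traces))

  out <- vector("list", spec$n_traces)
  pre <- times < 0
  for (i in seq_len(spec$n_traces)) {
    clean <- if (is.null(truths[[i]])) numeric(ns)
             else evaluate_spike(truths[[i]], times)
    values <- clean + stats::rnorm(ns, 0, sigma)
    bsd <- if (sum(pre) >= 2L) stats::sd(values[pre]) else NA_real_
    out[[i]] <- list(trace = fluo_trace(times, values, baseline_sd = bsd,
                                        center_column = spec$column),
                     truth = truths[[i]])
  }
  attr(out, "spec") <- spec
  attr(out, "noise_sd") <- sigma
  out
}

#' Render a synthetic x-t image
#'
#' Renders one or more spikes into a line-scan image with a Gaussian
#' spatial profile, evaluating every pixel at its own corrected
#' acquisition time, so sequential-sampling effects are physically
#' emulated:
#' \deqn{pixel(i,j) = background + F_0 (1 + \sum_k \Delta F_k(t_{ij})
#'   e^{-(j - col_k)^2 / 2 sd^2}) + noise}
#'
#' @param spikes list of \code{list(params = spike_params, column = j)}.
#' @param config the \code{\link{scan_config}} to render for.
#' @param stimulus_onset stimulus time, ms from the first line; spike
#'   latencies are relative to it.
#' @param F0 baseline fluorescence, detector units.
#' @param background non-cell background level, detector units.
#' @param spatial_sd Gaussian spatial SD of the spike profile, pixels
#'   (\code{Inf} for a spatially flat signal).
#' @param noise_sd per-pixel Gaussian noise SD, detector units.
#' @param seed optional seed for the noise.
#' @return A \code{\link{linescan_image}}.
#' @export
render_xt_image <- function(spikes, config, stimulus_onset = 50,
                            F0 = 100, background = 0, spatial_sd = 4,
                            noise_sd = 0, seed = NULL) {
  stopifnot(inherits(config, "scan_config"))
  if (!is.null(seed)) set.seed(seed)
  tm <- build_pixel_time_map(config)
  px <- matrix(background + F0, config$m, config$n)
  j <- seq_len(config$n)
  for (sp in spikes) {
    if (sp$column < 1 || sp$column > config$n)
      stop("spike column outside the image", call. = FALSE)
    wj <- exp(-(j - sp$column)^2 / (2 * spatial_sd^2))
    dF <- matrix(evaluate_spike(sp$params,
                                as.vector(tm$times) - stimulus_onset),
                 config$m, config$n)
    px <- px + F0 * dF * rep(wj, each = config$m)
  }
  if (noise_sd > 0)
    px <- px + stats::rnorm(length(px), 0, noise_sd)
  linescan_image(px, config, stimulus_onset)
}

#' Write a dataset as a CSV bundle
#'
#' Writes \code{traces.csv} (long format: \code{trace_id}, \code{time_ms},
#' \code{dF_F0}) and \code{truth.csv} (one row of seeded parameters per
#' trace, empty for pure-noise datasets) into a directory.
#'
#' @param dataset result of \code{\link{make_dataset}}.
#' @param dir output directory, created if needed.
#' @return \code{dir}, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- attr(dataset, "spec")
  n <- length(dataset)
  traces <- do.call(rbind, lapply(seq_len(n), function(i) {
    tr <- dataset[[i]]$trace
    data.frame(trace_id = i, time_ms = tr$times, dF_F0 = tr$values)
  }))
  meta <- c(sprintf("# caspikes %s",
                    as.character(utils::packageVersion("caspikes"))),
            sprintf("# dataset_type=%d indicator=%s seed=%d n=%d%s",
                    spec$dataset_type, spec$preset$name, spec$seed, n,
                    if (is.null(spec$snr)) "" else sprintf(" snr=%g", spec$snr)))
  tpath <- file.path(dir, "traces.csv")
  con <- file(tpath, "w"); writeLines(meta, con)
  utils::write.csv(traces, con, row.names = FALSE); close(con)
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    tp <- dataset[[i]]$truth
    if (is.null(tp)) return(NULL)
    data.frame(trace_id = i, t0 = tp$t0, FM = tp$FM, alpha = tp$alpha,
               tauA = tp$tauA, tauT = tp$tauT)
  }))
  upath <- file.path(dir, "truth.csv")
  con <- file(upath, "w"); writeLines(meta, con)
  utils::write.csv(if (is.null(truth)) data.frame() else truth,
                   con, row.names = FALSE); close(con)
  invisible(dir)
}
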