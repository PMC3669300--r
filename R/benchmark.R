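# Benchmarking harness: algorithm-comparison grid, SNR-dependent
# detectability with a logistic fit, and the sequential-sampling
# timing-error experiment.

#' The 14-configuration algorithm grid
#'
#' All supported combinations of minimization algorithm, robust method and
#' constraining: simplex (constrained/unconstrained, no robust variants),
#' trust region (3 robust modes x constrained/unconstrained) and
#' Levenberg-Marquardt / Gauss-Newton (3 robust modes, unconstrained
#' only).
#'
#' @return data.frame with columns \code{algorithm}, \code{robust},
#'   \code{constrained}.
#' @export
algorithm_grid <- function() {
  g <- rbind(
    expand.grid(algorithm = "simplex", robust = "none",
                constrained = c(TRUE, FALSE), stringsAsFactors = FALSE),
    expand.grid(algorithm = "trust_region",
                robust = c("none", "LAR", "bisquare"),
                constrained = c(TRUE, FALSE), stringsAsFactors = FALSE),
    expand.grid(algorithm = c("levenberg_marquardt", "gauss_newton"),
                robust = c("none", "LAR", "bisquare"),
                constrained = FALSE, stringsAsFactors = FALSE))
  rownames(g) <- NULL
  g
}

# Fit every trace of a dataset under one settings object; returns a
# data.frame of per-trace results.
.fit_dataset <- function(dataset, settings, descriptor_window = NULL) {
  rows <- lapply(dataset, function(el) {
    f <- fit_spike(el$trace, settings, descriptor_window = descriptor_window)
    data.frame(t0 = f$params$t0, FM = f$params$FM, alpha = f$params$alpha,
               tauA = f$params$tauA, tauT = f$params$tauT,
               A = f$descriptors$A, TTP = f$descriptors$TTP,
               FDHM = f$descriptors$FDHM,
               p_value = f$p_value, accepted = f$accepted,
               converged = f$converged,
               sel_A = apply_selection(f, "A"),
               baseline_sd = el$trace$baseline_sd)
  })
  do.call(rbind, rows)
}

.truth_table <- function(dataset) {
  do.call(rbind, lapply(dataset, function(el) {
    tp <- el$truth
    if (is.null(tp)) return(NULL)
    d <- compute_descriptors(tp)
    data.frame(t0 = tp$t0, FM = tp$FM, alpha = tp$alpha,
               tauA = tp$tauA, tauT = tp$tauT,
               A = d$A, TTP = d$TTP, FDHM = d$FDHM)
  }))
}

.safe_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' Compare fitting configurations on a dataset
#'
#' Fits every trace under every grid configuration and summarizes, per
#' configuration: the fraction of F-test-accepted fits, the fractions
#' passing the Selection A (parameter plausibility) and Selection B
#' (amplitude over noise) filters, Pearson correlations between seeded and
#' fitted descriptors (A, t0, TTP, FDHM) over the F-test-accepted fits
#' (with the all-fits variant recorded for diagnostics), the fraction of
#' accepted fits with any parameter outside the seeded mean +/- 3 SD, and
#' -- for pure-noise datasets -- the count of false-positive F-test
#' acceptances. Grid rows requesting constraints with an algorithm that
#' cannot handle them are skipped with a warning.
#'
#' @param dataset result of \code{\link{make_dataset}} (type 1 for
#'   correlations, type 2 for false positives).
#' @param grid configuration grid, default \code{\link{algorithm_grid}}.
#' @param init initialization vector for all fits; default the preset
#'   means of the dataset's recipe.
#' @param snr_threshold Selection B threshold (amplitude / trace noise SD).
#' @return data.frame of class \code{"benchmark_report"}, one row per
#'   configuration.
#' @export
compare_algorithms <- function(dataset, grid = algorithm_grid(),
                               init = NULL, snr_threshold = 2) {
  spec <- attr(dataset, "spec")
  if (is.null(init) && !is.null(spec)) init <- spec$preset$param_means
  truth <- .truth_table(dataset)
  has_truth <- !is.null(truth)
  if (has_truth) {
    tmu <- colMeans(truth[, .par_names])
    tsd <- vapply(truth[, .par_names], stats::sd, numeric(1))
  }

  out <- list()
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    if (g$constrained &&
        g$algorithm %in% c("levenberg_marquardt", "gauss_newton")) {
      warning(sprintf("skipping constrained %s (unsupported)", g$algorithm))
      next
    }
    st <- fit_settings(algorithm = g$algorithm, robust = g$robust,
                       constrained = g$constrained, init = init)
    res <- .fit_dataset(dataset, st)
    acc <- res$accepted
    sel_B <- is.finite(res$A) & is.finite(res$baseline_sd) &
      res$A / res$baseline_sd > snr_threshold

    row <- data.frame(algorithm = g$algorithm, robust = g$robust,
                      constrained = g$constrained,
                      n = nrow(res),
                      fraction_accepted_Ftest = mean(acc),
                      fraction_selection_A = mean(res$sel_A),
                      fraction_selection_B = mean(sel_B))
    if (has_truth) {
      for (d in c("A", "t0", "TTP", "FDHM")) {
        row[[paste0("R_", d)]] <- .safe_cor(truth[[d]][acc], res[[d]][acc])
        row[[paste0("R_", d, "_all")]] <- .safe_cor(truth[[d]], res[[d]])
      }
      fitted_pars <- as.matrix(res[, .par_names])
      outl <- sweep(fitted_pars, 2, tmu) # deviations
      outl <- abs(outl) > rep(3 * tsd, each = nrow(fitted_pars))
      row$outlier_fraction <- mean(rowSums(outl[acc, , drop = FALSE]) > 0)
      row$false_positive_count <- NA_integer_
    } else {
      for (d in c("A", "t0", "TTP", "FDHM")) {
        row[[paste0("R_", d)]] <- NA_real_
        row[[paste0("R_", d, "_all")]] <- NA_real_
      }
      row$outlier_fraction <- NA_real_
      row$false_positive_count <- sum(acc)
    }
    out[[length(out) + 1L]] <- row
  }
  if (length(out) == 0L) return(NULL)
  rep <- do.call(rbind, out)
  class(rep) <- c("benchmark_report", class(rep))
  rep
}

#' SNR-dependent spike detectability
#'
#' For each SNR of the preset grid, generates a type-3 dataset (the
#' mean-parameter spike plus \code{n_per_snr} independent noise
#' instances), fits every trace with the default pipeline (constrained
#' trust region, initialization at the seeded parameters) and records the
#' fraction of spikes not accepted by the F-test. The resulting
#' (SNR, fraction undetected) points are fitted with the logistic curve
#' \deqn{y = 1 / (1 + (x / S_{50})^h)}
#' where \eqn{S_{50}} is the SNR at 50\% undetected spikes and \eqn{h} the
#' steepness exponent.
#'
#' @param preset an \code{\link{indicator_preset}}.
#' @param n_per_snr traces per SNR level (1000 at full scale).
#' @param seed integer seed; dataset i uses \code{seed + i}.
#' @param sampling scan configuration for the sampling grid.
#' @return Object of class \code{"detectability_fit"}: list with
#'   \code{S50}, \code{h}, \code{curve_points} (data.frame of snr and
#'   fraction_undetected) and \code{ill_conditioned} (TRUE when the grid
#'   never brackets 50\% undetected).
#' @export
detectability_curve <- function(preset, n_per_snr = 1000L, seed = 1L,
                                sampling = scan_config_preset(1000)) {
  stopifnot(inherits(preset, "indicator_preset"))
  grid <- preset$snr_grid_type3
  frac <- numeric(length(grid))
  for (i in seq_along(grid)) {
    ds <- make_dataset(dataset_spec(3, preset, n_traces = n_per_snr,
                                    snr = grid[i], seed = seed + i,
                                    sampling = sampling))
    st <- fit_settings(init = preset$param_means)
    acc <- vapply(ds, function(el) fit_spike(el$trace, st)$accepted,
                  logical(1))
    frac[i] <- 1 - mean(acc)
  }
  pts <- data.frame(snr = grid, fraction_undetected = frac)
  fit <- fit_logistic_detectability(pts)
  structure(list(S50 = fit$S50, h = fit$h, curve_points = pts,
                 ill_conditioned = fit$ill_conditioned),
            class = "detectability_fit")
}

#' Fit the detectability logistic to (SNR, fraction undetected) points
#'
#' Least-squares fit of \code{y = 1 / (1 + (x/S50)^h)}.
#'
#' @param points data.frame with columns \code{snr} and
#'   \code{fraction_undetected}.
#' @return List with \code{S50}, \code{h}, \code{ill_conditioned}.
#' @export
fit_logistic_detectability <- function(points) {
  x <- points$snr; y <- points$fraction_undetected
  ill <- all(y < 0.5) || all(y > 0.5)
  # initial S50: abscissa where the curve crosses 0.5 (log-interpolated)
  s0 <- if (ill) exp(mean(log(x))) else {
    i <- which(y < 0.5)[1L]
    if (i == 1L) x[1L]
    else exp(stats::approx(y[c(i - 1L, i)], log(x[c(i - 1L, i)]),
                           xout = 0.5)$y)
  }
  obj <- function(p) sum((y - 1 / (1 + (x / p[1])^p[2]))^2)
  res <- stats::nlminb(c(s0, 10), obj, lower = c(1e-6, 1e-3),
                       upper = c(1e3, 1e3))
  list(S50 = res$par[1], h = res$par[2], ill_conditioned = ill)
}

#' @export
print.detectability_fit <- function(x, ...) {
  cat(sprintf("Detectability: S50 = %.3f SNR, steepness h = %.2f%s\n",
              x$S50, x$h,
              if (x$ill_conditioned) " (ill-conditioned)" else ""))
  invisible(x)
}

#' Sequential-sampling timing-error experiment
#'
#' Renders noise-free spikes at several image columns and sub-sample
#' latencies, extracts each with 7-pixel averaging, fits it, and tabulates
#' the latency error \code{t_fit - t_seeded}. With corrected pixel times
#' the error vanishes at every column; with the uncorrected line-time
#' convention it reproduces the position-dependent acquisition-time error
#' (odd/even mean for bidirectional scans). An additive two-way ANOVA
#' (column + latency) p-value for the latency factor is attached,
#' quantifying that the error does not depend on where the onset falls
#' within the sampling period.
#'
#' @param config a \code{\link{scan_config}}.
#' @param columns spike positions (must allow the 7-pixel window).
#' @param latencies seeded latencies, ms (default 10 values spanning one
#'   1-kHz sampling period, 3.9-4.4 ms).
#' @param correct_times logical; use corrected per-pixel times.
#' @param preset kinetics of the rendered spike (default OG-5N means).
#' @param stimulus_onset stimulus time, ms.
#' @param spatial_sd Gaussian spatial SD of the rendered spike, pixels.
#' @return data.frame with columns \code{column}, \code{latency_ms},
#'   \code{error_us}; ANOVA p-value for the latency factor in attribute
#'   \code{"anova_p_latency"}.
#' @export
timing_error_experiment <- function(config, columns = c(4L, 256L, 509L),
                                    latencies = seq(3.9, 4.4, length.out = 10),
                                    correct_times = TRUE,
                                    preset = indicator_preset("OG5N"),
                                    stimulus_onset = 50, spatial_sd = 4) {
  stopifnot(inherits(config, "scan_config"))
  tm <- build_pixel_time_map(config)
  F0 <- 100
  rows <- list()
  for (col in columns) {
    for (lat in latencies) {
      p <- preset$param_means
      p$t0 <- lat
      img <- render_xt_image(list(list(params = p, column = col)),
                             config, stimulus_onset = stimulus_onset,
                             F0 = F0, background = 0,
                             spatial_sd = spatial_sd, noise_sd = 0)
      tr <- extract_trace(img, col, F0 = F0, timemap = tm,
                          correct_times = correct_times)
      st <- fit_settings(init = p)
      f <- fit_spike(tr, st)
      rows[[length(rows) + 1L]] <-
        data.frame(column = col, latency_ms = lat,
                   error_us = (f$params$t0 - lat) * 1000)
    }
  }
  tab <- do.call(rbind, rows)
  p_lat <- NA_real_
  if (length(columns) > 1L && length(latencies) > 1L) {
    a <- stats::aov(error_us ~ factor(column) + factor(latency_ms),
                    data = tab)
    p_lat <- summary(a)[[1]][["Pr(>F)"]][2]
  }
  attr(tab, "anova_p_latency") <- p_lat
  tab
}

#' Write a benchmark report to CSV
#'
#' @param report a \code{\link{compare_algorithms}} report (or any
#'   data.frame).
#' @param path output CSV path.
#' @param meta optional named character vector written as header comments.
#' @return \code{path}, invisibly.
#' @export
write_benchmark_csv <- function(report, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# caspikes %s",
                     as.character(utils::packageVersion("caspikes"))), con)
  if (!is.null(meta))
    writeLines(sprintf("# %s=%s", names(meta), meta), con)
  utils::write.csv(as.data.frame(report), con, row.names = FALSE)
  invisible(path)
}
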