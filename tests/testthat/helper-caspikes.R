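# Shared fixtures, all generated in code.

# Small scan config for fast image-based tests.
small_scan <- function(mode = "unidirectional", m = 128L, n = 64L,
                       f = 1000) {
  scan_config(mode = mode, f = f, n = n, m = m, tp_us = 0.515)
}

# Default 1-kHz full-frame config used by the simulation studies.
study_scan <- function(mode = "unidirectional") {
  scan_config_preset(1000, mode)
}

# Random valid spike parameters (for property-style loops).
random_params <- function() {
  spike_params(t0 = runif(1, 1, 20), FM = runif(1, 0.2, 3),
               alpha = runif(1, 0, 0.6), tauA = runif(1, 1, 8),
               tauT = runif(1, 1, 20))
}

# Brute-force dense-grid descriptor oracle (1-us grid, linear bracketing of
# the half-maximum crossings); independent of compute_descriptors().
oracle_descriptors <- function(params, t_end = 200, step = 0.001) {
  tt <- seq(params$t0, t_end, by = step)
  v <- evaluate_spike(params, tt)
  i <- which.max(v)
  A <- v[i]
  TTP <- tt[i] - params$t0
  half <- A / 2
  FDHM <- NA_real_
  if (i < length(v)) {
    up <- which(v[seq_len(i)] >= half)[1]
    post <- v[i:length(v)]
    dn <- which(post < half)[1]
    if (!is.na(dn)) FDHM <- tt[i + dn - 1L] - tt[up]
  }
  list(A = A, TTP = TTP, FDHM = FDHM)
}

# Synthetic trace on the standard grid: spike + optional noise.
study_trace <- function(params, noise_sd = 0, stimulus_onset = 50,
                        config = study_scan(), column = 256L) {
  tm <- build_pixel_time_map(config)
  times <- tm$times[, column] - stimulus_onset
  vals <- evaluate_spike(params, times)
  if (noise_sd > 0) vals <- vals + rnorm(length(vals), 0, noise_sd)
  pre <- times < 0
  fluo_trace(times, vals,
             baseline_sd = if (noise_sd > 0) sd(vals[pre]) else 0,
             center_column = column)
}
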