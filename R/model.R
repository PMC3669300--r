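# Kinetic model of the calcium-spike fluorescence time course and its
# numerically derived descriptors.

#' Calcium-spike model parameters
#'
#' Bundle and validate the five parameters of the phenomenological spike
#' model. The fluorescence increase is
#' \deqn{\Delta F(t) = F_M (1 - e^{-(t-t_0)/\tau_A})
#'                      (\alpha + (1-\alpha) e^{-(t-t_0)/\tau_T})}
#' for \eqn{t \ge t_0} and 0 before the onset. \code{FM} is the maximal
#' increase of F/F0 that would be reached in the absence of release
#' termination, \code{alpha} the fraction of the signal contributed by the
#' calcium concentration build-up (the late plateau is \code{FM * alpha}),
#' and \code{tauA}, \code{tauT} the activation and termination time
#' constants.
#'
#' @param t0 latency of spike onset relative to the stimulus, ms
#'   (\code{t0 >= 0}).
#' @param FM maximal fluorescence increase, dF/F0 units (> 0).
#' @param alpha build-up fraction, dimensionless in \[0, 1\].
#' @param tauA activation time constant, ms (> 0).
#' @param tauT termination time constant, ms (> 0).
#' @return An object of class \code{"spike_params"}: a named list with the
#'   five parameters.
#' @examples
#' p <- spike_params(t0 = 4, FM = 1, alpha = 0.2, tauA = 3, tauT = 6)
#' evaluate_spike(p, c(0, 4, 10, 50))
#' @export
spike_params <- function(t0, FM, alpha, tauA, tauT) {
  p <- list(t0 = as.numeric(t0), FM = as.numeric(FM),
            alpha = as.numeric(alpha), tauA = as.numeric(tauA),
            tauT = as.numeric(tauT))
  validate_spike_params(p)
  structure(p, class = "spike_params")
}

#' @export
print.spike_params <- function(x, ...) {
  cat("Calcium spike parameters:\n")
  cat(sprintf("  t0    = %.4g ms\n  FM    = %.4g dF/F0\n  alpha = %.4g\n",
              x$t0, x$FM, x$alpha))
  cat(sprintf("  tauA  = %.4g ms\n  tauT  = %.4g ms\n", x$tauA, x$tauT))
  invisible(x)
}

validate_spike_params <- function(p) {
  vals <- unlist(p[c("t0", "FM", "alpha", "tauA", "tauT")])
  if (length(vals) != 5L || any(!is.finite(vals)))
    stop("spike parameters must be five finite numbers", call. = FALSE)
  if (p$FM <= 0) stop("FM must be > 0", call. = FALSE)
  if (p$tauA <= 0) stop("tauA must be > 0", call. = FALSE)
  if (p$tauT <= 0) stop("tauT must be > 0", call. = FALSE)
  if (p$alpha < 0 || p$alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (p$t0 < 0) stop("t0 must be >= 0", call. = FALSE)
  invisible(TRUE)
}

# Coerce a length-5 numeric vector in canonical order to spike_params-like
# list without validation (used inside optimizers where bounds guarantee
# validity up to numerical fuzz).
par_vec_to_list <- function(v) {
  list(t0 = v[[1L]], FM = v[[2L]], alpha = v[[3L]],
       tauA = v[[4L]], tauT = v[[5L]])
}

par_list_to_vec <- function(p) {
  c(t0 = p$t0, FM = p$FM, alpha = p$alpha, tauA = p$tauA, tauT = p$tauT)
}

#' Evaluate the spike model on an arbitrary time grid
#'
#' Pointwise evaluation, so non-uniform (acquisition-time-corrected) grids
#' are supported. The curve is exactly 0 for \code{t <= t0} and continuous
#' at the onset.
#'
#' @param params a \code{\link{spike_params}} object (or a named list with
#'   the same fields).
#' @param times numeric vector of times, ms.
#' @return Numeric vector of dF/F0 values, same length as \code{times}.
#' @export
evaluate_spike <- function(params, times) {
  validate_spike_params(params)
  if (any(!is.finite(times))) stop("times must be finite", call. = FALSE)
  s <- times - params$t0
  out <- numeric(length(times))
  on <- s > 0
  if (any(on)) {
    sp <- s[on]
    out[on] <- params$FM * (1 - exp(-sp / params$tauA)) *
      (params$alpha + (1 - params$alpha) * exp(-sp / params$tauT))
  }
  out
}

# Model and analytic Jacobian for a parameter vector in canonical order
# (t0, FM, alpha, tauA, tauT); used by the fitting module. No validation.
spike_model_vec <- function(v, times) {
  s <- times - v[1L]
  out <- numeric(length(times))
  on <- s > 0
  if (any(on)) {
    sp <- s[on]
    out[on] <- v[2L] * (1 - exp(-sp / v[4L])) *
      (v[3L] + (1 - v[3L]) * exp(-sp / v[5L]))
  }
  out
}

spike_jacobian_vec <- function(v, times) {
  n <- length(times)
  J <- matrix(0, n, 5L)
  s <- times - v[1L]
  on <- s > 0
  if (any(on)) {
    sp <- s[on]
    FM <- v[2L]; al <- v[3L]; tA <- v[4L]; tT <- v[5L]
    eA <- exp(-sp / tA)
    eT <- exp(-sp / tT)
    act <- 1 - eA
    ter <- al + (1 - al) * eT
    # d/dt0: shift derivative = -FM * d/ds [act*ter]
    dact_ds <- eA / tA
    dter_ds <- -(1 - al) * eT / tT
    J[on, 1L] <- -FM * (dact_ds * ter + act * dter_ds)
    J[on, 2L] <- act * ter
    J[on, 3L] <- FM * act * (1 - eT)
    J[on, 4L] <- FM * ter * (-eA * sp / tA^2)
    J[on, 5L] <- FM * act * (1 - al) * eT * sp / tT^2
  }
  J
}

#' Numeric descriptors of a fitted spike
#'
#' Computes the peak amplitude \code{A}, the time to peak \code{TTP}
#' (interval from the onset \code{t0} to the peak) and the full duration at
#' half-maximum \code{FDHM} (interval between the half-amplitude crossings
#' on the ascending and descending arms) of the theoretical curve defined
#' by \code{params}. The peak is located on a dense grid and refined by
#' golden-section search; the half-maximum crossings are located by
#' bracketed root finding.
#'
#' \code{FDHM} is \code{NA} when the curve never descends below A/2 inside
#' the window (e.g. \code{alpha = 1}, or a plateau above half-amplitude);
#' downstream plausibility filters treat \code{NA} as a failed duration
#' cut.
#'
#' @param params a \code{\link{spike_params}} object.
#' @param window numeric length-2, analysis window in ms; must contain
#'   \code{t0}. Default \code{c(0, 200)}.
#' @param resolution grid step for the coarse search, ms. Default 0.01.
#' @return Object of class \code{"spike_descriptors"}: list with fields
#'   \code{A}, \code{TTP}, \code{FDHM} (possibly \code{NA}) and \code{t0}.
#' @export
compute_descriptors <- function(params, window = c(0, 200), resolution = 0.01) {
  validate_spike_params(params)
  if (length(window) != 2L || window[2] <= window[1])
    stop("window must be an increasing length-2 vector", call. = FALSE)
  if (params$t0 < window[1] || params$t0 >= window[2])
    stop("analysis window must contain the onset t0", call. = FALSE)

  f <- function(t) evaluate_spike(params, t)
  t_end <- window[2]
  grid <- seq(params$t0, t_end, by = resolution)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  vals <- f(grid)
  imax <- which.max(vals)

  if (imax == length(grid) ||
      vals[imax] - vals[length(vals)] <= 1e-12 * vals[imax]) {
    # monotone (or numerically flat) up to the window end: no descending
    # arm; the peak position is reported at the window end
    A <- max(vals[imax], vals[length(vals)])
    t_peak <- t_end
    FDHM <- NA_real_
  } else {
    lo <- grid[max(imax - 1L, 1L)]
    hi <- grid[min(imax + 1L, length(grid))]
    opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                           tol = 1e-8)
    A <- opt$objective
    t_peak <- opt$maximum
    half <- A / 2
    # ascending crossing in (t0, t_peak)
    t_up <- stats::uniroot(function(t) f(t) - half,
                           lower = params$t0, upper = t_peak,
                           tol = 1e-6)$root
    # descending crossing: first grid point past the peak below half
    below <- which(vals < half & grid > t_peak)
    if (length(below) == 0L) {
      FDHM <- NA_real_
    } else {
      j <- below[1L]
      t_dn <- stats::uniroot(function(t) f(t) - half,
                             lower = grid[j - 1L], upper = grid[j],
                             tol = 1e-6)$root
      FDHM <- t_dn - t_up
    }
  }
  structure(list(A = A, TTP = t_peak - params$t0, FDHM = FDHM,
                 t0 = params$t0),
            class = "spike_descriptors")
}

#' @export
print.spike_descriptors <- function(x, ...) {
  cat(sprintf("A = %.4g dF/F0, TTP = %.4g ms, FDHM = %s, t0 = %.4g ms\n",
              x$A, x$TTP,
              if (is.na(x$FDHM)) "undefined" else sprintf("%.4g ms", x$FDHM),
              x$t0))
  invisible(x)
}
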