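#' Demodulate a ventilation signal and diagnose Cheyne-Stokes respiration
#'
#' Fits the amplitude-modulation model of periodic breathing to a raw
#' ventilation signal, end to end: breath detection by penalized
#' change-point segmentation, envelope reconstruction from retained
#' breath peaks (with apnea gaps forced to zero), sliding-window Matrix
#' Pencil estimation of the carrier amplitude, modulation index
#' \eqn{\hat h = 2|\hat a_2|/\hat a_1} and modulation frequency
#' \eqn{\hat f_m}, detection of pathological oscillation zones
#' (\eqn{\hat h \ge h_0}, \eqn{\hat f_m} within 8--30 mHz, one-minute
#' persistence), and the final three-class diagnosis (CSR with central
#' apneas, periodic breathing, or non-CSR).
#'
#' @param x the ventilation signal: a \code{ts} in seconds, a numeric
#'   vector (then \code{fs} is required), a \code{"csr_recording"}, or a
#'   file path readable by \code{\link{read_signal}}.
#' @param fs sampling rate in Hz when \code{x} is a bare numeric vector.
#' @param control a \code{\link{csr_control}} configuration.
#' @return An object of class \code{"csr_demod"} with components
#'   \code{signal}, \code{envelope}, \code{breaths} (the segmentation),
#'   \code{track} (per-window estimates), \code{flags}, \code{zones} and
#'   \code{diagnosis}; supports \code{print}, \code{summary},
#'   \code{coef}, \code{plot}, \code{fitted}, \code{residuals} and
#'   \code{simulate}.
#' @examples
#' sched <- csr_schedule(c(0, 300), c(300, 1200), h = c(0, 1.5), f_m = 0.01)
#' fit <- csr_demod(build_recording(sched, seed = 1))
#' fit$diagnosis$label
#' @export
csr_demod <- function(x, fs = NULL, control = csr_control()) {
  stopifnot(inherits(control, "csr_control"))
  if (inherits(x, "csr_recording")) x <- x$signal
  if (is.character(x)) x <- read_signal(x)
  if (!stats::is.ts(x)) {
    if (is.null(fs)) stop_invalid("fs is required for a plain numeric signal")
    x <- stats::ts(as.numeric(x), start = 0, frequency = fs)
  }
  env_out <- ventilation_envelope(x, control)
  track <- sliding_estimate(env_out$envelope,
                            window_s = control$window_s,
                            overlap = control$overlap,
                            order = control$order,
                            pencil_ratio = control$pencil_ratio,
                            amplitude_floor_frac = control$amplitude_floor_frac)
  flags <- flag_windows(track, h0 = control$h0, f_band = control$f_band)
  zones <- build_zones(track, flags, min_zone_s = control$min_zone_s)
  dur <- ts_duration(x)
  diag <- classify_patient(zones, total_min_s = control$total_min_s,
                           episode_min_s = control$episode_min_s,
                           h_apnea = control$h_apnea,
                           per_hour = control$per_hour, duration_s = dur)
  structure(list(signal = x, envelope = env_out$envelope,
                 breaths = env_out$segmentation, track = track,
                 flags = flags, zones = zones, diagnosis = diag,
                 duration_s = dur, control = control),
            class = "csr_demod")
}

#' @export
print.csr_demod <- function(x, ...) {
  cat(sprintf("Amplitude demodulation of a %.0f s ventilation signal (fs = %g Hz)\n",
              x$duration_s, ts_fs(x$signal)))
  cat(sprintf("  %d breaths, %d gaps, %d estimation windows (%d flagged)\n",
              nrow(x$breaths$peaks), nrow(x$breaths$gaps),
              nrow(x$track), sum(x$flags)))
  print(x$diagnosis)
  invisible(x)
}

#' @export
summary.csr_demod <- function(object, ...) {
  pk <- object$breaths$peaks
  tr <- object$track
  out <- list(
    duration_s = object$duration_s,
    n_breaths = nrow(pk),
    median_breath_interval_s = if (nrow(pk) >= 2) stats::median(diff(pk$time_s)) else NA_real_,
    n_gaps = nrow(object$breaths$gaps),
    n_windows = nrow(tr),
    frac_valid = if (nrow(tr)) mean(tr$valid) else NA_real_,
    h_range = if (any(tr$valid)) range(tr$h_hat[tr$valid]) else c(NA_real_, NA_real_),
    zones = object$zones,
    diagnosis = object$diagnosis)
  class(out) <- "summary.csr_demod"
  out
}

#' @export
print.summary.csr_demod <- function(x, ...) {
  cat(sprintf("Recording: %.0f s, %d breaths (median interval %.2f s), %d gap(s)\n",
              x$duration_s, x$n_breaths, x$median_breath_interval_s, x$n_gaps))
  cat(sprintf("Estimation: %d windows, %.0f%% valid, h_hat in [%.3f, %.3f]\n",
              x$n_windows, 100 * x$frac_valid, x$h_range[1], x$h_range[2]))
  if (nrow(x$zones)) {
    cat("Oscillation zones:\n")
    print(x$zones, row.names = FALSE)
  } else cat("No oscillation zones detected.\n")
  print(x$diagnosis)
  invisible(x)
}

#' @export
coef.csr_demod <- function(object, ...) {
  tr <- object$track
  fl <- object$flags
  c(h_bar = object$diagnosis$h_bar,
    f_m = if (any(fl)) stats::median(tr$f_m_hat[fl]) else NA_real_,
    A_c = if (any(tr$valid)) stats::median(tr$A_c_hat[tr$valid]) else NA_real_)
}

# Model envelope predicted by the per-window estimates, evaluated at the
# envelope sample times using each sample's nearest window.
model_envelope <- function(object) {
  env <- object$envelope
  tr <- object$track
  t <- ts_times(env)
  if (nrow(tr) == 0) return(rep(NA_real_, length(t)))
  w <- attr(tr, "window_s") %||% object$control$window_s
  idx <- vapply(t, function(tt) which.min(abs(tr$t_center - tt)), integer(1))
  tau <- t - (tr$t_center[idx] - w / 2)
  pmax(0, tr$A_c_hat[idx] + tr$A_c_hat[idx] * tr$h_hat[idx] *
         cos(2 * pi * tr$f_m_hat[idx] * tau + tr$phi_hat[idx]))
}

#' @export
fitted.csr_demod <- function(object, ...) {
  stats::ts(model_envelope(object), start = ts_start(object$envelope),
            frequency = ts_fs(object$envelope))
}

#' @export
residuals.csr_demod <- function(object, ...) {
  object$envelope - fitted(object)
}

#' Simulate recordings from a fitted demodulation
#'
#' Re-synthesises ventilation signals whose modulation schedule follows
#' the fitted per-window estimates (piecewise-constant \code{h} and
#' \code{f_m} over the hop grid, clipped at the Cheyne-Stokes band),
#' using the ideal cosine carrier and the recording's estimated carrier
#' amplitude.
#'
#' @param object a \code{"csr_demod"} fit.
#' @param nsim number of recordings.
#' @param seed integer seed.
#' @param noise_sd additive Gaussian noise SD.
#' @param ... unused.
#' @return A list of \code{"csr_recording"} objects (length \code{nsim}).
#' @export
simulate.csr_demod <- function(object, nsim = 1, seed = NULL,
                               noise_sd = 0, ...) {
  tr <- object$track
  if (nrow(tr) < 1) stop_invalid("no estimation windows to simulate from")
  hop <- attr(tr, "hop_s") %||% 24
  w <- attr(tr, "window_s") %||% object$control$window_s
  starts <- c(0, tr$t_center[-1] - hop / 2)
  ends <- c(starts[-1], tr$t_center[nrow(tr)] + w / 2)
  ok <- ends > starts
  A <- stats::median(tr$A_c_hat[tr$valid], na.rm = TRUE)
  if (!is.finite(A) || A <= 0) A <- 1
  sched <- csr_schedule(start_s = starts[ok], end_s = ends[ok],
                        h = pmax(0, tr$h_hat[ok]),
                        f_m = pmax(0, tr$f_m_hat[ok]), A_c = A)
  lapply(seq_len(nsim), function(k)
    build_recording(sched, fs = ts_fs(object$signal), noise_sd = noise_sd,
                    seed = if (is.null(seed)) NULL else seed + k - 1L))
}

#' Plot a fitted demodulation
#'
#' Three stacked panels: the ventilation signal with retained breath
#' peaks and the reconstructed envelope; the per-window modulation index
#' with the oscillation threshold and detected zones shaded; and the
#' per-window modulation frequency with the pathological band.
#'
#' @param x a \code{"csr_demod"}.
#' @param ... forwarded to the signal panel's \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.csr_demod <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1.5, 1), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op))
  tt <- ts_times(x$signal)
  plot(tt, as.numeric(x$signal), type = "l", col = "grey40",
       xlab = "time (s)", ylab = "ventilation", ...)
  graphics::lines(ts_times(x$envelope), as.numeric(x$envelope),
                  col = "red", lwd = 2)
  graphics::points(x$breaths$peaks$time_s, x$breaths$peaks$amplitude,
                   pch = 8, col = "red", cex = 0.6)
  tr <- x$track
  plot(tr$t_center, tr$h_hat, type = "b", pch = 16, cex = 0.5,
       xlab = "time (s)", ylab = "modulation index h", xlim = range(tt))
  graphics::abline(h = x$control$h0, lty = 2, col = "red")
  graphics::abline(h = x$control$h_apnea, lty = 3, col = "red")
  if (nrow(x$zones))
    graphics::rect(x$zones$start_s, graphics::par("usr")[3],
                   x$zones$end_s, graphics::par("usr")[4],
                   col = grDevices::adjustcolor("red", 0.12), border = NA)
  plot(tr$t_center, 1000 * tr$f_m_hat, type = "b", pch = 16, cex = 0.5,
       xlab = "time (s)", ylab = "f_m (mHz)", xlim = range(tt))
  graphics::abline(h = 1000 * x$control$f_band, lty = 2, col = "red")
  invisible(x)
}
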