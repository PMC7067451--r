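#' Penalized change-point segmentation of a ventilation signal
#'
#' Segments the signal by minimising the sum over segments of the residual
#' sum of squares of a straight-line fit (capturing both the local slope
#' and the local mean) plus a penalty \code{beta} per change point,
#' solved exactly by a pruned dynamic-programming search (PELT). On a
#' breathing signal the optimal break points sit at the inspiration peaks
#' and expiration troughs.
#'
#' @param signal a \code{\link[stats]{ts}} sampled in seconds (e.g. from
#'   \code{\link{modulate}} or \code{\link{read_signal}}).
#' @param beta penalty per change point, >= 0. The default (\code{NULL})
#'   scales with the squared robust signal amplitude and the sampling
#'   rate, \code{beta = 0.05 * fs * s^2} with \code{s} the 95th percentile
#'   of \code{|signal - median|}: large enough not to split breath
#'   half-waves, small enough to separate consecutive breaths.
#' @param min_seg_s minimum segment duration in seconds (default 0.5,
#'   half the shortest physiological inspiration).
#' @return Numeric vector of change-point times in seconds (interior
#'   segment boundaries, strictly increasing).
#' @examples
#' y <- modulate(csr_params(h = 0), duration_s = 60, fs = 25)
#' detect_change_points(y)
#' @export
detect_change_points <- function(signal, beta = NULL, min_seg_s = 0.5) {
  stopifnot(stats::is.ts(signal))
  v <- as.numeric(signal)
  if (length(v) < 3) stop_invalid("signal must have at least 3 samples")
  if (any(!is.finite(v))) stop_invalid("signal contains non-finite values")
  fs <- ts_fs(signal)
  if (is.null(beta)) beta <- 0.05 * fs * amp_scale(v)^2
  if (!is.numeric(beta) || beta < 0) stop_invalid("beta must be >= 0")
  minseg <- max(2L, as.integer(round(min_seg_s * fs)))
  idx <- pelt_linear(v, beta, minseg)
  ts_start(signal) + (idx - 1) / fs
}

#' Retain breath peaks from a change-point segmentation
#'
#' Fits a slope to every inter-change-point section, discards near-flat
#' sections (\code{|slope| < slope_min}, treated as noise), and keeps as
#' breath peaks the boundaries where a retained rising section meets a
#' retained falling section, provided the two flanking sections together
#' span more than \code{min_section_s} (so sub-second spikes are not
#' breaths).
#'
#' @param signal the segmented \code{ts}.
#' @param change_points change-point times from
#'   \code{\link{detect_change_points}} on the same signal.
#' @param slope_min minimum absolute section slope, in signal units per
#'   second (default 1e-3; intended for amplitude-normalised signals).
#' @param min_section_s minimum total flanking duration of a peak in
#'   seconds (default 1).
#' @return An object of class \code{"breath_seg"}: list with
#'   \code{change_points}, a \code{sections} data frame (start, end,
#'   slope, kept), a \code{peaks} data frame (\code{time_s},
#'   \code{amplitude}) and an empty \code{gaps} slot (see
#'   \code{\link{detect_gaps}}).
#' @export
extract_breaths <- function(signal, change_points, slope_min = 1e-3,
                            min_section_s = 1.0) {
  stopifnot(stats::is.ts(signal))
  v <- as.numeric(signal)
  fs <- ts_fs(signal)
  t0 <- ts_start(signal)
  t_end <- t0 + length(v) / fs
  bounds <- sort(unique(c(t0, change_points, t_end)))
  empty <- data.frame(time_s = numeric(0), amplitude = numeric(0))
  if (length(bounds) < 3) {
    return(structure(list(change_points = change_points,
                          sections = NULL, peaks = empty,
                          gaps = data.frame(start_s = numeric(0),
                                            end_s = numeric(0)),
                          t_end = t_end),
                     class = "breath_seg"))
  }
  ns <- length(bounds) - 1L
  slope <- numeric(ns)
  for (k in seq_len(ns)) {
    i <- max(1L, round((bounds[k] - t0) * fs) + 1L)
    j <- min(length(v), round((bounds[k + 1] - t0) * fs))
    if (j - i < 1L) { slope[k] <- 0; next }
    tt <- (i:j) / fs
    slope[k] <- stats::cov(tt, v[i:j]) / stats::var(tt)
  }
  sections <- data.frame(start_s = bounds[-length(bounds)],
                         end_s = bounds[-1], slope = slope,
                         kept = abs(slope) >= slope_min)
  ks <- which(sections$kept)
  peaks <- empty
  if (length(ks) >= 2) {
    for (q in seq_len(length(ks) - 1L)) {
      a <- ks[q]; b <- ks[q + 1L]
      if (sections$slope[a] > 0 && sections$slope[b] < 0) {
        flank <- (sections$end_s[a] - sections$start_s[a]) +
                 (sections$end_s[b] - sections$start_s[b])
        if (flank > min_section_s) {
          # breath maximum over the two flanking sections (the
          # change-point boundary only brackets it)
          i <- max(1L, round((sections$start_s[a] - t0) * fs) + 1L)
          j <- min(length(v), round((sections$end_s[b] - t0) * fs))
          im <- i + which.max(v[i:j]) - 1L
          peaks <- rbind(peaks, data.frame(time_s = t0 + (im - 1L) / fs,
                                           amplitude = v[im]))
        }
      }
    }
  }
  structure(list(change_points = change_points, sections = sections,
                 peaks = peaks,
                 gaps = data.frame(start_s = numeric(0), end_s = numeric(0)),
                 t_end = t_end),
            class = "breath_seg")
}

#' @export
print.breath_seg <- function(x, ...) {
  cat(sprintf("Breath segmentation: %d change points, %d peaks, %d gaps\n",
              length(x$change_points), nrow(x$peaks), nrow(x$gaps)))
  if (nrow(x$peaks) >= 2)
    cat(sprintf("  median inter-peak interval: %.2f s\n",
                stats::median(diff(x$peaks$time_s))))
  invisible(x)
}

#' Detect ventilation interruptions between breaths
#'
#' A gap (interrupted ventilation, e.g. a central apnea) is declared
#' between two consecutive breath peaks whenever their spacing is strictly
#' greater than \code{gap_factor} times the median inter-peak spacing.
#'
#' @param peak_times ordered breath peak times in seconds (or a
#'   \code{"breath_seg"} object, whose gaps slot is then filled).
#' @param gap_factor multiple of the median spacing (default 3).
#' @return A data frame with columns \code{start_s}, \code{end_s}; with
#'   fewer than 3 peaks an empty frame is returned with a warning.
#' @examples
#' detect_gaps(c(0, 4, 8, 12, 16, 36, 40, 44))
#' @export
detect_gaps <- function(peak_times, gap_factor = 3) {
  seg <- NULL
  if (inherits(peak_times, "breath_seg")) {
    seg <- peak_times
    peak_times <- seg$peaks$time_s
  }
  if (length(peak_times) < 3) {
    warning("fewer than 3 peaks: no gap detection possible")
    gaps <- data.frame(start_s = numeric(0), end_s = numeric(0))
  } else {
    sp <- diff(peak_times)
    med <- stats::median(sp)
    w <- which(sp > gap_factor * med)
    gaps <- data.frame(start_s = peak_times[w], end_s = peak_times[w + 1])
  }
  if (!is.null(seg)) { seg$gaps <- gaps; return(seg) }
  gaps
}

#' Reconstruct the ventilation envelope from breath peaks
#'
#' Linearly interpolates through the (peak time, peak amplitude) points
#' and resamples uniformly at \code{fs_env}; inside every detected gap the
#' envelope is forced to zero (the transition ramps stay between the
#' bounding peaks and the gap interior). Values are clipped at zero.
#'
#' @param seg a \code{"breath_seg"} with gaps filled (see
#'   \code{\link{detect_gaps}}), needing at least 2 peaks.
#' @param fs_env output sampling rate in Hz (default 1; the envelope band
#'   is below 30 mHz so 1 Hz leaves a wide Nyquist margin).
#' @param t_end end of the output grid in seconds (defaults to the end of
#'   the segmented signal).
#' @return A \code{ts} at rate \code{fs_env} with attribute
#'   \code{"source_peaks"}.
#' @export
reconstruct_envelope <- function(seg, fs_env = 1.0, t_end = NULL) {
  stopifnot(inherits(seg, "breath_seg"))
  if (nrow(seg$peaks) < 2) stop_invalid("insufficient breaths for envelope")
  if (is.null(t_end)) t_end <- seg$t_end
  n <- round(t_end * fs_env)
  t <- (seq_len(n) - 1) / fs_env
  env <- stats::approx(seg$peaks$time_s, seg$peaks$amplitude,
                       xout = t, rule = 2)$y
  if (nrow(seg$gaps) > 0)
    for (g in seq_len(nrow(seg$gaps)))
      env[t > seg$gaps$start_s[g] & t < seg$gaps$end_s[g]] <- 0
  env[env < 0] <- 0
  out <- stats::ts(env, start = 0, frequency = fs_env)
  attr(out, "source_peaks") <- nrow(seg$peaks)
  out
}

#' Full envelope extraction from a raw ventilation signal
#'
#' Convenience wrapper running the whole first stage: baseline removal
#' (subtract a running 30 s median), amplitude normalisation (divide by
#' the 95th percentile of the absolute detrended signal, so the slope
#' threshold acts on a unit-amplitude signal), change-point segmentation,
#' breath filtering, gap detection and envelope reconstruction. Peak
#' amplitudes and the envelope are returned in the detrended signal's
#' original units.
#'
#' @param signal a \code{ts} ventilation signal (seconds time base).
#' @param control a \code{\link{csr_control}} list of tunables.
#' @return List with \code{envelope} (a \code{ts} at
#'   \code{control$fs_env}), \code{segmentation} (a \code{"breath_seg"}),
#'   and \code{scale} (the normalisation factor).
#' @export
ventilation_envelope <- function(signal, control = csr_control()) {
  stopifnot(stats::is.ts(signal))
  v <- as.numeric(signal)
  fs <- ts_fs(signal)
  if (control$detrend_s > 0 && length(v) > 3) {
    k <- min(round(control$detrend_s * fs), length(v) - 1)
    k <- max(3L, as.integer(k - (k %% 2 == 0)))
    # reflection padding: the running median must behave at the edges as
    # it does in the interior, or the first/last breaths are flattened
    p <- k %/% 2
    vp <- c(rev(v[seq_len(p) + 1L]), v, rev(v[length(v) - seq_len(p)]))
    trend <- stats::runmed(vp, k)[p + seq_along(v)]
    v <- v - trend
  }
  s <- amp_scale(v)
  xn <- stats::ts(v / s, start = ts_start(signal), frequency = fs)
  cps <- detect_change_points(xn, beta = control$beta,
                              min_seg_s = control$min_seg_s)
  seg <- extract_breaths(xn, cps, slope_min = control$slope_min,
                         min_section_s = control$min_section_s)
  seg <- detect_gaps(seg, gap_factor = control$gap_factor)
  seg$peaks$amplitude <- seg$peaks$amplitude * s
  env <- reconstruct_envelope(seg, fs_env = control$fs_env,
                              t_end = length(v) / fs)
  list(envelope = env, segmentation = seg, scale = s)
}
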