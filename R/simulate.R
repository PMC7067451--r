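#' Amplitude-modulation parameters of a breathing pattern
#'
#' Bundles the parameters of the amplitude-modulated ventilation model:
#' a sinusoidal carrier at the breathing rate \code{f_c}, and a sinusoidal
#' envelope \eqn{env(t) = A_c [1 + h \cos(2\pi f_m t + \phi_m)]} whose
#' oscillation rate \code{f_m} and depth \code{h} describe the
#' periodic-breathing pattern. Over-modulation (\code{h > 1}) drives the
#' envelope negative; clipping it at zero produces central apneas.
#'
#' @param A_c carrier (breath) amplitude, arbitrary ventilation units, > 0.
#' @param f_c carrier frequency in Hz; adult breathing is 0.25--0.33 Hz.
#' @param h modulation index, dimensionless, >= 0. 0 is steady breathing,
#'   (0, 1] is periodic breathing, > 1 produces apneas.
#' @param f_m modulation frequency in Hz; pathological Cheyne-Stokes
#'   oscillations lie in 8--30 mHz.
#' @param phi_m modulation phase in radians.
#' @return An object of class \code{"csr_params"}.
#' @examples
#' csr_params(h = 0.5, f_m = 0.01)
#' @export
csr_params <- function(A_c = 1, f_c = 0.3, h = 0, f_m = 0.015, phi_m = 0) {
  if (!is.numeric(A_c) || A_c <= 0) stop_invalid("A_c must be > 0")
  if (!is.numeric(f_c) || f_c <= 0) stop_invalid("f_c must be > 0")
  if (!is.numeric(h) || h < 0) stop_invalid("h must be >= 0")
  if (!is.numeric(f_m) || f_m < 0) stop_invalid("f_m must be >= 0")
  structure(list(A_c = A_c, f_c = f_c, h = h, f_m = f_m, phi_m = phi_m),
            class = "csr_params")
}

#' @export
print.csr_params <- function(x, ...) {
  cat(sprintf(
    "AM breathing model: A_c = %g, f_c = %g Hz, h = %g, f_m = %g Hz, phi_m = %g rad\n",
    x$A_c, x$f_c, x$h, x$f_m, x$phi_m))
  invisible(x)
}

# Clipped modulation envelope at times t (seconds).
envelope_model <- function(t, A_c, h, f_m, phi_m) {
  pmax(0, A_c * (1 + h * cos(2 * pi * f_m * t + phi_m)))
}

#' Synthesise an amplitude-modulated ventilation signal
#'
#' Samples \eqn{y(t) = env(t)\,H(env(t))\cos(2\pi f_c t)} where
#' \eqn{env(t) = A_c[1 + h\cos(2\pi f_m t + \phi_m)]} and \eqn{H} is the
#' Heaviside step; the clipping is only active when \code{h > 1}, in which
#' case each modulation cycle contains an apnea (an interval of exact
#' zeros) of duration \code{\link{apnea_duration}(h, f_m)}.
#'
#' @param params a \code{\link{csr_params}} object.
#' @param duration_s signal duration in seconds, > 0.
#' @param fs sampling rate in Hz; must resolve the carrier
#'   (\code{fs >= 4 * f_c}).
#' @return A \code{\link[stats]{ts}} object starting at time 0 with
#'   \code{frequency = fs} (time unit: seconds).
#' @examples
#' y <- modulate(csr_params(h = 1.5, f_m = 0.01), duration_s = 300, fs = 25)
#' @export
modulate <- function(params, duration_s, fs = 25) {
  stopifnot(inherits(params, "csr_params"))
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop_invalid("duration_s must be > 0")
  if (!is.numeric(fs) || fs <= 0) stop_invalid("fs must be > 0")
  if (fs < 4 * params$f_c)
    stop_invalid("fs must be at least 4 * f_c to resolve the carrier")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  env <- envelope_model(t, params$A_c, params$h, params$f_m, params$phi_m)
  stats::ts(env * cos(2 * pi * params$f_c * t), start = 0, frequency = fs)
}

#' Apnea duration implied by over-modulation
#'
#' For \code{h > 1} the clipped envelope is zero once per modulation cycle;
#' the zero run lasts \eqn{\delta = (\pi - \arccos(-1/h)) / (\pi f_m)}
#' seconds. For \code{h <= 1} there is no clipping and the duration is 0.
#' As \code{h} grows, \eqn{\delta} approaches half the modulation period.
#'
#' @param h modulation index, >= 0 (vectorised).
#' @param f_m modulation frequency in Hz, > 0 (vectorised).
#' @return Apnea duration in seconds.
#' @examples
#' apnea_duration(1.5, 0.01)  # ~26.8 s
#' @export
apnea_duration <- function(h, f_m) {
  if (any(!is.finite(h)) || any(h < 0)) stop_invalid("h must be >= 0")
  if (any(!is.finite(f_m)) || any(f_m <= 0)) stop_invalid("f_m must be > 0")
  out <- numeric(length(h))
  over <- h > 1
  out[over] <- (pi - acos(-1 / h[over])) / (pi * f_m[if (length(f_m) == 1L) 1L else over])
  out
}

#' Piecewise-constant simulation schedule
#'
#' Describes a recording as consecutive regimes, each with its own
#' modulation parameters (e.g. normal breathing, then \code{h = 0.5},
#' then \code{h = 1.5}). Segments must start at 0, be contiguous and
#' sorted.
#'
#' @param start_s,end_s segment boundaries in seconds (half-open
#'   \code{[start, end)} intervals).
#' @param h,f_m per-segment modulation index and frequency (Hz).
#' @param A_c,f_c carrier amplitude and frequency (recycled).
#' @param phi_m initial modulation phase of the first segment; later
#'   segments continue the modulation phase so the envelope oscillation
#'   is phase-continuous across boundaries.
#' @return A data frame of class \code{"csr_schedule"}.
#' @examples
#' csr_schedule(start_s = c(0, 120, 660), end_s = c(120, 660, 900),
#'              h = c(0, 0.5, 1.5), f_m = 0.01)
#' @export
csr_schedule <- function(start_s, end_s, h, f_m, A_c = 1, f_c = 0.3,
                         phi_m = 0) {
  n <- length(start_s)
  sched <- data.frame(start_s = start_s, end_s = end_s,
                      h = rep_len(h, n), f_m = rep_len(f_m, n),
                      A_c = rep_len(A_c, n), f_c = rep_len(f_c, n))
  if (n < 1) stop_invalid("schedule needs at least one segment")
  if (any(sched$end_s <= sched$start_s))
    stop_invalid("each segment must have end_s > start_s")
  if (is.unsorted(sched$start_s, strictly = TRUE))
    stop_invalid("segments must be sorted by start time")
  if (sched$start_s[1] != 0 ||
      (n > 1 && any(abs(sched$start_s[-1] - sched$end_s[-n]) > 1e-9)))
    stop_invalid("segments must be contiguous from t = 0 (no overlap, no holes)")
  if (any(sched$h < 0) || any(sched$f_m < 0) || any(sched$A_c <= 0))
    stop_invalid("invalid segment parameters (need h >= 0, f_m >= 0, A_c > 0)")
  attr(sched, "phi_m") <- phi_m
  class(sched) <- c("csr_schedule", "data.frame")
  sched
}

# Modulation phase at times t for a schedule, continuous across segment
# boundaries: theta(t) = phi0 + integral of 2*pi*f_m.
schedule_phase <- function(sched, t) {
  phi0 <- attr(sched, "phi_m") %||% 0
  n <- nrow(sched)
  # phase accumulated at each segment start
  acc <- phi0 + c(0, cumsum(2 * pi * sched$f_m * (sched$end_s - sched$start_s)))[seq_len(n)]
  idx <- findInterval(t, sched$start_s, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  acc[idx] + 2 * pi * sched$f_m[idx] * (t - sched$start_s[idx])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Breath-shaped carrier: each cycle is a positive half-sine inspiration
# (fraction `insp_frac` of the cycle) followed by a longer negative
# half-sine expiration, both of unit amplitude. Cycle periods are jittered
# by +/- `jitter` (fraction, uniform). Returns the carrier sampled at `t`
# plus the inspiration peak times (the ground-truth breath times).
breath_carrier <- function(t, sched, jitter = 0, insp_frac = 0.4) {
  dur <- sched$end_s[nrow(sched)]
  starts <- numeric(0)
  periods <- numeric(0)
  pos <- 0
  while (pos < dur) {
    seg <- findInterval(pos, sched$start_s)
    T0 <- 1 / sched$f_c[seg]
    Ti <- T0 * (1 + jitter * stats::runif(1, -1, 1))
    starts <- c(starts, pos)
    periods <- c(periods, Ti)
    pos <- pos + Ti
  }
  idx <- findInterval(t, starts)
  u <- (t - starts[idx]) / periods[idx]
  insp <- u < insp_frac
  val <- numeric(length(t))
  val[insp] <- sin(pi * u[insp] / insp_frac)
  val[!insp] <- -sin(pi * (u[!insp] - insp_frac) / (1 - insp_frac))
  list(values = val, peak_times = starts + insp_frac * periods / 2)
}

# Cosine carrier with phase continuity across segments (f_c may change).
cosine_carrier <- function(t, sched) {
  n <- nrow(sched)
  acc <- c(0, cumsum(2 * pi * sched$f_c * (sched$end_s - sched$start_s)))[seq_len(n)]
  idx <- findInterval(t, sched$start_s)
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  phase <- acc[idx] + 2 * pi * sched$f_c[idx] * (t - sched$start_s[idx])
  # breath times: carrier maxima, one per cycle
  total <- acc[n] + 2 * pi * sched$f_c[n] * (sched$end_s[n] - sched$start_s[n])
  ks <- seq(0, floor(total / (2 * pi)))
  peaks <- stats::approx(c(acc, total),
                         c(sched$start_s, sched$end_s[n]),
                         xout = 2 * pi * ks, rule = 2)$y
  list(values = cos(phase), peak_times = peaks)
}

#' Simulate an annotated ventilation recording
#'
#' Concatenates amplitude-modulated breathing regimes from a
#' \code{\link{csr_schedule}} with an envelope that is phase-continuous
#' across regime boundaries, using either the ideal cosine carrier or a
#' breath-shaped carrier (asymmetric half-sine inspiration/expiration with
#' jittered cycle periods), plus additive Gaussian noise. Per-minute ground
#' truth marks a minute "oscillating" when at least 30 s of it lies in a
#' regime with \code{h >= 0.12} and \code{f_m} within 8--30 mHz.
#'
#' @param schedule a \code{\link{csr_schedule}}.
#' @param fs sampling rate in Hz (default 25).
#' @param noise_sd standard deviation of additive Gaussian noise, in signal
#'   units, >= 0.
#' @param breath_jitter per-cycle uniform period jitter as a fraction in
#'   [0, 0.5); only used by the breath-shaped carrier.
#' @param carrier \code{"cosine"} (ideal model) or \code{"breath"}
#'   (asymmetric, jittered breath shapes).
#' @param seed integer seed; identical seeds give identical recordings.
#' @param h0,f_band threshold and frequency band (Hz) defining which
#'   regimes count as pathological in the ground-truth minutes.
#' @return An object of class \code{"csr_recording"}: list with the signal
#'   (a \code{ts}), the schedule, ground-truth breath (inspiration peak)
#'   times, and per-minute truth labels.
#' @examples
#' sched <- csr_schedule(c(0, 120, 660), c(120, 660, 900),
#'                       h = c(0, 0.5, 1.5), f_m = 0.01)
#' rec <- build_recording(sched, fs = 25, seed = 1)
#' table(rec$truth_minutes)
#' @export
build_recording <- function(schedule, fs = 25, noise_sd = 0,
                            breath_jitter = 0, carrier = c("cosine", "breath"),
                            seed = NULL, h0 = 0.12, f_band = c(0.008, 0.030)) {
  stopifnot(inherits(schedule, "csr_schedule"))
  carrier <- match.arg(carrier)
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (!is.numeric(breath_jitter) || breath_jitter < 0 || breath_jitter >= 0.5)
    stop_invalid("breath_jitter must be in [0, 0.5)")
  dur <- schedule$end_s[nrow(schedule)]
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs

  idx <- findInterval(t, schedule$start_s)
  theta <- schedule_phase(schedule, t)
  env <- pmax(0, schedule$A_c[idx] * (1 + schedule$h[idx] * cos(theta)))

  out <- with_seed(seed, {
    car <- if (carrier == "breath")
      breath_carrier(t, schedule, jitter = breath_jitter)
    else cosine_carrier(t, schedule)
    y <- env * car$values
    if (noise_sd > 0) y <- y + stats::rnorm(n, sd = noise_sd)
    list(y = y, peaks = car$peak_times)
  })

  n_min <- floor(dur / 60)
  patho <- schedule$h >= h0 & schedule$f_m >= f_band[1] & schedule$f_m <= f_band[2]
  truth <- vapply(seq_len(n_min) - 1L, function(m) {
    lo <- 60 * m; hi <- lo + 60
    cov <- sum(pmax(0, pmin(schedule$end_s[patho], hi) -
                       pmax(schedule$start_s[patho], lo)))
    if (cov >= 30) "oscillating" else "normal"
  }, character(1))

  structure(list(signal = stats::ts(out$y, start = 0, frequency = fs),
                 fs = fs, schedule = schedule, carrier = carrier,
                 noise_sd = noise_sd, breath_jitter = breath_jitter,
                 seed = seed, breath_times = out$peaks,
                 truth_minutes = truth),
            class = "csr_recording")
}

#' @export
print.csr_recording <- function(x, ...) {
  cat(sprintf("Synthetic ventilation recording: %.0f s at %g Hz, %s carrier\n",
              ts_duration(x$signal), x$fs, x$carrier))
  cat(sprintf("  %d regimes, noise SD %g, jitter %g, %d/%d minutes oscillating\n",
              nrow(x$schedule), x$noise_sd, x$breath_jitter,
              sum(x$truth_minutes == "oscillating"), length(x$truth_minutes)))
  invisible(x)
}
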