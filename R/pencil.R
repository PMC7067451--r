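#' Matrix Pencil estimation of complex exponentials
#'
#' Estimates the poles and complex amplitudes of a sum of complex
#' exponentials from a uniformly sampled window using the Matrix Pencil
#' method: Hankel data matrices with pencil parameter
#' \code{L = round(pencil_ratio * N)}, a singular-value decomposition
#' truncated to the requested model order, poles from the generalized
#' eigenvalue problem of the pencil, and amplitudes from a linear
#' least-squares fit of the pole Vandermonde matrix to the data. The
#' modulated-envelope model is order 3: a DC term plus a conjugate pair
#' at the modulation frequency.
#'
#' @param window numeric vector (or \code{ts}) of uniformly sampled
#'   values; needs \code{length >= 3 * order}.
#' @param fs sampling rate in Hz (taken from the \code{ts} if omitted).
#' @param order number of exponentials to estimate (default 3).
#' @param pencil_ratio pencil parameter as a fraction of the window
#'   length (default 1/3, the standard noise-robust choice).
#' @return List with complex \code{poles}, complex \code{amplitudes},
#'   \code{freqs_hz} (signed, \code{Arg(pole) / (2 pi dt)}; damping is
#'   ignored), and \code{reduced} — \code{TRUE} when fewer than
#'   \code{order} singular values exceed 1e-8 of the largest and a
#'   reduced-order solution is returned.
#' @examples
#' t <- 0:119
#' env <- 1 + 0.5 * cos(2 * pi * 0.02 * t)
#' matrix_pencil(env, fs = 1)$freqs_hz
#' @export
matrix_pencil <- function(window, fs = NULL, order = 3, pencil_ratio = 1/3) {
  if (stats::is.ts(window)) {
    if (is.null(fs)) fs <- ts_fs(window)
    window <- as.numeric(window)
  }
  if (is.null(fs)) stop_invalid("fs is required for a plain numeric window")
  N <- length(window)
  if (N < 3 * order)
    stop_invalid("window too short: need at least 3 * order samples")
  if (any(!is.finite(window))) stop_invalid("window contains non-finite values")
  L <- round(pencil_ratio * N)
  L <- max(order, min(L, N - order - 1L))
  nr <- N - L
  Y <- matrix(0, nr, L + 1L)
  for (j in seq_len(L + 1L)) Y[, j] <- window[j:(j + nr - 1L)]
  Y1 <- Y[, seq_len(L), drop = FALSE]
  Y2 <- Y[, 1L + seq_len(L), drop = FALSE]
  sv <- svd(Y1)
  M <- min(order, sum(sv$d >= 1e-8 * sv$d[1] & sv$d > 0))
  if (M == 0L)
    return(list(poles = complex(0), amplitudes = complex(0),
                freqs_hz = numeric(0), reduced = TRUE))
  A <- diag(1 / sv$d[seq_len(M)], M) %*%
    t(sv$u[, seq_len(M), drop = FALSE]) %*% Y2 %*%
    sv$v[, seq_len(M), drop = FALSE]
  z <- eigen(A, only.values = TRUE)$values
  z <- as.complex(z)
  Z <- outer(0:(N - 1L), z, function(n, zz) zz^n)
  G <- Conj(t(Z)) %*% Z
  a <- tryCatch(solve(G, Conj(t(Z)) %*% window)[, 1L],
                error = function(e) rep(complex(real = NA), M))
  list(poles = z, amplitudes = a,
       freqs_hz = Arg(z) * fs / (2 * pi), reduced = M < order)
}

#' Envelope-model parameters from a Matrix Pencil fit
#'
#' Maps the pole/amplitude pairs of an order-3 fit back to the modulated
#' envelope parameters: the pole nearest 0 Hz is the DC term with
#' amplitude \code{A_c_hat}; the remaining conjugate pair gives
#' \code{f_m_hat} (mean absolute frequency) and the modulation index
#' \code{h_hat = (|a2| + |a3|) / |a1|}, which reduces to the symmetric
#' form \code{2 |a2| / |a1|} when the pair is exact. The estimate is
#' marked invalid when no pole lies within 5 mHz of DC or when the DC
#' amplitude falls below \code{amplitude_floor} (the index is a ratio and
#' diverges as the DC amplitude vanishes).
#'
#' @param mp output of \code{\link{matrix_pencil}}.
#' @param amplitude_floor minimum DC amplitude for a valid estimate.
#' @param t_center optional window centre time (seconds), stored in the
#'   result.
#' @return One-row data frame: \code{t_center}, \code{A_c_hat},
#'   \code{h_hat}, \code{f_m_hat}, \code{phi_hat}, \code{valid},
#'   \code{reduced}.
#' @export
window_params <- function(mp, amplitude_floor = 0, t_center = NA_real_) {
  out <- data.frame(t_center = t_center, A_c_hat = 0, h_hat = 0,
                    f_m_hat = 0, phi_hat = 0, valid = FALSE,
                    reduced = isTRUE(mp$reduced))
  f <- mp$freqs_hz
  a <- mp$amplitudes
  if (length(f) == 0L || anyNA(a)) return(out)
  dc <- which.min(abs(f))
  out$A_c_hat <- Mod(a[dc])
  rest <- setdiff(seq_along(f), dc)
  if (length(rest) >= 1L) {
    out$f_m_hat <- mean(abs(f[rest]))
    out$h_hat <- if (length(rest) >= 2L) sum(Mod(a[rest])) / Mod(a[dc])
                 else 2 * Mod(a[rest]) / Mod(a[dc])
    pos <- rest[which.max(f[rest])]
    out$phi_hat <- if (f[pos] >= 0) Arg(a[pos]) else -Arg(a[pos])
  }
  out$valid <- abs(f[dc]) <= 0.005 && out$A_c_hat >= amplitude_floor &&
    is.finite(out$h_hat)
  out
}

#' Sliding-window estimation of the modulation parameters
#'
#' Runs the Matrix Pencil fit over sliding windows of the reconstructed
#' envelope (default 2 min windows with 80\% overlap, i.e. a 24 s hop)
#' and collects per-window estimates of the carrier amplitude, modulation
#' index and modulation frequency. Windows are passed to the estimator
#' as-is (no detrending — the DC term is part of the model); a trailing
#' partial window is skipped.
#'
#' @param env envelope \code{ts} (e.g. from
#'   \code{\link{reconstruct_envelope}}).
#' @param window_s window length in seconds (default 120).
#' @param overlap fractional overlap between successive windows in
#'   [0, 1) (default 0.8).
#' @param order,pencil_ratio passed to \code{\link{matrix_pencil}}.
#' @param amplitude_floor_frac validity floor for the DC amplitude, as a
#'   fraction of the median envelope (default 0.1; the modulation index is a ratio and explodes when the fitted DC amplitude collapses).
#' @return A data frame of class \code{"csr_track"} with one row per
#'   window and attributes \code{window_s}, \code{hop_s}, \code{overlap}.
#' @examples
#' env <- stats::ts(1 + 0.5 * cos(2 * pi * 0.015 * (0:599)),
#'                  start = 0, frequency = 1)
#' tr <- sliding_estimate(env)
#' range(tr$h_hat)
#' @export
sliding_estimate <- function(env, window_s = 120, overlap = 0.8,
                             order = 3, pencil_ratio = 1/3,
                             amplitude_floor_frac = 0.1) {
  stopifnot(stats::is.ts(env))
  if (overlap < 0 || overlap >= 1) stop_invalid("overlap must be in [0, 1)")
  fs <- ts_fs(env)
  v <- as.numeric(env)
  n_w <- round(window_s * fs)
  hop <- max(1L, round(n_w * (1 - overlap)))
  empty <- structure(
    data.frame(t_center = numeric(0), A_c_hat = numeric(0),
               h_hat = numeric(0), f_m_hat = numeric(0),
               phi_hat = numeric(0), valid = logical(0),
               reduced = logical(0)),
    window_s = window_s, hop_s = hop / fs, overlap = overlap,
    class = c("csr_track", "data.frame"))
  if (length(v) < n_w) {
    warning("envelope shorter than one estimation window: empty track")
    return(empty)
  }
  floor_amp <- amplitude_floor_frac * stats::median(v)
  starts <- seq(1L, length(v) - n_w + 1L, by = hop)
  rows <- lapply(starts, function(s) {
    w <- v[s:(s + n_w - 1L)]
    tc <- ts_start(env) + (s - 1L) / fs + window_s / 2
    if (all(w == 0))
      return(data.frame(t_center = tc, A_c_hat = 0, h_hat = 0,
                        f_m_hat = 0, phi_hat = 0, valid = FALSE,
                        reduced = TRUE))
    mp <- matrix_pencil(w, fs = fs, order = order,
                        pencil_ratio = pencil_ratio)
    window_params(mp, amplitude_floor = floor_amp, t_center = tc)
  })
  out <- do.call(rbind, rows)
  attr(out, "window_s") <- window_s
  attr(out, "hop_s") <- hop / fs
  attr(out, "overlap") <- overlap
  class(out) <- c("csr_track", "data.frame")
  out
}
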