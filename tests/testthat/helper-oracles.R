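# Shared fixtures and independent oracles.

# Exhaustive optimal-partitioning DP for the penalized linear-fit
# segmentation; O(N^2), no pruning. Independent check for the package's
# pruned search.
dp_changepoints <- function(x, beta, minseg = 2L) {
  N <- length(x)
  cum1 <- c(0, cumsum(x)); cum2 <- c(0, cumsum(x^2))
  cumk <- c(0, cumsum(seq_along(x) * x))
  cost <- function(i, j) {
    n <- j - i + 1
    sy <- cum1[j + 1] - cum1[i]; syy <- cum2[j + 1] - cum2[i]
    sky <- cumk[j + 1] - cumk[i]
    sxx <- n * (n * n - 1) / 12
    sxy <- sky - 0.5 * (i + j) * sy
    max(0, (syy - sy * sy / n) - sxy * sxy / sxx)
  }
  F <- rep(Inf, N + 1); F[1] <- -beta; prev <- integer(N + 1)
  for (t in minseg:N) {
    taus <- c(0L, if (t >= 2 * minseg) seq(minseg, t - minseg))
    vals <- vapply(taus, function(tau) F[tau + 1] + cost(tau + 1, t) + beta,
                   numeric(1))
    F[t + 1] <- min(vals)
    prev[t + 1] <- taus[which.min(vals)]
  }
  cps <- integer(0); t <- N
  while (prev[t + 1] > 0) { cps <- c(prev[t + 1], cps); t <- prev[t + 1] }
  cps
}

# Greedy 1-1 matching of detected against true event times.
match_events <- function(detected, truth, tol = 0.5) {
  used <- logical(length(detected)); tp <- 0L
  for (tt in truth) {
    i <- which(!used & abs(detected - tt) <= tol)
    if (length(i)) { used[i[1]] <- TRUE; tp <- tp + 1L }
  }
  c(recall = tp / max(1L, length(truth)),
    precision = tp / max(1L, length(detected)))
}

# Fourier-quadrature oracle for the clipped-envelope modulation index:
# ratio of the fundamental to the DC Fourier coefficient of
# max(0, 1 + h cos(theta)).
clipped_h_oracle <- function(h) {
  c0 <- stats::integrate(function(th) pmax(0, 1 + h * cos(th)) / (2 * pi),
                         -pi, pi)$value
  c1 <- stats::integrate(function(th) pmax(0, 1 + h * cos(th)) * cos(th) / pi,
                         -pi, pi)$value
  c1 / c0
}

# One-regime breath-shaped recording plus its envelope extraction.
breath_fixture <- function(h, f_m = 0.01, duration = 300, noise = 0,
                           jitter = 0.1, seed = 1) {
  sched <- csr_schedule(0, duration, h = h, f_m = f_m)
  build_recording(sched, fs = 25, noise_sd = noise, breath_jitter = jitter,
                  carrier = "breath", seed = seed)
}
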