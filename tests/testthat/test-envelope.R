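test_that("exact slope breaks are recovered and constants stay unsegmented", {
  x <- c(seq(0, 1, length.out = 51)[-51], seq(1, 0, length.out = 51)[-51],
         seq(0, 2, length.out = 51)[-51], seq(2, 0, length.out = 51)[-51],
         seq(0, 1, length.out = 50))
  sig <- stats::ts(x, start = 0, frequency = 25)
  cps <- detect_change_points(sig, beta = 0.01)
  expect_equal(cps, c(50, 100, 150, 200) / 25, tolerance = 1 / 25)
  const <- stats::ts(rep(2, 200), start = 0, frequency = 25)
  expect_length(detect_change_points(const, beta = 0.5), 0)
})

test_that("triangular breath train segments at peaks and troughs", {
  fs <- 25
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  tri <- 2 * abs(2 * (t / 4 - floor(t / 4 + 0.5))) - 1  # period 4 s
  sig <- stats::ts(tri, start = 0, frequency = fs)
  cps <- detect_change_points(sig, beta = 0.05)
  vertices <- seq(2, 58, by = 2)  # alternating peaks/troughs
  expect_gte(length(cps), 28)
  for (cp in cps)
    expect_lte(min(abs(cp - vertices)), 1 / fs + 1e-9)
})

test_that("pruned search equals exhaustive dynamic programming", {
  set.seed(5)
  for (k in 1:3) {
    n <- sample(400:900, 1)
    x <- cumsum(rnorm(n))
    beta <- exp(runif(1, -1, 3))
    sig <- stats::ts(x, start = 0, frequency = 1)
    got <- detect_change_points(sig, beta = beta, min_seg_s = 5) + 1
    expect_equal(as.integer(got), dp_changepoints(x, beta, 5L))
  }
})

test_that("pruned search equals DP on a breathing signal", {
  rec <- breath_fixture(h = 0.5, duration = 70, seed = 3)
  v <- as.numeric(rec$signal)
  v <- v / stats::quantile(abs(v - stats::median(v)), 0.95, names = FALSE)
  sig <- stats::ts(v, start = 0, frequency = 25)
  beta <- 0.05 * 25
  got <- round(detect_change_points(sig, beta = beta) * 25) + 1
  expect_equal(as.integer(got), dp_changepoints(v, beta, 13L))
})

test_that("a clean sinusoid yields one peak per period at 4 s spacing", {
  fs <- 25
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  sig <- stats::ts(sin(2 * pi * 0.25 * t), start = 0, frequency = fs)
  cps <- detect_change_points(sig)
  seg <- extract_breaths(sig, cps)
  expect_equal(nrow(seg$peaks), 15)
  expect_equal(median(diff(seg$peaks$time_s)), 4, tolerance = 0.1)
})

test_that("near-flat drift sections are discarded as noise", {
  fs <- 25
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 0.25 * t)
  drift <- t >= 20 & t < 28
  x[drift] <- 1e-4 * (t[drift] - 20)  # drift section, slope 1e-4
  sig <- stats::ts(x, start = 0, frequency = fs)
  # boundaries at the sine vertices and the drift edges
  cps <- c(seq(1, 19, by = 2), 20, 28, seq(29, 39, by = 2))
  seg <- extract_breaths(sig, cps)
  expect_false(any(seg$peaks$time_s > 20 & seg$peaks$time_s < 28))
  expect_true(any(abs(seg$sections$slope) < 1e-3 & !seg$sections$kept))
  # breaths on both sides of the drift survive
  expect_gte(nrow(seg$peaks), 6)
})

test_that("sub-second spikes are not breaths", {
  fs <- 25
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 0.25 * t)
  spike <- t >= 20.0 & t < 20.5
  x[spike] <- x[spike] + 3 * sin(2 * pi * (t[spike] - 20) / 0.5)
  sig <- stats::ts(x, start = 0, frequency = fs)
  seg <- extract_breaths(sig, detect_change_points(sig))
  sp <- seg$peaks$time_s[seg$peaks$time_s > 19.9 & seg$peaks$time_s < 20.6]
  expect_length(sp, 0)
})

test_that("gap rule: spacing strictly greater than 3x the median", {
  g <- detect_gaps(c(0, 4, 8, 12, 16, 36, 40, 44, 48))
  expect_equal(nrow(g), 1)
  expect_equal(c(g$start_s, g$end_s), c(16, 36))
  expect_equal(nrow(detect_gaps(seq(0, 40, by = 4))), 0)
  # spacing exactly 3x the median is NOT a gap
  g2 <- detect_gaps(c(0, 4, 8, 12, 24, 28, 32))
  expect_equal(nrow(g2), 0)
  expect_warning(g3 <- detect_gaps(c(0, 4)), "fewer than 3")
  expect_equal(nrow(g3), 0)
})

test_that("envelope interpolates peaks, zeroes gaps, never goes negative", {
  seg <- structure(list(
    peaks = data.frame(time_s = c(0, 4, 8, 12, 16, 36, 40, 44),
                       amplitude = rep(1, 8)),
    gaps = data.frame(start_s = 16, end_s = 36),
    t_end = 48), class = "breath_seg")
  env <- reconstruct_envelope(seg, fs_env = 1, t_end = 48)
  t <- (seq_along(env) - 1)
  expect_true(all(env[t > 16 & t < 36] == 0))
  expect_true(all(env[t <= 16 | t >= 36] == 1))
  expect_true(all(env >= 0))
  seg$peaks <- seg$peaks[1, , drop = FALSE]
  expect_error(reconstruct_envelope(seg, 1, 48), "insufficient breaths")
})

test_that("reconstructed envelope tracks the analytic modulation at peaks", {
  y <- modulate(csr_params(A_c = 1, h = 0.5, f_m = 0.02), 300, fs = 25)
  ve <- ventilation_envelope(y)
  pk <- ve$segmentation$peaks
  pk <- pk[pk$time_s > 5 & pk$time_s < 295, ]
  model <- 1 + 0.5 * cos(2 * pi * 0.02 * pk$time_s)
  expect_lt(max(abs(pk$amplitude - model)), 0.05)
})

test_that("breath detection is accurate on jittered noiseless recordings", {
  for (h in c(0, 0.5)) {
    rec <- breath_fixture(h = h, duration = 300, noise = 0, jitter = 0.1,
                          seed = 11)
    ve <- ventilation_envelope(rec$signal)
    truth <- rec$breath_times[rec$breath_times > 2 & rec$breath_times < 298]
    m <- match_events(ve$segmentation$peaks$time_s, truth, tol = 0.5)
    expect_gte(m["recall"], 0.95)
    expect_gte(m["precision"], 0.95)
  }
})

test_that("breath filtering is idempotent on its own retained output", {
  rec <- breath_fixture(h = 0.5, duration = 120, jitter = 0.05, seed = 4)
  v <- as.numeric(rec$signal)
  v <- v / stats::quantile(abs(v - stats::median(v)), 0.95, names = FALSE)
  sig <- stats::ts(v, start = 0, frequency = 25)
  seg1 <- extract_breaths(sig, detect_change_points(sig))
  kept <- seg1$sections[seg1$sections$kept, ]
  bounds <- sort(unique(c(kept$start_s, kept$end_s)))
  bounds <- bounds[bounds > 0 & bounds < max(seg1$sections$end_s)]
  seg2 <- extract_breaths(sig, bounds)
  expect_equal(seg2$peaks$time_s, seg1$peaks$time_s)
  expect_equal(seg2$peaks$amplitude, seg1$peaks$amplitude)
})

test_that("envelope non-negativity and gap zeroing hold under fuzzing", {
  set.seed(99)
  for (k in 1:5) {
    h <- runif(1, 0, 1.6)
    rec <- breath_fixture(h = h, f_m = runif(1, 0.008, 0.03), duration = 240,
                          noise = runif(1, 0, 0.05), jitter = runif(1, 0, 0.1),
                          seed = 500 + k)
    ve <- ventilation_envelope(rec$signal)
    env <- as.numeric(ve$envelope)
    expect_true(all(env >= 0))
    g <- ve$segmentation$gaps
    if (nrow(g)) {
      t <- (seq_along(env) - 1)
      for (j in seq_len(nrow(g)))
        expect_true(all(env[t > g$start_s[j] & t < g$end_s[j]] == 0))
    }
  }
})
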