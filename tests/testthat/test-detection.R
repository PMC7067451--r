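mk_track <- function(h, fm, valid = TRUE, hop = 24, window = 120) {
  n <- length(h)
  structure(data.frame(t_center = window / 2 + hop * (seq_len(n) - 1),
                       A_c_hat = 1, h_hat = h, f_m_hat = fm,
                       phi_hat = 0, valid = rep_len(valid, n),
                       reduced = FALSE),
            window_s = window, hop_s = hop, overlap = 1 - hop / window,
            class = c("csr_track", "data.frame"))
}

test_that("a window is pathological only when both h and f_m are", {
  tr <- mk_track(h = c(0.3, 0.3, 0.05, 0.3), fm = c(0.015, 0.05, 0.015, 0.015),
                 valid = c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(flag_windows(tr), c(TRUE, FALSE, FALSE, FALSE))
  # inclusive boundaries
  tr2 <- mk_track(h = c(0.12, 0.12), fm = c(0.008, 0.030))
  expect_identical(flag_windows(tr2), c(TRUE, TRUE))
})

test_that("flag runs become zones with one-minute persistence", {
  tr <- mk_track(h = rep(c(0.5, 0), c(5, 5)), fm = 0.015)
  z <- build_zones(tr, flag_windows(tr))
  expect_equal(nrow(z), 1)
  expect_equal(z$end_s - z$start_s, 120 + 4 * 24)
  expect_equal(z$mean_h, 0.5)
  # a single isolated flagged window still spans >= 60 s
  tr2 <- mk_track(h = c(0, 0.5, 0, 0, 0), fm = 0.015)
  z2 <- build_zones(tr2, flag_windows(tr2))
  expect_equal(nrow(z2), 1)
  expect_equal(z2$end_s - z2$start_s, 120)
  # a short run under a hypothetical 10 s window is discarded
  tr3 <- mk_track(h = c(0, 0.5, 0.5, 0), fm = 0.015, hop = 10, window = 10)
  expect_equal(nrow(build_zones(tr3, flag_windows(tr3))), 0)
})

test_that("zone construction matches brute-force run enumeration", {
  set.seed(17)
  for (k in 1:10) {
    n <- 40
    flags <- runif(n) < 0.4
    tr <- mk_track(h = ifelse(flags, 0.6, 0.01), fm = 0.015)
    z <- build_zones(tr, flag_windows(tr))
    # oracle: enumerate maximal runs directly on the flag vector
    r <- rle(flags)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    runs <- data.frame(i = starts[r$values], j = ends[r$values])
    runs$start <- tr$t_center[runs$i] - 60
    runs$end <- tr$t_center[runs$j] + 60
    runs <- runs[runs$end - runs$start >= 60, ]
    # merge runs separated by < hop (oracle mirror of the rule)
    if (nrow(runs) > 1) {
      keep <- list(runs[1, ])
      for (q in 2:nrow(runs)) {
        last <- keep[[length(keep)]]
        if (runs$start[q] - last$end < 24) {
          last$end <- runs$end[q]; last$j <- runs$j[q]
          keep[[length(keep)]] <- last
        } else keep[[length(keep) + 1]] <- runs[q, ]
      }
      runs <- do.call(rbind, keep)
    }
    expect_equal(z$start_s, runs$start)
    expect_equal(z$end_s, runs$end)
    expect_true(all(diff(z$start_s) > 0))
    expect_true(all(z$end_s - z$start_s >= 60))
    if (nrow(z) > 1) expect_true(all(z$start_s[-1] >= z$end_s[-nrow(z)]))
  }
})

test_that("three-class rule follows total, episode and depth conditions", {
  z1 <- data.frame(start_s = c(0, 500), end_s = c(480, 740),
                   mean_h = c(1.3, 1.0), max_h = c(1.5, 1.2))
  expect_equal(classify_patient(z1)$label, "CSR_CSA")
  z2 <- data.frame(start_s = c(0, 500), end_s = c(420, 800),
                   mean_h = c(0.5, 0.5), max_h = c(0.6, 0.6))
  expect_equal(classify_patient(z2)$label, "PB")
  z3 <- data.frame(start_s = 0, end_s = 240, mean_h = 1.4, max_h = 1.5)
  expect_equal(classify_patient(z3)$label, "NON_CSR")
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      mean_h = numeric(0), max_h = numeric(0))
  d <- classify_patient(empty)
  expect_equal(d$label, "NON_CSR")
  expect_equal(d$total_oscillation_s, 0)
})

test_that("per-hour normalisation rescales the total-duration rule", {
  z <- data.frame(start_s = 0, end_s = 400, mean_h = 0.5, max_h = 0.6)
  expect_equal(classify_patient(z)$label, "NON_CSR")
  expect_equal(classify_patient(z, per_hour = TRUE, duration_s = 1800,
                                episode_min_s = 360)$label, "PB")
  expect_error(classify_patient(z, per_hour = TRUE), "duration_s")
})

test_that("flagged time is monotone in the modulation depth", {
  total_flagged <- vapply(c(0, 0.3, 0.6, 1.0, 1.5), function(h) {
    sched <- if (h == 0) csr_schedule(0, 900, h = 0, f_m = 0.012)
      else csr_schedule(c(0, 180, 780), c(180, 780, 900), h = c(0, h, 0),
                        f_m = 0.012)
    rec <- build_recording(sched, fs = 25, noise_sd = 0.02,
                           breath_jitter = 0.05, carrier = "breath", seed = 77)
    fit <- csr_demod(rec)
    sum(fit$flags) * attr(fit$track, "hop_s")
  }, numeric(1))
  expect_true(all(diff(total_flagged) >= 0))
})

test_that("lowering the threshold never removes a flag", {
  rec <- build_recording(csr_schedule(c(0, 300), c(300, 900), h = c(0, 0.5),
                                      f_m = 0.015),
                         fs = 25, noise_sd = 0.05, breath_jitter = 0.05,
                         carrier = "breath", seed = 13)
  fit <- csr_demod(rec)
  f_low <- flag_windows(fit$track, h0 = 0.05)
  f_mid <- flag_windows(fit$track, h0 = 0.12)
  f_high <- flag_windows(fit$track, h0 = 0.3)
  expect_true(all(f_mid <= f_low))
  expect_true(all(f_high <= f_mid))
})
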