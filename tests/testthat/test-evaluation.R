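test_that("zone coverage maps to minutes by the 30 s majority rule", {
  z <- data.frame(start_s = 90, end_s = 300, mean_h = 0.5, max_h = 0.6)
  expect_identical(minutes_from_zones(z, 6),
                   c("normal", rep("oscillation", 4), "normal"))
  none <- data.frame(start_s = numeric(0), end_s = numeric(0),
                     mean_h = numeric(0), max_h = numeric(0))
  expect_true(all(minutes_from_zones(none, 5) == "normal"))
  z2 <- data.frame(start_s = 60, end_s = 120, mean_h = 0.5, max_h = 0.6)
  expect_identical(which(minutes_from_zones(z2, 4) == "oscillation"), 2L)
  # interval-overlap oracle on a random zone set
  set.seed(8)
  zs <- data.frame(start_s = sort(runif(3, 0, 500)))
  zs$end_s <- zs$start_s + runif(3, 10, 100)
  zs <- zs[c(TRUE, zs$start_s[-1] > zs$end_s[-3]), ]
  got <- minutes_from_zones(zs, 10)
  for (m in 0:9) {
    cov <- sum(pmax(0, pmin(zs$end_s, 60 * m + 60) - pmax(zs$start_s, 60 * m)))
    expect_identical(got[m + 1] == "oscillation", cov >= 30)
  }
})

test_that("sensitivity and both specificity variants follow the counts", {
  pred <- c(rep("oscillation", 45), rep("normal", 6), rep("normal", 100))
  ref <- c(rep("csr_pb", 40), rep("normal", 5), rep("csr_pb", 6),
           rep("normal", 100))
  p <- se_sp(pred, ref)
  expect_equal(p$TP, 40); expect_equal(p$FP, 5); expect_equal(p$FN, 6)
  expect_equal(p$se, 100 * 40 / 46, tolerance = 1e-10)        # 86.96
  expect_equal(p$sp_as_printed, 100 * 40 / 45, tolerance = 1e-10)  # 88.89
  expect_equal(p$specificity_conventional, 100 * 100 / 105, tolerance = 1e-10)
  # perfect prediction
  perfect <- se_sp(c("oscillation", "normal"), c("csr_pb", "normal"))
  expect_equal(perfect$se, 100)
  expect_equal(perfect$sp_as_printed, 100)
  # all-normal prediction
  expect_equal(se_sp(rep("normal", 3), c("csr_pb", "normal", "normal"))$se, 0)
  expect_error(se_sp("normal", c("normal", "normal")), "length")
})

test_that("erratic minutes are excluded from the binary scores", {
  pred <- c("oscillation", "oscillation", "normal", "normal")
  ref <- c("csr_pb", "erratic", "erratic", "normal")
  p <- se_sp(pred, ref)
  expect_equal(p$n_erratic_excluded, 2)
  expect_equal(p$TP + p$FP + p$FN + p$TN, 2)
  expect_equal(p$se, 100)
})

test_that("scores are invariant to minute order and monotone in added TPs", {
  set.seed(21)
  pred <- sample(c("oscillation", "normal"), 60, replace = TRUE)
  ref <- sample(c("csr_pb", "normal", "erratic"), 60, replace = TRUE,
                prob = c(0.4, 0.5, 0.1))
  p1 <- se_sp(pred, ref)
  o <- sample(60)
  p2 <- se_sp(pred[o], ref[o])
  expect_equal(p1[c("TP", "FP", "FN", "TN", "se")], p2[c("TP", "FP", "FN", "TN", "se")])
  p3 <- se_sp(c(pred, "oscillation"), c(ref, "csr_pb"))
  expect_gte(p3$se, p1$se)
})

test_that("ROC selection returns the smallest Youden-optimal threshold", {
  mk <- function(h) structure(
    data.frame(t_center = seq(60, 60 + 24 * 24, by = 24), A_c_hat = 1,
               h_hat = h, f_m_hat = 0.015, phi_hat = 0, valid = TRUE,
               reduced = FALSE),
    window_s = 120, hop_s = 24, overlap = 0.8,
    class = c("csr_track", "data.frame"))
  tracks <- list(mk(0.45), mk(0.45), mk(0.02), mk(0.02))
  refs <- list(rep("csr_pb", 11), rep("csr_pb", 11),
               rep("normal", 11), rep("normal", 11))
  r <- roc_select_threshold(tracks, refs, grid = seq(0.05, 0.5, by = 0.05))
  # perfect separation: every threshold in (0.02, 0.45] is optimal;
  # the smallest grid value above the negatives wins
  expect_equal(r$h0, 0.05)
  expect_equal(max(r$roc$youden), 100)
  expect_error(roc_select_threshold(tracks[1:2], refs[1:2]), "degenerate")
})

test_that("diagnosis confusion matrix tallies predicted vs reference", {
  pred <- c(rep("CSR_CSA", 4), "PB", rep("NON_CSR", 10))
  ref <- pred
  cm <- confusion_matrix(pred, ref)
  expect_equal(unname(diag(cm)), c(4, 1, 10))
  expect_equal(sum(cm), 15)
  # all-non-CSR prediction: bottom row equals the column sums
  cm2 <- confusion_matrix(rep("NON_CSR", 15), ref)
  expect_equal(unname(cm2["NON_CSR", ]), unname(colSums(cm)))
  # mixed errors vs a hand tally
  cm3 <- confusion_matrix(c("CSR_CSA", "PB", "PB", "NON_CSR"),
                          c("CSR_CSA", "CSR_CSA", "PB", "PB"))
  expect_equal(unname(cm3["PB", "CSR_CSA"]), 1)
  expect_equal(unname(cm3["NON_CSR", "PB"]), 1)
  expect_error(confusion_matrix("bogus", "PB"), "unknown")
})
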