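#' Per-minute predictions from oscillation zones
#'
#' Minute \code{m} (the half-open interval \code{[60m, 60(m+1))}) is
#' predicted "oscillation" when zones cover at least \code{min_cover_s}
#' of it (majority rule, default 30 s), otherwise "normal".
#'
#' @param zones zone data frame from \code{\link{build_zones}}.
#' @param n_minutes number of minutes in the recording, >= 1.
#' @param min_cover_s minimum covered seconds per positive minute.
#' @return Character vector of length \code{n_minutes} with values
#'   \code{"oscillation"} / \code{"normal"}.
#' @examples
#' z <- data.frame(start_s = 90, end_s = 300, mean_h = 0.5, max_h = 0.6)
#' minutes_from_zones(z, 6)
#' @export
minutes_from_zones <- function(zones, n_minutes, min_cover_s = 30) {
  if (!is.numeric(n_minutes) || n_minutes < 1)
    stop_invalid("n_minutes must be >= 1")
  vapply(seq_len(n_minutes) - 1L, function(m) {
    lo <- 60 * m; hi <- lo + 60
    cov <- if (nrow(zones)) sum(pmax(0, pmin(zones$end_s, hi) -
                                        pmax(zones$start_s, lo))) else 0
    if (cov >= min_cover_s) "oscillation" else "normal"
  }, character(1))
}

# Normalise reference minute labels; simulator truth uses "oscillating".
norm_ref <- function(ref) {
  ref <- as.character(ref)
  ref[ref %in% c("oscillating", "csr_pb", "CSR_or_PB")] <- "csr_pb"
  ref[ref %in% c("normal", "no_abnormal")] <- "normal"
  ref[ref %in% c("erratic", "erratic_possible_PB")] <- "erratic"
  bad <- setdiff(unique(ref), c("csr_pb", "normal", "erratic"))
  if (length(bad)) stop_invalid("unknown reference labels: ",
                                paste(bad, collapse = ", "))
  ref
}

#' Minute-level sensitivity and specificity
#'
#' Scores per-minute predictions against reference annotations on the
#' binary task (CSR/PB vs no abnormal pattern); minutes annotated
#' "erratic" (possible periodic breathing the annotator could not
#' confirm) are excluded from the counts and tallied separately. Two
#' specificity variants are reported: \code{sp_as_printed = TP/(TP+FP)}
#' (the positive predictive value, as printed in the source formulas)
#' and the conventional \code{specificity_conventional = TN/(TN+FP)}.
#'
#' @param pred character vector of per-minute predictions
#'   (\code{"oscillation"} / \code{"normal"}).
#' @param ref reference labels per minute: \code{"csr_pb"},
#'   \code{"normal"}, \code{"erratic"} (the simulator's
#'   \code{"oscillating"} is accepted as \code{"csr_pb"}).
#' @return Object of class \code{"csr_performance"}: counts TP/FP/FN/TN,
#'   \code{se}, \code{sp_as_printed}, \code{specificity_conventional}
#'   (all percent), and \code{n_erratic_excluded}.
#' @export
se_sp <- function(pred, ref) {
  if (length(pred) != length(ref))
    stop_invalid("prediction and reference tracks differ in length")
  ref <- norm_ref(ref)
  keep <- ref != "erratic"
  p <- pred[keep] == "oscillation"
  r <- ref[keep] == "csr_pb"
  tp <- sum(p & r); fp <- sum(p & !r); fn <- sum(!p & r); tn <- sum(!p & !r)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn,
                 se = pct(tp, tp + fn),
                 sp_as_printed = pct(tp, tp + fp),
                 specificity_conventional = pct(tn, tn + fp),
                 n_erratic_excluded = sum(!keep)),
            class = "csr_performance")
}

#' @export
print.csr_performance <- function(x, ...) {
  cat(sprintf("Minute-level performance (%d minutes scored, %d erratic excluded)\n",
              x$TP + x$FP + x$FN + x$TN, x$n_erratic_excluded))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$TP, x$FP, x$FN, x$TN))
  cat(sprintf("  Se %.2f%%  Sp (as printed, = PPV) %.2f%%  Sp (conventional) %.2f%%\n",
              x$se, x$sp_as_printed, x$specificity_conventional))
  invisible(x)
}

#' ROC selection of the modulation-index threshold
#'
#' Sweeps candidate thresholds \code{h0} over a grid; at each value the
#' per-minute predictions of every recording are recomputed from its
#' estimate track (flags, zones, minutes) and pooled sensitivity and
#' conventional specificity are evaluated against the references. The
#' returned threshold maximises the Youden index
#' \code{Se + Sp - 100}; among ties the smallest grid value is returned.
#'
#' @param tracks list of \code{"csr_track"} objects, one per recording.
#' @param refs list of per-minute reference label vectors, aligned with
#'   \code{tracks}.
#' @param grid candidate thresholds (default \code{seq(0.02, 0.5, 0.02)}).
#' @param f_band,min_zone_s,min_cover_s forwarded to
#'   \code{\link{flag_windows}}, \code{\link{build_zones}},
#'   \code{\link{minutes_from_zones}}.
#' @return List with \code{h0} (chosen threshold) and \code{roc}, a data
#'   frame of grid values with Se, both specificity variants and Youden.
#' @export
roc_select_threshold <- function(tracks, refs, grid = seq(0.02, 0.5, by = 0.02),
                                 f_band = c(0.008, 0.030), min_zone_s = 60,
                                 min_cover_s = 30) {
  stopifnot(length(tracks) == length(refs), length(tracks) >= 1)
  all_ref <- norm_ref(unlist(refs))
  scored <- all_ref[all_ref != "erratic"]
  if (length(unique(scored)) < 2)
    stop_invalid("degenerate references: need both positive and negative minutes")
  rows <- lapply(grid, function(h0) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(tracks)) {
      zones <- build_zones(tracks[[i]],
                           flag_windows(tracks[[i]], h0 = h0, f_band = f_band),
                           min_zone_s = min_zone_s)
      pred <- minutes_from_zones(zones, length(refs[[i]]), min_cover_s)
      perf <- se_sp(pred, refs[[i]])
      tp <- tp + perf$TP; fp <- fp + perf$FP
      fn <- fn + perf$FN; tn <- tn + perf$TN
    }
    data.frame(h0 = h0, se = 100 * tp / max(1, tp + fn),
               specificity_conventional = 100 * tn / max(1, tn + fp),
               sp_as_printed = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_)
  })
  roc <- do.call(rbind, rows)
  roc$youden <- roc$se + roc$specificity_conventional - 100
  best <- roc$h0[which(roc$youden >= max(roc$youden) - 1e-9)]
  list(h0 = min(best), roc = roc)
}

#' Confusion matrix of recording-level diagnoses
#'
#' Tallies predicted against reference three-class labels; rows are the
#' predicted class, columns the reference class, and the counts sum to
#' the number of recordings. A perfect classifier fills only the
#' diagonal.
#'
#' @param pred,ref character vectors of labels in
#'   \code{c("CSR_CSA", "PB", "NON_CSR")} (one per recording).
#' @return 3 x 3 integer matrix (predicted x reference).
#' @export
confusion_matrix <- function(pred, ref) {
  lev <- c("CSR_CSA", "PB", "NON_CSR")
  if (length(pred) != length(ref))
    stop_invalid("pred and ref must cover the same recordings")
  bad <- setdiff(unique(c(pred, ref)), lev)
  if (length(bad)) stop_invalid("unknown labels: ", paste(bad, collapse = ", "))
  as.matrix(table(factor(pred, lev), factor(ref, lev)))
}
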