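#' Flag pathological estimation windows
#'
#' A window is pathological when its estimate is valid, the modulation
#' index reaches the oscillation threshold (\code{h_hat >= h0}) and the
#' modulation frequency lies inside the Cheyne-Stokes band
#' (\code{f_band}, inclusive bounds). Both conditions are required: a
#' deep modulation outside the band, or an in-band frequency with a flat
#' envelope, is not an oscillation zone.
#'
#' @param track a \code{"csr_track"} from \code{\link{sliding_estimate}}.
#' @param h0 modulation-index threshold (default 0.12, selected in the
#'   source study by ROC analysis against expert annotations).
#' @param f_band pathological frequency band in Hz (default 8--30 mHz).
#' @return Logical vector, one flag per window.
#' @export
flag_windows <- function(track, h0 = 0.12, f_band = c(0.008, 0.030)) {
  stopifnot(inherits(track, "csr_track") || is.data.frame(track))
  track$valid & track$h_hat >= h0 &
    track$f_m_hat >= f_band[1] & track$f_m_hat <= f_band[2]
}

#' Convert flagged windows into oscillation zones
#'
#' Maximal runs of flagged windows become time intervals
#' \code{[first window start, last window end)}; runs spanning less than
#' \code{min_zone_s} are discarded (the one-minute persistence rule that
#' suppresses short false positives), and zones separated by less than
#' one hop are merged. Each zone carries the mean and maximum
#' modulation index of its windows.
#'
#' @param track a \code{"csr_track"}.
#' @param flags logical vector aligned with \code{track} (defaults to
#'   \code{\link{flag_windows}} with standard thresholds).
#' @param min_zone_s minimum zone span in seconds (default 60).
#' @return Data frame with columns \code{start_s}, \code{end_s},
#'   \code{mean_h}, \code{max_h}; zones are disjoint and sorted.
#' @export
build_zones <- function(track, flags = flag_windows(track), min_zone_s = 60) {
  stopifnot(length(flags) == nrow(track))
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      mean_h = numeric(0), max_h = numeric(0))
  if (!any(flags)) return(empty)
  w <- attr(track, "window_s") %||% 120
  hop <- attr(track, "hop_s") %||% (w * 0.2)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zones <- empty
  for (k in which(r$values)) {
    i <- starts[k]; j <- ends[k]
    z_start <- track$t_center[i] - w / 2
    z_end <- track$t_center[j] + w / 2
    if (z_end - z_start < min_zone_s) next
    zones <- rbind(zones, data.frame(
      start_s = z_start, end_s = z_end,
      mean_h = mean(track$h_hat[i:j]), max_h = max(track$h_hat[i:j])))
  }
  if (nrow(zones) <= 1) return(zones)
  # merge zones separated by less than one hop
  merged <- zones[1, ]
  for (k in 2:nrow(zones)) {
    last <- nrow(merged)
    if (zones$start_s[k] - merged$end_s[last] < hop) {
      d1 <- merged$end_s[last] - merged$start_s[last]
      d2 <- zones$end_s[k] - zones$start_s[k]
      merged$mean_h[last] <- (merged$mean_h[last] * d1 + zones$mean_h[k] * d2) /
        (d1 + d2)
      merged$max_h[last] <- max(merged$max_h[last], zones$max_h[k])
      merged$end_s[last] <- zones$end_s[k]
    } else {
      merged <- rbind(merged, zones[k, ])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Three-class diagnosis from oscillation zones
#'
#' Applies the final classification rule: with \code{T} the total zone
#' duration, \code{E} the longest single zone and \code{h_bar} the
#' duration-weighted mean modulation index over zones, a recording is
#' \itemize{
#'   \item \code{CSR_CSA} when \code{T > 600 s}, \code{E >= 360 s} and
#'     \code{h_bar > 1} (oscillation deep enough to clip, i.e. apneas);
#'   \item \code{PB} (periodic breathing, the early stage) when the
#'     duration conditions hold but \code{h_bar <= 1}, with \code{h_bar}
#'     grading the degree of certainty;
#'   \item \code{NON_CSR} otherwise.
#' }
#' For overnight recordings \code{per_hour = TRUE} rescales the total
#' oscillation time to a per-hour rate before applying
#' \code{total_min_s}.
#'
#' @param zones zone data frame from \code{\link{build_zones}}.
#' @param total_min_s minimum total oscillation for a pathological label
#'   (default 600 s = 10 min).
#' @param episode_min_s minimum longest single episode (default 360 s).
#' @param h_apnea modulation-index boundary between PB and CSR with
#'   apneas (default 1).
#' @param per_hour logical; normalise total oscillation per hour of
#'   recording (requires \code{duration_s}).
#' @param duration_s recording duration, only needed for
#'   \code{per_hour}.
#' @return An object of class \code{"csr_diagnosis"}: list with
#'   \code{label}, \code{total_oscillation_s}, \code{longest_episode_s},
#'   \code{h_bar}, \code{n_zones}.
#' @export
classify_patient <- function(zones, total_min_s = 600, episode_min_s = 360,
                             h_apnea = 1.0, per_hour = FALSE,
                             duration_s = NULL) {
  durs <- zones$end_s - zones$start_s
  total <- sum(durs)
  longest <- if (length(durs)) max(durs) else 0
  h_bar <- if (length(durs)) stats::weighted.mean(zones$mean_h, durs) else NA_real_
  total_eff <- total
  if (per_hour) {
    if (is.null(duration_s)) stop_invalid("per_hour needs duration_s")
    total_eff <- total * 3600 / duration_s
  }
  label <- if (total_eff > total_min_s && longest >= episode_min_s) {
    if (isTRUE(h_bar > h_apnea)) "CSR_CSA" else "PB"
  } else "NON_CSR"
  structure(list(label = label, total_oscillation_s = total,
                 longest_episode_s = longest, h_bar = h_bar,
                 n_zones = length(durs)),
            class = "csr_diagnosis")
}

#' @export
print.csr_diagnosis <- function(x, ...) {
  cat(sprintf("Diagnosis: %s\n", x$label))
  cat(sprintf("  oscillation: %.0f s total, longest episode %.0f s, %d zone(s)\n",
              x$total_oscillation_s, x$longest_episode_s, x$n_zones))
  if (!is.na(x$h_bar))
    cat(sprintf("  mean modulation index over zones: %.2f\n", x$h_bar))
  invisible(x)
}
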