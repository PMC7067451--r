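#' Pipeline configuration
#'
#' Collects every tunable of the detection pipeline with its default.
#' Unknown names are rejected and every value is validated against its
#' documented range.
#'
#' @param fs_env envelope resampling rate, Hz (> 0).
#' @param detrend_s running-median baseline window in seconds (0 disables).
#' @param beta change-point penalty; \code{NULL} = automatic scaling (see
#'   \code{\link{detect_change_points}}).
#' @param min_seg_s minimum change-point segment duration, seconds.
#' @param slope_min,min_section_s,gap_factor breath filtering parameters
#'   (see \code{\link{extract_breaths}}, \code{\link{detect_gaps}}).
#' @param window_s,overlap,order,pencil_ratio,amplitude_floor_frac
#'   sliding estimation parameters (see \code{\link{sliding_estimate}}).
#' @param h0,f_band oscillation thresholds (see
#'   \code{\link{flag_windows}}).
#' @param min_zone_s,min_cover_s zone persistence and minute coverage.
#' @param total_min_s,episode_min_s,h_apnea,per_hour classification rule
#'   (see \code{\link{classify_patient}}).
#' @param seed optional integer seed recorded with the configuration.
#' @return A validated list of class \code{"csr_control"}.
#' @export
csr_control <- function(fs_env = 1.0, detrend_s = 30, beta = NULL,
                        min_seg_s = 0.5, slope_min = 1e-3,
                        min_section_s = 1.0, gap_factor = 3.0,
                        window_s = 120, overlap = 0.8, order = 3,
                        pencil_ratio = 1/3, amplitude_floor_frac = 0.1,
                        h0 = 0.12, f_band = c(0.008, 0.030),
                        min_zone_s = 60, min_cover_s = 30,
                        total_min_s = 600, episode_min_s = 360,
                        h_apnea = 1.0, per_hour = FALSE, seed = NULL) {
  ctl <- list(fs_env = fs_env, detrend_s = detrend_s, beta = beta,
              min_seg_s = min_seg_s, slope_min = slope_min,
              min_section_s = min_section_s, gap_factor = gap_factor,
              window_s = window_s, overlap = overlap, order = order,
              pencil_ratio = pencil_ratio,
              amplitude_floor_frac = amplitude_floor_frac, h0 = h0,
              f_band = f_band, min_zone_s = min_zone_s,
              min_cover_s = min_cover_s, total_min_s = total_min_s,
              episode_min_s = episode_min_s, h_apnea = h_apnea,
              per_hour = per_hour, seed = seed)
  chk <- function(ok, msg) if (!ok) stop_invalid("csr_control: ", msg)
  chk(fs_env > 0, "fs_env must be > 0")
  chk(detrend_s >= 0, "detrend_s must be >= 0")
  chk(is.null(beta) || beta >= 0, "beta must be >= 0 or NULL")
  chk(min_seg_s > 0, "min_seg_s must be > 0")
  chk(slope_min >= 0, "slope_min must be >= 0")
  chk(min_section_s >= 0, "min_section_s must be >= 0")
  chk(gap_factor > 0, "gap_factor must be > 0")
  chk(window_s > 0, "window_s must be > 0")
  chk(overlap >= 0 && overlap < 1, "overlap must be in [0, 1)")
  chk(order >= 1, "order must be >= 1")
  chk(pencil_ratio > 0 && pencil_ratio < 1, "pencil_ratio must be in (0, 1)")
  chk(amplitude_floor_frac >= 0, "amplitude_floor_frac must be >= 0")
  chk(h0 >= 0, "h0 must be >= 0")
  chk(length(f_band) == 2 && f_band[1] >= 0 && f_band[2] > f_band[1],
      "f_band must be increasing and non-negative")
  chk(min_zone_s >= 0, "min_zone_s must be >= 0")
  chk(min_cover_s >= 0 && min_cover_s <= 60, "min_cover_s must be in [0, 60]")
  chk(total_min_s >= 0, "total_min_s must be >= 0")
  chk(episode_min_s >= 0, "episode_min_s must be >= 0")
  chk(h_apnea > 0, "h_apnea must be > 0")
  chk(is.logical(per_hour), "per_hour must be logical")
  structure(ctl, class = "csr_control")
}

#' Read or write a pipeline configuration as YAML
#'
#' \code{read_control} loads a YAML file of overrides onto the built-in
#' defaults (unknown keys are rejected by \code{\link{csr_control}});
#' \code{write_control} dumps a configuration so that reading it back
#' reproduces it exactly.
#'
#' @param path YAML file path.
#' @param control a \code{"csr_control"} object.
#' @return \code{read_control} returns a \code{"csr_control"};
#'   \code{write_control} returns \code{path} invisibly.
#' @export
read_control <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.null(vals$f_band)) vals$f_band <- as.numeric(vals$f_band)
  do.call(csr_control, vals)
}

#' @rdname read_control
#' @export
write_control <- function(control, path) {
  stopifnot(inherits(control, "csr_control"))
  yaml::write_yaml(unclass(control), path, precision = 15)
  invisible(path)
}

#' Read a ventilation signal
#'
#' Reads a uniformly sampled single-channel signal either from a
#' two-column CSV (\code{time_s,value}, header mandatory, comma
#' separator) or from one named channel of an EDF file. CSV timestamps
#' are checked for uniformity within 1 microsecond.
#'
#' @param path input file.
#' @param format \code{"csv"} or \code{"edf"} (guessed from the file
#'   extension by default).
#' @param channel EDF channel label (required for EDF files with more
#'   than one channel).
#' @return A \code{ts} with \code{frequency} = sampling rate in Hz.
#' @export
read_signal <- function(path, format = c("auto", "csv", "edf"),
                        channel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") return(read_signal_edf(path, channel))
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop_invalid("CSV must have columns time_s,value")
  tm <- d[[1]]; v <- d[[2]]
  if (length(tm) < 2) stop_invalid("signal too short")
  dt <- diff(tm)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6)
    stop_invalid("non-uniform sampling in CSV time column")
  stats::ts(v, start = tm[1], frequency = 1 / stats::median(dt))
}

#' Write a signal as two-column CSV
#'
#' @param x a \code{ts} in seconds.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_signal <- function(x, path) {
  stopifnot(stats::is.ts(x))
  utils::write.csv(data.frame(time_s = ts_times(x), value = as.numeric(x)),
                   path, row.names = FALSE)
  invisible(path)
}

# ---- minimal EDF support (16-bit standard EDF) -------------------------
# One data record holding the whole signal per channel keeps the writer
# trivial; the reader handles arbitrary record layouts.

pad <- function(s, n) {
  s <- substr(as.character(s), 1L, n)
  formatC(s, width = -n)
}

# numeric header field: the most precise decimal that fits 8 ASCII bytes
num8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= 8) return(s)
  }
  formatC(x, format = "e", digits = 0)
}

#' Write a single-channel EDF file
#'
#' Minimal standard-EDF writer (16-bit samples, one data record). The
#' physical range is taken from the data.
#'
#' @param x a \code{ts} in seconds.
#' @param path output file.
#' @param channel channel label (default "Flow").
#' @param phys_dim physical dimension string (default "au").
#' @return \code{path}, invisibly.
#' @export
write_signal_edf <- function(x, path, channel = "Flow", phys_dim = "au") {
  stopifnot(stats::is.ts(x))
  v <- as.numeric(x)
  fs <- ts_fs(x)
  n <- length(v)
  pmin_ <- min(v); pmax_ <- max(v)
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1
  # quantise against the bounds as written (8-char ASCII fields)
  pmin_ <- as.numeric(num8(pmin_)); pmax_ <- as.numeric(num8(pmax_))
  dmin <- -32768; dmax <- 32767
  dig <- round((v - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  rec_dur <- n / fs
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("", 80), pad("", 80),
                pad("01.01.00", 8), pad("00.00.00", 8),
                pad(256 + 256, 8), pad("", 44), pad(1, 8),
                pad(num8(rec_dur), 8), pad(1, 4))
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  sig <- paste0(pad(channel, 16), pad("", 80), pad(phys_dim, 8),
                pad(num8(pmin_), 8),
                pad(num8(pmax_), 8),
                pad(dmin, 8), pad(dmax, 8), pad("", 80), pad(n, 8),
                pad("", 32))
  writeChar(sig, con, nchars = nchar(sig), eos = NULL)
  writeBin(as.integer(dig), con, size = 2, endian = "little")
  invisible(path)
}

read_signal_edf <- function(path, channel = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header length (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop_invalid("unreadable EDF header")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)          # prefiltering
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  if (is.null(channel)) {
    if (ns > 1) stop_invalid("EDF has ", ns,
                             " channels; specify `channel` by label")
    ci <- 1L
  } else {
    ci <- match(channel, labels)
    if (is.na(ci)) stop_invalid("channel not found in EDF: ", channel,
                                " (available: ", paste(labels, collapse = ", "), ")")
  }
  chunks <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, integer(), n = nsamp[i], size = 2,
                     endian = "little", signed = TRUE)
      if (i == ci) chunks[[r]] <- raw
    }
  }
  dig <- unlist(chunks)
  v <- (dig - dmin[ci]) / (dmax[ci] - dmin[ci]) * (pmax_[ci] - pmin_[ci]) + pmin_[ci]
  fs <- nsamp[ci] / rec_dur
  stats::ts(v, start = 0, frequency = fs)
}

#' Read per-minute annotations
#'
#' Reads a CSV with columns \code{minute_index,label}; labels may be
#' \code{csr_pb}/\code{normal}/\code{erratic} (expert style) or the
#' simulator's \code{oscillating}/\code{normal}. Minute indices must be
#' contiguous from 0.
#'
#' @param path CSV path.
#' @return Character vector of normalised labels, one per minute.
#' @export
read_annotations <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("minute_index", "label") %in% names(d)))
    stop_invalid("annotation CSV needs columns minute_index,label")
  d <- d[order(d$minute_index), ]
  if (!identical(as.integer(d$minute_index), seq_len(nrow(d)) - 1L))
    stop_invalid("minute_index must be contiguous from 0")
  norm_ref(d$label)
}

#' Write simulator ground truth
#'
#' Writes the per-minute truth labels as \code{minute_index,label} CSV
#' and, optionally, the schedule as JSON.
#'
#' @param rec a \code{"csr_recording"}.
#' @param path truth CSV path.
#' @param schedule_path optional JSON path for the schedule dump.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(rec, path, schedule_path = NULL) {
  stopifnot(inherits(rec, "csr_recording"))
  utils::write.csv(data.frame(
    minute_index = seq_along(rec$truth_minutes) - 1L,
    label = rec$truth_minutes), path, row.names = FALSE)
  if (!is.null(schedule_path))
    jsonlite::write_json(as.data.frame(rec$schedule), schedule_path,
                         digits = NA)
  invisible(path)
}
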