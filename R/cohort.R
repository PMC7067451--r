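#' Simulate a validation cohort of annotated recordings
#'
#' Builds the two standard synthetic cohorts used to validate the
#' pipeline, 30-minute recordings at 25 Hz with the breath-shaped
#' carrier:
#' \describe{
#'   \item{\code{"diagnosis"}}{15 recordings for the three-class
#'     classification task: 4 with a 13-min severe episode
#'     (\code{h = 1.5}), 1 with a 13-min periodic-breathing episode
#'     (\code{h = 0.5}), 7 entirely normal, and 3 with a short (3-min,
#'     sub-diagnostic) oscillation at \code{h = 0.4}; mild noise
#'     (SD 0.02) and cycle jitter 0.05.}
#'   \item{\code{"roc"}}{10 recordings for threshold selection:
#'     5 oscillating throughout at \code{h} in 0.3--1.5, 5 entirely
#'     normal; noise SD 0.05, jitter 0.05.}
#' }
#' Modulation frequencies are spread over the pathological 8--30 mHz
#' band.
#'
#' @param type \code{"diagnosis"} or \code{"roc"}.
#' @param seed integer; recording \code{i} uses seed
#'   \code{seed * 100 + i}.
#' @return A list with one element per recording: \code{rec} (a
#'   \code{"csr_recording"}) and \code{label} (the designed diagnosis).
#' @export
simulate_cohort <- function(type = c("diagnosis", "roc"), seed = 1) {
  type <- match.arg(type)
  specs <- if (type == "diagnosis") {
    c(lapply(c(0.01, 0.0125, 0.02, 0.01), function(fm)
        list(label = "CSR_CSA", h = 1.5, on = 300, len = 780, fm = fm)),
      list(list(label = "PB", h = 0.5, on = 300, len = 780, fm = 0.0125)),
      lapply(c(0.012, 0.015, 0.02, 0.01, 0.025, 0.015, 0.012), function(fm)
        list(label = "NON_CSR", h = 0, on = 0, len = 0, fm = fm)),
      lapply(c(0.015, 0.015, 0.015), function(fm)
        list(label = "NON_CSR", h = 0.4, on = 600, len = 180, fm = fm)))
  } else {
    c(lapply(seq_along(hs <- c(0.3, 0.6, 0.9, 1.2, 1.5)), function(i)
        list(label = if (hs[i] > 1) "CSR_CSA" else "PB", h = hs[i],
             on = 0, len = 1800, fm = c(0.01, 0.0125, 0.015, 0.02, 0.01)[i])),
      lapply(c(0.012, 0.015, 0.02, 0.01, 0.025), function(fm)
        list(label = "NON_CSR", h = 0, on = 0, len = 0, fm = fm)))
  }
  noise <- if (type == "diagnosis") 0.02 else 0.05
  lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    sched <- if (sp$h == 0 || sp$len >= 1800) {
      csr_schedule(0, 1800, h = sp$h, f_m = sp$fm)
    } else {
      csr_schedule(c(0, sp$on, sp$on + sp$len), c(sp$on, sp$on + sp$len, 1800),
                   h = c(0, sp$h, 0), f_m = sp$fm)
    }
    list(rec = build_recording(sched, fs = 25, noise_sd = noise,
                               breath_jitter = 0.05, carrier = "breath",
                               seed = seed * 100 + i),
         label = sp$label)
  })
}
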