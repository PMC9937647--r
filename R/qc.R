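# Particle-inclusion rules applied before analysis: a usable recording must
# show single-step photobleaching (exactly one fluorophore), carry at least
# 15 events (95% confidence for state identification), and have per-frame
# SNR above 5 (minimum angle resolution).

#' Detect the photobleach step in a trace's total intensity
#'
#' Runs the changepoint detector on the summed four-channel photon trace
#' (single-channel likelihood) and classifies the detected intensity levels:
#' a bleach step is a drop of more than 30% of the trace's level range into
#' the dark regime (below 25% of the top level). The trace passes iff there
#' is exactly one such major drop, after which the trace stays dark.
#'
#' @param photons A `photon_trace` (or numeric matrix of channel photons).
#' @param config A [changepoint_config()] calibrated for single-channel
#'   detection at the trace's SNR and length.
#' @return List with `single_step` (logical), `bleach_frame` (last bright
#'   frame, NA if none), `n_steps`, `reason` ("", "no bleach", or
#'   "multi-step bleach").
#' @export
check_bleach <- function(photons, config) {
  mat <- if (inherits(photons, "photon_trace")) photons$photons else as.matrix(photons)
  tot <- matrix(rowSums(mat), ncol = 1)
  ts <- detect_transitions(tot, config)
  means <- as.numeric(ts$segment_means)
  bounds <- c(0L, ts$changepoints, ts$n_frames)
  top <- max(means)
  dark <- means < 0.25 * top
  drops <- which(diff(means) < -0.30 * top)
  major <- drops[dark[drops + 1]]
  if (length(major) == 0 || !dark[length(means)]) {
    return(list(single_step = FALSE, bleach_frame = NA_integer_,
                n_steps = length(major), reason = "no bleach"))
  }
  after_dark <- all(dark[(major[1] + 1):length(means)])
  extra_drops <- length(drops) > 1
  if (length(major) == 1 && after_dark && !extra_drops) {
    list(single_step = TRUE, bleach_frame = bounds[major[1] + 1],
         n_steps = 1L, reason = "")
  } else {
    list(single_step = FALSE,
         bleach_frame = bounds[major[1] + 1],
         n_steps = max(length(major), length(drops)),
         reason = "multi-step bleach")
  }
}

#' Apply the particle-inclusion filters
#'
#' A trace is included iff it bleaches in a single step, has at least
#' `min_events` detected events, and mean per-frame SNR above `min_snr`.
#' The filters are order-independent; the reported `exclusion_reason` lists
#' every failed criterion.
#'
#' @param traces List of per-trace summaries: each a list with
#'   `single_step` (logical), `n_events`, `snr`.
#' @param min_events Minimum events per trace (default 15).
#' @param min_snr Minimum SNR (default 5, exclusive).
#' @return Data.frame of class `qc_report`: `trace`, `single_step_bleach`,
#'   `n_events`, `snr`, `included`, `exclusion_reason`.
#' @export
apply_filters <- function(traces, min_events = 15, min_snr = 5) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    fails <- c(if (!isTRUE(tr$single_step)) "bleach",
               if (tr$n_events < min_events) "min_events",
               if (!(tr$snr > min_snr)) "snr")
    data.frame(trace = i, single_step_bleach = isTRUE(tr$single_step),
               n_events = tr$n_events, snr = tr$snr,
               included = length(fails) == 0,
               exclusion_reason = paste(fails, collapse = "+"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("qc_report", "data.frame")
  out
}
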