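# EMCCD camera model: gain/offset calibration and count -> photon conversion.
#
# Recorded counts relate to photoelectrons by I*dt = G*N + offset. The
# electron-multiplying register adds multiplicative noise that scales the
# shot-noise standard deviation by sqrt(2), so SNR = (I - offset)/sd = sqrt(N/2)
# and I*dt = 2*G*SNR^2 + offset: on a plot of mean counts against SNR^2 the
# slope is twice the gain and the intercept is the offset.

#' EMCCD camera model
#'
#' @param G Camera counts per photoelectron (gain), > 0.
#' @param offset Counts recorded with the shutter closed, >= 0.
#' @param QE Quantum efficiency (probability a photon yields an electron).
#' @param N_bak Background photons per frame per channel.
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(G = 146, offset = 220, QE = 0.95, N_bak = 0) {
  stopifnot(G > 0, offset >= 0, QE > 0, QE <= 1, N_bak >= 0)
  structure(list(G = G, offset = offset, QE = QE, N_bak = N_bak),
            class = "camera_model")
}

#' Fit camera gain and offset from a calibration series
#'
#' Least-squares line of mean recorded counts (`I*dt`) on `SNR^2`;
#' the gain is half the slope and the offset is the intercept.
#'
#' @param calibration Data.frame with columns `I_dt` (mean counts per frame)
#'   and `snr` (effective per-frame SNR), one row per illumination level,
#'   e.g. from [simulate_calibration_series()].
#' @param weighted Weight levels by `1/(SNR^2 + 1/2)` (default). The
#'   variance of a level's mean counts grows with its photon rate, and the
#'   intercept (the offset) is carried by the dim levels, so inverse-rate
#'   weighting recovers it far more precisely than an unweighted fit.
#' @return List with `G`, `offset` and the underlying `lm` fit.
#' @export
fit_gain_offset <- function(calibration, weighted = TRUE) {
  stopifnot(is.data.frame(calibration), all(c("I_dt", "snr") %in% names(calibration)))
  snr2 <- calibration$snr^2
  if (length(unique(round(snr2, 12))) < 2) {
    stop("calibration error: need >= 2 distinct SNR^2 levels (rank-deficient input)")
  }
  w <- if (weighted) 1 / (snr2 + 0.5) else rep(1, length(snr2))
  fit <- stats::lm(I_dt ~ snr2, weights = w,
                   data = data.frame(I_dt = calibration$I_dt, snr2 = snr2))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) stop("calibration error: non-positive slope")
  list(G = slope / 2, offset = unname(stats::coef(fit)[1]), fit = fit)
}

#' Convert camera counts to photon counts and per-frame SNR
#'
#' Inverts the camera relation per channel, `N = (signal - offset)/G - N_bak`,
#' divides by the quantum efficiency to estimate incident photons, and
#' computes the per-frame effective SNR `sqrt(N_total/2)` from the summed
#' channels. Negative per-frame estimates (noise below offset) are retained
#' so event averages stay unbiased.
#'
#' @param trace A `polarized_trace` (see [emit_photon_trace()]) or a numeric
#'   matrix of camera counts with 4 columns.
#' @param camera A [camera_model()]. For a `polarized_trace` the background is
#'   estimated from the post-bleach segment when one is recorded, otherwise
#'   `camera$N_bak` is used.
#' @return Object of class `photon_trace`: list with `photons` (matrix of
#'   per-frame detected photons per channel, QE-corrected), `snr` (per-frame),
#'   `frame_interval`, `N_bak` and `bleach_frame` (if known).
#' @export
counts_to_photons <- function(trace, camera) {
  stopifnot(inherits(camera, "camera_model"))
  if (inherits(trace, "polarized_trace")) {
    counts <- trace$counts
    frame_interval <- trace$frame_interval
    bleach_frame <- trace$bleach_frame
  } else {
    counts <- as.matrix(trace)
    frame_interval <- 0.01
    bleach_frame <- NA_integer_
  }
  stopifnot(ncol(counts) == 4)
  if (mean(counts < camera$offset) > 0.10) {
    warning("offset exceeds signal in >10% of frames: possible mis-calibration")
  }
  N_bak <- camera$N_bak
  if (is.finite(bleach_frame) && !is.na(bleach_frame) &&
      bleach_frame < nrow(counts) - 10) {
    post <- counts[(bleach_frame + 1):nrow(counts), , drop = FALSE]
    N_bak <- max(mean((post - camera$offset) / camera$G), 0)
  }
  N <- (counts - camera$offset) / camera$G - N_bak
  N_det <- N / camera$QE
  snr <- sqrt(pmax(rowSums(N_det), 0) / 2)
  structure(list(photons = N_det, snr = snr, frame_interval = frame_interval,
                 N_bak = N_bak, bleach_frame = bleach_frame),
            class = "photon_trace")
}
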