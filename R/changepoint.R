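# Binned-photon log-likelihood-ratio changepoint detection across the four
# polarization channels. For a segment of T frames with per-channel photon
# totals N_r and pre-changepoint cumulative counts m_r at candidate frame tau,
#
#   LLR(tau) = sum_r [ m_r ln(m_r/tau) + (N_r - m_r) ln((N_r - m_r)/(T - tau))
#                      - N_r ln(N_r/T) ]
#
# with 0*ln(0) == 0. Concurrent rate changes in all channels add, which is
# what makes four-channel detection sensitive to small orientation changes.

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Log-likelihood ratio profile of a rate change within a segment
#'
#' Computes `LLR(tau)` for every interior candidate changepoint of a
#' multi-channel photon-count segment. Counts may be non-integer (photon
#' estimates from camera inversion); channels whose segment total is not
#' positive contribute zero.
#'
#' @param counts Numeric matrix, frames x channels (any number of channels).
#' @param tau Candidate changepoint frame(s), `0 < tau < nrow(counts)`;
#'   default all interior frames. A changepoint at `tau` means frames
#'   `1..tau` precede the change.
#' @return Numeric vector of LLR values, one per `tau`.
#' @export
llr <- function(counts, tau = seq_len(nrow(counts) - 1L)) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1)
  T_ <- nrow(counts)
  stopifnot(all(tau >= 1), all(tau <= T_ - 1L))
  out <- numeric(length(tau))
  for (r in seq_len(ncol(counts))) {
    cum <- cumsum(counts[, r])
    N <- cum[T_]
    if (!is.finite(N) || N <= 0) next
    m <- clamp(cum[tau], 0, N)
    out <- out + xlogx(m) - m * log(tau) +
      xlogx(N - m) - (N - m) * log(T_ - tau) -
      xlogx(N) + N * log(T_)
  }
  out
}

#' Changepoint detection configuration
#'
#' @param threshold_table Data.frame with columns `length` and `threshold`
#'   giving the LLR acceptance threshold as a function of segment length
#'   (frames), e.g. from [calibrate_threshold_table()]. Thresholds are
#'   interpolated linearly in log-length and held constant beyond the grid.
#' @param confidence Target per-trace false-positive rate used when the
#'   table was calibrated (informational; default 0.05).
#' @param min_segment Minimum segment length in frames on either side of a
#'   changepoint (default 2).
#' @return Object of class `changepoint_config`.
#' @export
changepoint_config <- function(threshold_table, confidence = 0.05,
                               min_segment = 2L) {
  stopifnot(is.data.frame(threshold_table),
            all(c("length", "threshold") %in% names(threshold_table)),
            confidence > 0, confidence < 1, min_segment >= 1)
  tt <- threshold_table[order(threshold_table$length), ]
  structure(list(threshold_table = tt, confidence = confidence,
                 min_segment = as.integer(min_segment)),
            class = "changepoint_config")
}

threshold_for_length <- function(config, len) {
  tt <- config$threshold_table
  if (nrow(tt) == 1) return(tt$threshold)
  stats::approx(log(tt$length), tt$threshold, xout = log(len), rule = 2)$y
}

#' Recursive changepoint detection on a multi-channel photon trace
#'
#' Finds the interior frame maximizing the LLR over the whole trace; if that
#' maximum exceeds the (length-dependent) threshold the changepoint is
#' accepted and the search recurses on both sub-segments, until no
#' supra-threshold changepoint remains. Ties in the argmax break toward the
#' earlier frame.
#'
#' @param trace A `photon_trace` from [counts_to_photons()] or a numeric
#'   matrix of per-frame photon counts (frames x channels).
#' @param config A [changepoint_config()].
#' @param end Optional last frame to search (e.g. a bleach frame).
#' @return Object of class `transition_set`: list with sorted `changepoints`
#'   (frame indices; segment `k` covers frames `(cp[k-1], cp[k]]`), `llr`
#'   per accepted changepoint, `n_frames`, and `segment_means` (matrix of
#'   per-segment per-channel means).
#' @export
detect_transitions <- function(trace, config, end = NULL) {
  mat <- if (inherits(trace, "photon_trace")) trace$photons else as.matrix(trace)
  nf <- nrow(mat)
  if (!is.null(end) && is.finite(end)) nf <- min(nf, end)
  mat <- mat[seq_len(nf), , drop = FALSE]
  ms <- config$min_segment
  found <- integer(0); found_llr <- numeric(0)
  if (nf < 2 * ms) {
    warning("trace shorter than twice the minimum segment; no detection run")
  } else {
    stack <- list(c(1L, nf))
    while (length(stack) > 0) {
      seg <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      a <- seg[1]; b <- seg[2]
      len <- b - a + 1L
      if (len < 2 * ms) next
      taus <- (a + ms - 1L):(b - ms)          # absolute frame index of change
      vals <- llr(mat[a:b, , drop = FALSE], tau = taus - a + 1L)
      if (!any(is.finite(vals))) next
      best <- which.max(vals)                  # first maximum: earlier frame
      if (vals[best] > threshold_for_length(config, len)) {
        cp <- taus[best]
        found <- c(found, cp)
        found_llr <- c(found_llr, vals[best])
        stack[[length(stack) + 1L]] <- c(a, cp)
        stack[[length(stack) + 1L]] <- c(cp + 1L, b)
      }
    }
  }
  ord <- order(found)
  cps <- found[ord]
  bounds <- c(0L, cps, nf)
  seg_means <- t(vapply(seq_len(length(bounds) - 1L), function(k) {
    colMeans(mat[(bounds[k] + 1L):bounds[k + 1L], , drop = FALSE])
  }, numeric(ncol(mat))))
  structure(list(changepoints = cps, llr = found_llr[ord], n_frames = nf,
                 segment_means = seg_means),
            class = "transition_set")
}

# Simulate one batch of null (constant-rate) traces with EMCCD excess noise
# and return the maximum interior LLR of each. Rates are per frame per
# channel; excess noise smears each frame's Poisson count through the
# normalized gain distribution (Gamma with unit scale), doubling the variance.
null_max_llr <- function(n_traces, length_frames, rate_per_channel, h = 4,
                         min_segment = 2L, excess_noise = TRUE) {
  ms <- as.integer(min_segment)
  vapply(seq_len(n_traces), function(i) {
    N <- matrix(stats::rpois(length_frames * h, rate_per_channel),
                length_frames, h)
    if (excess_noise) {
      pos <- N > 0
      N[pos] <- stats::rgamma(sum(pos), shape = N[pos], scale = 1)
    }
    taus <- ms:(length_frames - ms)
    max(llr(N, tau = taus))
  }, numeric(1))
}

#' Calibrate the LLR threshold for one (SNR, length) condition
#'
#' Simulates constant-orientation (null) traces at the given effective SNR
#' (total photons per frame `N = 2 SNR^2`, split evenly across channels,
#' Poisson shot noise with EMCCD excess noise) and returns the LLR value
#' whose exceedance probability by the trace-wide maximum equals the target
#' false-positive rate.
#'
#' @param snr Effective per-frame SNR (`sqrt(N_total/2)`).
#' @param length_frames Trace length in frames.
#' @param confidence Target per-trace false-positive rate (default 0.05).
#' @param n_sim Number of simulated null traces (>= 2000 recommended).
#' @param seed RNG seed.
#' @param h Number of channels (4 for the polarization system).
#' @param min_segment As in [changepoint_config()].
#' @return Threshold (numeric scalar).
#' @export
calibrate_threshold <- function(snr, length_frames, confidence = 0.05,
                                n_sim = 2000, seed = 1, h = 4,
                                min_segment = 2L) {
  stopifnot(snr > 0, length_frames >= 2 * min_segment)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rate <- 2 * snr^2 / h
  mx <- null_max_llr(n_sim, length_frames, rate, h = h, min_segment = min_segment)
  unname(stats::quantile(mx, 1 - confidence, type = 7))
}

#' Calibrate a threshold table over segment lengths
#'
#' Builds the length-indexed threshold table used by the recursive detector,
#' enforcing monotone non-decreasing thresholds in length (an extreme-value
#' property of the null maximum).
#'
#' @inheritParams calibrate_threshold
#' @param lengths Grid of segment lengths (frames).
#' @return A [changepoint_config()] ready for [detect_transitions()].
#' @export
calibrate_threshold_table <- function(snr, lengths = c(8, 16, 32, 64, 128, 256,
                                                       512, 768, 1024),
                                      confidence = 0.05, n_sim = 2000,
                                      seed = 1, h = 4, min_segment = 2L) {
  lengths <- sort(unique(as.integer(lengths)))
  thr <- vapply(seq_along(lengths), function(i) {
    calibrate_threshold(snr, lengths[i], confidence, n_sim,
                        seed = seed + i, h = h, min_segment = min_segment)
  }, numeric(1))
  thr <- cummax(thr)
  changepoint_config(data.frame(length = lengths, threshold = thr),
                     confidence = confidence, min_segment = min_segment)
}

# Save/restore .Random.seed so seeded helpers do not disturb callers' RNG.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
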