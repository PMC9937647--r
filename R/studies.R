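# Self-contained simulation studies used to verify the pipeline's headline
# operating characteristics: per-event angle precision, changepoint
# false-positive rate, and state-count recovery. Each study regenerates its
# inputs from scratch under a single seed.

#' Per-event angle precision at a given SNR
#'
#' Fixes a dipole orientation, simulates many events of consecutive frames
#' with the photon budget implied by the effective SNR (`N = 2 SNR^2`
#' photons/frame summed over channels, Poisson shot noise with EMCCD excess
#' noise), solves each event's orientation from its mean intensities, and
#' reports the standard deviation of the estimates across events.
#'
#' @param snr Effective per-frame SNR (default 5).
#' @param theta_deg,phi_deg True dipole orientation (default 60, 30).
#' @param event_photons Total photons averaged per event (default 1740, the
#'   typical photon count collected over one dwell); determines the frame
#'   count at the given SNR when `frames_per_event` is not supplied.
#' @param frames_per_event Frames averaged per event; default derived as
#'   `event_photons / (2 snr^2)`.
#' @param n_events Number of simulated events (default 1000).
#' @param params [system_params()]; defaults to ideal correction parameters.
#' @param seed RNG seed.
#' @return List with `sigma_theta`, `sigma_phi` (degrees), `n_events`,
#'   `frames_per_event`.
#' @export
angle_precision_study <- function(snr = 5, theta_deg = 60, phi_deg = 30,
                                  event_photons = 1740,
                                  frames_per_event = NULL, n_events = 1000,
                                  params = ideal_system_params(), seed = 1) {
  if (is.null(frames_per_event)) {
    frames_per_event <- max(1L, round(event_photons / (2 * snr^2)))
  }
  coeffs <- system_coefficients(params)
  I1 <- polarized_intensity(theta_deg, phi_deg, 1, params, coeffs)
  rates <- as.numeric(I1) * (2 * snr^2) / sum(I1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lam <- rep(rates * frames_per_event, each = n_events)
  N <- matrix(stats::rpois(n_events * 4, lam), n_events, 4)
  amp <- matrix(0, n_events, 4)
  pos <- N > 0
  amp[pos] <- stats::rgamma(sum(pos), shape = N[pos], scale = 1)
  sol <- solve_orientation_batch(amp / frames_per_event, params, coeffs)
  dphi <- (sol$phi_deg - phi_deg + 90) %% 180 - 90
  list(sigma_theta = stats::sd(sol$theta_deg),
       sigma_phi = stats::sd(dphi),
       n_events = n_events, frames_per_event = frames_per_event)
}

#' Changepoint false-positive rate with independently calibrated threshold
#'
#' Calibrates the LLR threshold on a training set of simulated
#' constant-orientation traces, then applies the recursive detector to an
#' independent test set and reports the fraction of traces with at least
#' one detected changepoint.
#'
#' @param snr Effective per-frame SNR (default 7).
#' @param length_frames Trace length (default 720, i.e. 7.2 s at 10 ms).
#' @param confidence Target per-trace false-positive rate (default 0.05).
#' @param n_train,n_test Training and test trace counts (default 2000 each).
#' @param seed RNG seed (training and test sets use disjoint sub-seeds).
#' @return List with `fp_rate` (fraction), `threshold`, `n_test`.
#' @export
fp_rate_study <- function(snr = 7, length_frames = 720, confidence = 0.05,
                          n_train = 2000, n_test = 2000, seed = 1) {
  thr <- calibrate_threshold(snr, length_frames, confidence,
                             n_sim = n_train, seed = seed)
  config <- changepoint_config(data.frame(length = length_frames,
                                          threshold = thr),
                               confidence = confidence)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 104729L)   # disjoint test stream
  rate <- 2 * snr^2 / 4
  hits <- 0L
  for (i in seq_len(n_test)) {
    N <- matrix(stats::rpois(length_frames * 4, rate), length_frames, 4)
    pos <- N > 0
    N[pos] <- stats::rgamma(sum(pos), shape = N[pos], scale = 1)
    ts <- detect_transitions(N, config)
    if (length(ts$changepoints) > 0) hits <- hits + 1L
  }
  list(fp_rate = hits / n_test, threshold = thr, n_test = n_test)
}

#' State-count recovery over seeded synthetic ensembles
#'
#' For each seed, simulates an ensemble of molecules with the four-state
#' ground-truth geometry (equal state occupancies) and the reference photon
#' statistics, runs the full per-molecule pipeline (photon conversion,
#' changepoint detection, angle solving, state sorting with the 2.5-sigma
#' criterion), and records the modal resolved state count across the
#' ensemble's molecules.
#'
#' @param n_seeds Number of independent ensembles (default 20).
#' @param n_molecules Molecules per ensemble (default 30).
#' @param duration_s Recording length per molecule (default 12 s, about 30
#'   usable events at the default 350 ms dwells).
#' @param params [system_params()] of the simulated instrument.
#' @param camera [camera_model()].
#' @param config Optional pre-calibrated [changepoint_config()]; calibrated
#'   at SNR 7 when omitted.
#' @param seed Master RNG seed.
#' @return List with `k_per_seed` (integer vector), `majority_k`,
#'   `fraction_k4`, `n_molecules`.
#' @export
state_count_study <- function(n_seeds = 20, n_molecules = 30,
                              duration_s = 12,
                              params = system_params(alpha = 70),
                              camera = camera_model(),
                              config = NULL, seed = 1) {
  if (is.null(config)) {
    config <- calibrate_threshold_table(7, n_sim = 2000, seed = seed + 17L)
  }
  truth <- ground_truth_model(
    equilibrium_params = equilibrium_params(c(1, 1, 1), c(1, 1, 1), 49))
  k_per_seed <- integer(n_seeds)
  for (s in seq_len(n_seeds)) {
    ds <- simulate_dataset(n_molecules, concentrations_uM = 0,
                           duration_s = duration_s, truth = truth,
                           params = params, camera = camera,
                           seed = (seed * 131L + s * 7L) %% 2000000000L)
    ks <- vapply(seq_along(ds$traces), function(i) {
      res <- tryCatch(
        analyse_trace(ds$traces[[i]], camera, params, config,
                      cluster_seed = s * 1000L + i),
        error = function(e) NULL)
      if (is.null(res)) NA_integer_ else as.integer(res$model$k)
    }, integer(1))
    tb <- table(ks)
    k_per_seed[s] <- as.integer(names(tb)[which.max(tb)])
  }
  tb_all <- table(k_per_seed)
  list(k_per_seed = k_per_seed,
       majority_k = as.integer(names(tb_all)[which.max(tb_all)]),
       fraction_k4 = mean(k_per_seed == 4L),
       n_molecules = n_molecules)
}
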