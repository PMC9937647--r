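# Synthetic-data generator emulating the microscope's photon statistics:
# exponential dwells from a reversible Markov chain whose stationary law is
# the eight-state equilibrium model, a forward polarized-intensity model per
# state orientation, Poisson shot noise with EMCCD excess noise, single-step
# photobleaching, and random in-plane molecule orientation.

#' Default four-state dipole geometry
#'
#' Four unit vectors (local frame) with pairwise great-circle separations of
#' 16-40 degrees, inside the 10-40 degree range typical of helix-orientation
#' changes between transporter conformations and comfortably above the
#' 2.5-sigma resolution limit (about 10 degrees at sigma = 4), so that a
#' correctly working pipeline resolves all four states. States 1 and 4 lie
#' in the local x-y plane (theta = 90) as the local-frame convention
#' requires; the middle states sit at moderate inclinations, where both
#' angles are measured precisely, with slightly different inclinations so
#' that the state-sequence direction is identifiable (a perfectly
#' palindromic geometry would make it unobservable).
#'
#' @return 4 x 3 matrix of unit row vectors, in state order C1..C4.
#' @export
default_state_geometry <- function() {
  ang <- rbind(c(90, 0), c(72, 13), c(68, 30), c(90, 40))
  sph_to_cart(ang[, 1], ang[, 2])
}

#' Ground-truth model for synthetic recordings
#'
#' @param state_orientations 4 x 3 matrix of unit vectors (dipole direction
#'   per state, local frame); default [default_state_geometry()].
#' @param dwell_means Mean dwell time per state, ms (default 350 ms each, about 20 events in a 7.2 s recording).
#' @param equilibrium_params [equilibrium_params()]; default
#'   [reference_equilibrium_params()].
#' @param molecule_rotation 3 x 3 rotation taking local to lab frame.
#' @param bleach_time Time of the single-step photobleach, s (`Inf` = none).
#' @param background_rate Background photons/frame/channel.
#' @param frame_interval Frame interval, s (default 0.01).
#' @param mean_total_photons Expected detected photons per frame summed over
#'   the four channels, averaged over the stationary state mixture
#'   (default 92, effective SNR ~ 7).
#' @return Object of class `ground_truth_model`; its
#'   `pairwise_separation_deg` field reports the 6 state separations.
#' @export
ground_truth_model <- function(state_orientations = default_state_geometry(),
                               dwell_means = rep(350, 4),
                               equilibrium_params = reference_equilibrium_params(),
                               molecule_rotation = diag(3),
                               bleach_time = Inf,
                               background_rate = 0,
                               frame_interval = 0.01,
                               mean_total_photons = 92) {
  V <- as.matrix(state_orientations)
  stopifnot(nrow(V) == 4, ncol(V) == 3)
  nrm <- sqrt(rowSums(V^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("state orientations must be unit vectors")
  stopifnot(all(dwell_means > 0), frame_interval > 0, mean_total_photons > 0,
            background_rate >= 0)
  pairs <- utils::combn(4, 2)
  sep <- apply(pairs, 2, function(ij) angular_distance(V[ij[1], ], V[ij[2], ]))
  structure(list(state_orientations = V, dwell_means = dwell_means,
                 equilibrium_params = equilibrium_params,
                 molecule_rotation = molecule_rotation,
                 bleach_time = bleach_time,
                 background_rate = background_rate,
                 frame_interval = frame_interval,
                 mean_total_photons = mean_total_photons,
                 pairwise_separation_deg = stats::setNames(
                   sep, apply(pairs, 2, paste, collapse = "-"))),
            class = "ground_truth_model")
}

#' Simulate a state path sampled at frame boundaries
#'
#' Continuous-time reversible Markov chain over the four conformations with
#' detailed-balance rates `q_ij = c sqrt(p_j / p_i)` (so the stationary law
#' equals the equilibrium-model probabilities at the given concentration) and
#' exponential dwell times; the overall rate scale `c` is set so the
#' occupancy-weighted mean dwell equals `mean(dwell_means)`. The path is
#' sampled at frame starts.
#'
#' @param truth A [ground_truth_model()].
#' @param concentration_uM Ligand concentration (>= 0).
#' @param duration_s Trace duration, s (>= one frame).
#' @param seed RNG seed.
#' @return Integer vector of per-frame state labels (1..4) with attributes
#'   `jump_times` and `occupancy` (stationary probabilities used).
#' @export
simulate_state_path <- function(truth, concentration_uM, duration_s, seed = 1) {
  stopifnot(inherits(truth, "ground_truth_model"), concentration_uM >= 0)
  dt <- truth$frame_interval
  if (duration_s < dt) stop("duration must cover at least one frame")
  n_frames <- floor(duration_s / dt + 1e-9)
  p <- as.numeric(state_probabilities(truth$equilibrium_params, concentration_uM))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  state0 <- sample.int(4, 1, prob = p)
  tau_bar <- mean(truth$dwell_means) / 1000   # target mean dwell, s
  labels <- integer(n_frames)
  if (!is.finite(tau_bar)) {
    labels[] <- state0
    attr(labels, "jump_times") <- numeric(0)
    attr(labels, "occupancy") <- p
    return(labels)
  }
  sp <- sqrt(p)
  # exit rate of state i at scale c: lam_i = c * sum_{j != i}(sp_j) / sp_i
  exit_unit <- vapply(1:4, function(i) sum(sp[-i]) / sp[i], numeric(1))
  c_scale <- sum(p / exit_unit) / tau_bar   # occupancy-weighted mean dwell
  Q <- outer(1 / sp, sp) * c_scale
  diag(Q) <- 0
  t_now <- 0; s <- state0; i_frame <- 1L
  jumps <- numeric(0)
  while (i_frame <= n_frames) {
    lam <- sum(Q[s, ])
    dwell <- stats::rexp(1, lam)
    t_end <- t_now + dwell
    last <- min(n_frames, ceiling(t_end / dt - 1e-12))
    if (last >= i_frame) {
      labels[i_frame:last] <- s
      i_frame <- last + 1L
    }
    if (t_end > n_frames * dt) break
    jumps <- c(jumps, t_end)
    s <- sample.int(4, 1, prob = Q[s, ])
    t_now <- t_end
  }
  if (i_frame <= n_frames) labels[i_frame:n_frames] <- s
  attr(labels, "jump_times") <- jumps
  attr(labels, "occupancy") <- p
  labels
}

# Per-state expected channel intensities (photons/frame), scaled so the
# stationary mean of the channel sum equals mean_total_photons.
state_channel_rates <- function(truth, params, concentration_uM = 0) {
  Vlab <- truth$state_orientations %*% t(truth$molecule_rotation)
  sph <- cart_to_sph(Vlab)
  th <- sph$theta_deg
  # forward model is invariant under the antipode/mirror degeneracy
  th <- ifelse(th > 90, 180 - th, th)
  I1 <- polarized_intensity(th, sph$phi_deg, itot = 1, params = params)
  p <- as.numeric(state_probabilities(truth$equilibrium_params, concentration_uM))
  scale_ <- truth$mean_total_photons / sum(p * rowSums(I1))
  I1 * scale_
}

#' Emit a four-channel camera-count trace for a state path
#'
#' Per frame, expected photons per channel follow the forward polarized
#' intensity model at the lab-frame orientation of the current state, plus
#' background. Realized photoelectrons are Poisson; the EM register applies
#' per-electron Gamma gain (mean `G`, shape 1), so camera-count variance is
#' `2 G^2 N`; the offset is added last. After the bleach time all channels
#' carry only background and offset.
#'
#' @param path Per-frame state labels from [simulate_state_path()].
#' @param truth The [ground_truth_model()].
#' @param params [system_params()] of the simulated instrument.
#' @param camera [camera_model()] of the simulated camera.
#' @param seed RNG seed.
#' @param concentration_uM Concentration (only used for the photon-scale
#'   stationary average; default 0).
#' @return Object of class `polarized_trace`: list with `counts` (frames x 4
#'   camera counts), `true_state` (0 after bleach), `frame_interval`,
#'   `bleach_frame`, `camera`, and `rates` (expected photons/frame/channel
#'   per state).
#' @export
emit_photon_trace <- function(path, truth, params, camera = camera_model(),
                              seed = 1, concentration_uM = 0) {
  stopifnot(length(path) >= 1)
  rates <- state_channel_rates(truth, params, concentration_uM)
  n <- length(path)
  bleach_frame <- if (is.finite(truth$bleach_time)) {
    min(n, floor(truth$bleach_time / truth$frame_interval))
  } else n
  lam <- rates[path, , drop = FALSE] * camera$QE + truth$background_rate
  if (bleach_frame < n) {
    lam[(bleach_frame + 1):n, ] <- truth$background_rate
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  N <- matrix(stats::rpois(n * 4, as.numeric(lam)), n, 4)
  amplified <- N
  pos <- N > 0
  if (any(pos)) {
    amplified[pos] <- stats::rgamma(sum(pos), shape = N[pos], scale = camera$G)
  }
  counts <- amplified + camera$offset
  true_state <- path
  if (bleach_frame < n) true_state[(bleach_frame + 1):n] <- 0L
  structure(list(counts = counts, true_state = as.integer(true_state),
                 frame_interval = truth$frame_interval,
                 bleach_frame = if (bleach_frame < n) bleach_frame else NA_integer_,
                 camera = camera, rates = rates),
            class = "polarized_trace")
}

#' Simulate a camera calibration series
#'
#' Generates frames at several illumination levels with the EMCCD model
#' (Poisson photons, Gamma excess noise, offset) plus an internal dark
#' (shutter-closed) series, and summarizes each level as mean counts `I_dt`
#' and the empirical effective SNR `(mean - dark mean)/sd`. With
#' `noise = FALSE` the analytic moments are used, so the points lie exactly
#' on `I_dt = 2 G SNR^2 + offset`.
#'
#' @param camera A [camera_model()].
#' @param levels Illumination levels (mean photons per frame), >= 3 levels.
#' @param frames_per_level Frames simulated per level (>= 100).
#' @param seed RNG seed.
#' @param noise Simulate noise (default) or return the deterministic limit.
#' @return Data.frame with `level`, `I_dt`, `snr`.
#' @export
simulate_calibration_series <- function(camera, levels, frames_per_level = 500,
                                        seed = 1, noise = TRUE) {
  if (length(levels) < 2) stop("need at least 2 illumination levels")
  if (length(levels) < 3) warning("fewer than 3 levels: fit will be fragile")
  if (noise && frames_per_level < 100) stop("frames_per_level must be >= 100")
  if (!noise) {
    I_dt <- camera$G * levels + camera$offset
    snr <- sqrt(levels / 2)
    return(data.frame(level = levels, I_dt = I_dt, snr = snr))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dark_mean <- camera$offset   # shutter closed: no photons, readout at offset
  out <- lapply(levels, function(lv) {
    N <- stats::rpois(frames_per_level, lv)
    amp <- numeric(frames_per_level)
    pos <- N > 0
    if (any(pos)) amp[pos] <- stats::rgamma(sum(pos), shape = N[pos], scale = camera$G)
    counts <- amp + camera$offset
    data.frame(level = lv, I_dt = mean(counts),
               snr = (mean(counts) - dark_mean) / stats::sd(counts))
  })
  do.call(rbind, out)
}

#' Simulate a labelled multi-concentration dataset
#'
#' Generates one recording per molecule at each requested concentration:
#' a random molecule orientation (uniform in-plane rotation and a modest
#' random tilt), a state path, and a four-channel camera trace.
#'
#' @param n_per_conc Molecules per concentration.
#' @param concentrations_uM Ligand series; default
#'   `c(0, 10, 25, 50, 100, 250, 750, 3000)` uM, log-spaced around the
#'   reference `K_D` range.
#' @param duration_s Trace duration (default 7.2 s).
#' @param truth Template [ground_truth_model()]; per-molecule rotation and
#'   bleach time are drawn per trace.
#' @param params [system_params()] used by the instrument model.
#' @param camera [camera_model()].
#' @param seed Master seed; every trace derives its own sub-seed.
#' @param bleach_mean_s Mean of the exponential bleach time (`Inf` = no
#'   bleaching), default `Inf`.
#' @param tilt_range_deg Range of the random molecule tilt away from the
#'   optical axis (uniform; default 15-45 degrees). Flexibly tethered
#'   molecules sit well off the optical axis, which also keeps dipoles away
#'   from the theta = 90 rim where the inclination solution loses precision.
#' @return Object of class `synthetic_dataset`: list with `traces` (list of
#'   `polarized_trace` with `$concentration_uM`, `$molecule_rotation`,
#'   `$path`), `concentrations`, `truth`, `seed`.
#' @export
simulate_dataset <- function(n_per_conc, concentrations_uM = c(0, 10, 25, 50,
                                                               100, 250, 750, 3000),
                             duration_s = 7.2,
                             truth = ground_truth_model(),
                             params = system_params(alpha = 70),
                             camera = camera_model(),
                             seed = 1, bleach_mean_s = Inf,
                             tilt_range_deg = c(15, 45)) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  traces <- list(); k <- 0
  for (conc in concentrations_uM) {
    for (m in seq_len(n_per_conc)) {
      k <- k + 1
      rot_z <- rotation_about_axis(c(0, 0, 1), stats::runif(1, 0, 360))
      tilt_ax <- c(cos(stats::runif(1, 0, 2 * pi)), sin(stats::runif(1, 0, 2 * pi)), 0)
      rot <- rot_z %*% rotation_about_axis(
        tilt_ax, stats::runif(1, tilt_range_deg[1], tilt_range_deg[2]))
      bt <- if (is.finite(bleach_mean_s)) stats::rexp(1, 1 / bleach_mean_s) else Inf
      tr_truth <- truth
      tr_truth$molecule_rotation <- rot
      tr_truth$bleach_time <- bt
      sub_seed <- (seed * 10000 + k * 7 + 3) %% .Machine$integer.max
      path <- simulate_state_path(tr_truth, conc, duration_s, seed = sub_seed)
      tr <- emit_photon_trace(path, tr_truth, params, camera,
                              seed = sub_seed + 1, concentration_uM = conc)
      tr$concentration_uM <- conc
      tr$molecule_rotation <- rot
      tr$path <- as.integer(path)
      traces[[k]] <- tr
    }
  }
  structure(list(traces = traces,
                 concentrations = rep(concentrations_uM, each = n_per_conc),
                 truth = truth, seed = seed),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to CSV traces with a manifest and JSON sidecar
#'
#' One CSV per trace (`frame_index, I0, I45, I90, I135, true_state`), a
#' manifest CSV (`trace_id, concentration_uM, path`), and a JSON sidecar
#' with the ground-truth model and seed.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset$traces), function(i) {
    tr <- dataset$traces[[i]]
    fn <- sprintf("trace_%04d.csv", i)
    df <- data.frame(frame_index = seq_len(nrow(tr$counts)) - 1L,
                     I0 = tr$counts[, 1], I45 = tr$counts[, 2],
                     I90 = tr$counts[, 3], I135 = tr$counts[, 4],
                     true_state = tr$true_state)
    utils::write.csv(df, file.path(dir, fn), row.names = FALSE)
    data.frame(trace_id = i, concentration_uM = tr$concentration_uM, path = fn)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  truth <- dataset$truth
  sidecar <- list(seed = dataset$seed,
                  state_orientations = truth$state_orientations,
                  dwell_means_ms = truth$dwell_means,
                  equilibrium = list(K = truth$equilibrium_params$K,
                                     LK = truth$equilibrium_params$LK,
                                     KD1 = truth$equilibrium_params$KD1),
                  frame_interval_s = truth$frame_interval,
                  mean_total_photons = truth$mean_total_photons,
                  background_rate = truth$background_rate)
  jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
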