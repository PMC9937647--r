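# Forward intensity model and closed-form orientation solver for the
# four-channel polarized emission system.
#
# The expected intensity in the channel with polarizer angle psi, for a dipole
# at (theta, phi) wobbling in a cone of half-angle delta, collected by an
# objective of half-angle alpha, is
#
#   I_psi = (1/4) g_psi Itot [ X4(delta) ( sin^2(theta)
#             ( f_psi X1(alpha) cos(2(phi - psi)) + X2(alpha) )
#             - (2/3) X2(alpha) ) + X3(alpha) ]
#
# f_psi corrects for finite polarizer extinction, g_psi for unequal channel
# response (the 90 degree channel is the reference, g_90 = 1).

PSI_DEG <- c(0, 45, 90, 135)
CHANNEL_NAMES <- c("I0", "I45", "I90", "I135")

#' Optical system parameters
#'
#' Bundles the predetermined correction constants of the polarization
#' microscope. `alpha` has no default: the collection half-angle is an
#' instrument property that must come from configuration. The wobble-cone
#' half-angle `delta` defaults to 22.5 degrees, its experimentally estimated
#' value for bifunctional-rhodamine labels.
#'
#' @param alpha Objective collection half-angle, degrees, in (0, 90].
#' @param f_psi Extinction-correction factors for channels 0/45/90/135 (<= 1).
#' @param delta Wobble-cone half-angle, degrees, in [0, 90).
#' @param g_psi Channel response factors for channels 0/45/90/135; the 90
#'   degree channel is the reference and must have `g = 1`.
#' @return Object of class `system_params`.
#' @export
system_params <- function(alpha, f_psi = c(1, 1, 1, 1), delta = 22.5,
                          g_psi = c(1, 1, 1, 1)) {
  stopifnot(length(alpha) == 1, is.finite(alpha))
  if (alpha <= 0 || alpha > 90) stop("alpha must be in (0, 90] degrees")
  if (delta < 0 || delta >= 90) stop("delta must be in [0, 90) degrees")
  if (length(f_psi) != 4 || any(f_psi <= 0)) stop("f_psi must be 4 positive factors")
  if (length(g_psi) != 4 || any(g_psi <= 0)) stop("g_psi must be 4 positive factors")
  if (abs(g_psi[3] - 1) > 1e-9) stop("g for the 90 degree reference channel must equal 1")
  structure(list(alpha = alpha, f_psi = f_psi, delta = delta, g_psi = g_psi,
                 psi = PSI_DEG),
            class = "system_params")
}

#' Ideal system parameters (full collection, perfect optics, no wobble)
#' @return A `system_params` with `alpha = 90`, `f = g = 1`, `delta = 0`.
#' @export
ideal_system_params <- function() system_params(alpha = 90, delta = 0)

#' Optical correction coefficients
#'
#' Closed-form coefficients: `X1`, `X2`, `X3` correct for incomplete photon
#' collection by an objective with half-angle `alpha`,
#' \deqn{X_1 = \pi/12 (7 - 3\cos\alpha - 3\cos^2\alpha - \cos^3\alpha),\;
#'       X_2 = \pi/2 (\cos\alpha - \cos^3\alpha),\;
#'       X_3 = 2\pi/3 (1 - \cos\alpha)}
#' and `X4 = cos(delta)(1 + cos(delta))/2` corrects for sub-frame wobble of
#' the probe in a cone of half-angle `delta`.
#'
#' @param params A [system_params()] object.
#' @return Object of class `system_coefficients` with fields `X1`..`X4`.
#' @export
system_coefficients <- function(params) {
  stopifnot(inherits(params, "system_params"))
  ca <- cos(deg2rad(params$alpha))
  cd <- cos(deg2rad(params$delta))
  structure(list(
    X1 = pi / 12 * (7 - 3 * ca - 3 * ca^2 - ca^3),
    X2 = pi / 2 * (ca - ca^3),
    X3 = 2 * pi / 3 * (1 - ca),
    X4 = cd * (1 + cd) / 2
  ), class = "system_coefficients")
}

#' Expected polarized channel intensities for a dipole orientation
#'
#' Evaluates the forward model for one or more orientations.
#'
#' @param theta_deg,phi_deg Dipole orientation(s), degrees; `theta` in [0, 90].
#' @param itot Total emission intensity parameter (photons/frame scale).
#' @param params A [system_params()] object.
#' @param coeffs Optional precomputed [system_coefficients()].
#' @return Matrix with columns `I0`, `I45`, `I90`, `I135`.
#' @export
polarized_intensity <- function(theta_deg, phi_deg, itot, params,
                                coeffs = system_coefficients(params)) {
  if (any(theta_deg < 0 | theta_deg > 90)) {
    stop("theta must lie in [0, 90] degrees")
  }
  n <- max(length(theta_deg), length(phi_deg), length(itot))
  th <- deg2rad(rep_len(theta_deg, n))
  ph <- deg2rad(rep_len(phi_deg, n))
  it <- rep_len(itot, n)
  out <- matrix(0, n, 4, dimnames = list(NULL, CHANNEL_NAMES))
  s2 <- sin(th)^2
  for (k in 1:4) {
    psi <- deg2rad(PSI_DEG[k])
    out[, k] <- 0.25 * params$g_psi[k] * it *
      (coeffs$X4 * (s2 * (params$f_psi[k] * coeffs$X1 * cos(2 * (ph - psi)) +
                            coeffs$X2) - (2 / 3) * coeffs$X2) + coeffs$X3)
  }
  out
}

#' Solve dipole orientation from four polarized intensities
#'
#' Closed-form inversion of the forward model. `phi` comes from the analytic
#' arctangent solution; given `phi` the model is linear in
#' `(Itot, Itot X4 sin^2 theta)`, which is solved by least squares over the
#' four channels (the exact algebraic inverse for noiseless input, and the
#' natural estimator when photon noise makes the 4x2 system inconsistent).
#' When noise pushes `sin^2 theta` above 1 the event is reported at
#' `theta = 90` degrees and flagged; below 0, at `theta = 0`.
#'
#' @param intensities Numeric length-4 vector (I0, I45, I90, I135) of mean
#'   photon counts, or a matrix with those four columns (one row per event).
#' @param params A [system_params()] object.
#' @param coeffs Optional precomputed [system_coefficients()].
#' @param n_photons Photons underlying each estimate; used for the
#'   uncertainty propagation (per-channel variance `2 I` under EMCCD excess
#'   noise). Defaults to the summed intensities.
#' @param propagate_sigma Compute delta-method `sigma_theta`, `sigma_phi`?
#' @return A data.frame with columns `theta_deg`, `phi_deg`, `itot`,
#'   `sigma_theta`, `sigma_phi`, `flag` (""/"theta_clipped"/"phi_undefined").
#' @export
solve_orientation <- function(intensities, params,
                              coeffs = system_coefficients(params),
                              n_photons = NULL, propagate_sigma = FALSE) {
  if (is.null(dim(intensities))) intensities <- matrix(intensities, nrow = 1)
  stopifnot(ncol(intensities) == 4)
  n <- nrow(intensities)
  out <- data.frame(theta_deg = numeric(n), phi_deg = numeric(n),
                    itot = numeric(n), sigma_theta = NA_real_,
                    sigma_phi = NA_real_, flag = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sol <- solve_orientation_one(intensities[i, ], params, coeffs)
    out$theta_deg[i] <- sol$theta_deg
    out$phi_deg[i] <- sol$phi_deg
    out$itot[i] <- sol$itot
    out$flag[i] <- sol$flag
    if (propagate_sigma) {
      np <- if (is.null(n_photons)) sum(intensities[i, ]) else n_photons[i]
      sg <- orientation_sigma(intensities[i, ], params, coeffs, np)
      out$sigma_theta[i] <- sg[1]
      out$sigma_phi[i] <- sg[2]
    }
  }
  out
}

solve_orientation_one <- function(I, params, coeffs) {
  if (all(abs(I) < 1e-300) || sum(I) <= 0) {
    stop("orientation undefined: non-positive total intensity")
  }
  f <- params$f_psi
  Ic <- I / params$g_psi          # undo per-channel response
  psi <- deg2rad(PSI_DEG)
  c2 <- cos(2 * psi)              # (1, 0, -1, 0)
  s2 <- sin(2 * psi)              # (0, 1, 0, -1)
  d0 <- Ic[1] - Ic[3]             # I0 - I90
  d45 <- Ic[2] - Ic[4]            # I45 - I135
  num <- d45 * (f[1] * c2[1] - f[3] * c2[3]) - d0 * (f[2] * c2[2] - f[4] * c2[4])
  den <- d0 * (f[2] * s2[2] - f[4] * s2[4]) - d45 * (f[1] * s2[1] - f[3] * s2[3])
  flag <- ""
  if (abs(num) < 1e-12 && abs(den) < 1e-12) {
    ph <- 0                       # theta ~ 0: phi undefined, fixed by convention
    flag <- "phi_undefined"
  } else {
    ph <- 0.5 * atan2(num, den)
  }
  phi_deg <- rad2deg(ph) %% 180
  if (180 - phi_deg < 1e-7) phi_deg <- 0

  # Linear solve for u = Itot and w = Itot * X4 * sin^2(theta).
  cpsi <- f * cos(2 * (deg2rad(phi_deg) - psi))
  B <- coeffs$X3 - (2 / 3) * coeffs$X2 * coeffs$X4
  A <- cbind(0.25 * (coeffs$X1 * cpsi + coeffs$X2), 0.25 * B)
  fit <- stats::lm.fit(A, Ic)
  w <- fit$coefficients[1]
  u <- fit$coefficients[2]
  if (!is.finite(u) || u <= 0) {
    # sin^2(theta) term carries all intensity (theta -> 90 with X2 = 0 case)
    u <- sum(Ic) / (B + coeffs$X4 * (coeffs$X1 * mean(cpsi) + coeffs$X2 / 3))
  }
  s2th <- w / (u * coeffs$X4)
  if (!is.finite(s2th)) s2th <- 0
  if (s2th > 1) {
    theta_deg <- 90
    flag <- paste0(flag, if (nzchar(flag)) "+" else "", "theta_clipped")
  } else if (s2th < 0) {
    theta_deg <- 0
    flag <- paste0(flag, if (nzchar(flag)) "+" else "", "theta_clipped")
  } else {
    theta_deg <- rad2deg(asin(sqrt(s2th)))
  }
  list(theta_deg = theta_deg, phi_deg = phi_deg, itot = u, flag = flag)
}

# Vectorized inversion for many intensity 4-vectors at once (used by the
# Monte-Carlo measurement floor and simulation studies). Same mathematics
# as solve_orientation_one: phi from the arctangent solution, then the
# 4x2 linear system solved via closed-form 2x2 normal equations per row.
# Returns theta/phi in degrees with theta clipped into [0, 90].
solve_orientation_batch <- function(I, params, coeffs) {
  f <- params$f_psi
  Ic <- sweep(I, 2, params$g_psi, "/")
  psi <- deg2rad(PSI_DEG)
  c2 <- cos(2 * psi); s2 <- sin(2 * psi)
  d0 <- Ic[, 1] - Ic[, 3]
  d45 <- Ic[, 2] - Ic[, 4]
  num <- d45 * (f[1] * c2[1] - f[3] * c2[3]) - d0 * (f[2] * c2[2] - f[4] * c2[4])
  den <- d0 * (f[2] * s2[2] - f[4] * s2[4]) - d45 * (f[1] * s2[1] - f[3] * s2[3])
  ph <- 0.5 * atan2(num, den)
  phi_deg <- rad2deg(ph) %% 180
  B <- coeffs$X3 - (2 / 3) * coeffs$X2 * coeffs$X4
  # design columns per row: a1_k = (X1 f_k cos(2(phi - psi_k)) + X2)/4,
  # a2 = B/4 (constant across channels)
  a2 <- 0.25 * B
  cphi <- matrix(0, nrow(I), 4)
  for (k in 1:4) {
    cphi[, k] <- 0.25 * (coeffs$X1 * f[k] * cos(2 * (deg2rad(phi_deg) - psi[k])) +
                           coeffs$X2)
  }
  s11 <- rowSums(cphi^2)
  s12 <- rowSums(cphi) * a2
  s22 <- 4 * a2^2
  b1 <- rowSums(cphi * Ic)
  b2 <- a2 * rowSums(Ic)
  det_ <- s11 * s22 - s12^2
  w <- (s22 * b1 - s12 * b2) / det_
  u <- (s11 * b2 - s12 * b1) / det_
  s2th <- w / (u * coeffs$X4)
  s2th[!is.finite(s2th)] <- 0
  theta_deg <- rad2deg(asin(sqrt(clamp(s2th, 0, 1))))
  list(theta_deg = theta_deg, phi_deg = phi_deg, itot = u,
       clipped = s2th > 1 | s2th < 0)
}

# Delta-method angle uncertainties. Per-channel variance of a mean over an
# event is 2*I/nframes-equivalent; callers supply the photon total so the
# variance of the per-frame mean intensity is 2*I_psi * (I_psi/total share).
orientation_sigma <- function(I, params, coeffs, n_photons) {
  tot <- sum(I)
  if (tot <= 0 || n_photons <= 0) return(c(NA_real_, NA_real_))
  # variance of the event-mean channel intensity, EMCCD excess factor 2:
  # counts over the event are ~2x overdispersed Poisson; mean over nf frames
  # with per-frame intensity I has var 2*I/nf = 2*I^2*... expressed via the
  # event photon total: var(mean_psi) = 2 * I_psi * (tot / n_photons) / 1
  scale_ <- tot / n_photons
  v <- 2 * I * scale_
  eps <- pmax(1e-4 * I, 1e-6)
  base <- solve_orientation_one(I, params, coeffs)
  J <- matrix(0, 2, 4)
  for (k in 1:4) {
    Ip <- I; Ip[k] <- Ip[k] + eps[k]
    sp <- solve_orientation_one(Ip, params, coeffs)
    dth <- sp$theta_deg - base$theta_deg
    dph <- (sp$phi_deg - base$phi_deg + 90) %% 180 - 90
    J[1, k] <- dth / eps[k]
    J[2, k] <- dph / eps[k]
  }
  sig2 <- J^2 %*% v
  sqrt(pmax(as.numeric(sig2), 0))
}

#' Resolve the quarter-sphere degeneracy across a molecule's events
#'
#' Each solved orientation is determined only up to the degenerate branches
#' (theta, 180 - theta) x (phi, 180 + phi). For a single molecule whose state
#' changes are small (tens of degrees), the true orientations lie within one
#' quarter sphere; the branch per event is chosen to minimize the total
#' angular variance of the molecule's events, and the solution is mapped to
#' the quarter sphere containing the mean direction.
#'
#' @param theta_deg,phi_deg Event orientations, degrees.
#' @param exhaustive Search all `4^n` branch combinations (oracle; only
#'   sensible for very few events). Default uses iterated alignment.
#' @return Data.frame with resolved `theta_deg`, `phi_deg` and the unit
#'   vectors `x`, `y`, `z`.
#' @export
resolve_degeneracy <- function(theta_deg, phi_deg, exhaustive = FALSE) {
  n <- length(theta_deg)
  V <- sph_to_cart(theta_deg, phi_deg)
  branch <- function(v, b) {
    switch(b,
           v,
           c(v[1], v[2], -v[3]),     # theta -> 180 - theta
           c(-v[1], -v[2], v[3]),    # phi -> phi + 180
           -v)                       # both (antipode)
  }
  if (n == 1) {
    sph <- cart_to_sph(V)
    return(data.frame(theta_deg = sph$theta_deg, phi_deg = sph$phi_deg,
                      x = V[, 1], y = V[, 2], z = V[, 3]))
  }
  obj <- function(W) {
    m <- unit(colMeans(W))
    sum((W - matrix(m, n, 3, byrow = TRUE))^2)
  }
  if (exhaustive) {
    if (n > 8) stop("exhaustive branch search limited to 8 events")
    grid <- as.matrix(expand.grid(rep(list(1:4), n)))
    best <- NULL; best_obj <- Inf
    for (r in seq_len(nrow(grid))) {
      W <- t(vapply(seq_len(n), function(i) branch(V[i, ], grid[r, i]),
                    numeric(3)))
      o <- obj(W)
      if (o < best_obj) { best_obj <- o; best <- W }
    }
    W <- best
  } else {
    W <- V
    m <- W[which.max(rowSums(abs(W))), ]
    for (iter in 1:50) {
      changed <- FALSE
      for (i in seq_len(n)) {
        cand <- vapply(1:4, function(b) sum(branch(V[i, ], b) * m), numeric(1))
        b <- which.max(cand)
        w <- branch(V[i, ], b)
        if (any(abs(w - W[i, ]) > 1e-12)) { W[i, ] <- w; changed <- TRUE }
      }
      m <- unit(colMeans(W))
      if (!changed) break
    }
  }
  # canonical quarter sphere: mean direction with z >= 0 and phi in [0, 180)
  m <- unit(colMeans(W))
  if (m[3] < 0) W[, 3] <- -W[, 3]
  m <- unit(colMeans(W))
  if (m[2] < 0) { W[, 1] <- -W[, 1]; W[, 2] <- -W[, 2] }
  sph <- cart_to_sph(W)
  data.frame(theta_deg = sph$theta_deg, phi_deg = sph$phi_deg,
             x = W[, 1], y = W[, 2], z = W[, 3])
}

#' Build the per-event table from a photon trace and detected transitions
#'
#' Averages the four channel photon counts over each dwell (the segment
#' between consecutive detected transitions), solves the orientation from the
#' event means, and reports per-event dwell time and SNR. Frames at or after
#' a bleach point are excluded.
#'
#' @param photons A `photon_trace` from [counts_to_photons()], or a numeric
#'   matrix of per-frame photon counts with 4 columns.
#' @param transitions A `transition_set` from [detect_transitions()], or an
#'   integer vector of changepoint frame indices (a changepoint at `i` means
#'   the new segment starts at frame `i + 1`).
#' @param params A [system_params()] object.
#' @param frame_interval Frame interval in seconds (taken from `photons` when
#'   it is a `photon_trace`).
#' @param bleach_frame Last pre-bleach frame; `Inf` keeps the whole trace.
#' @param resolve Apply [resolve_degeneracy()] across the trace's events.
#' @return Data.frame of class `event_table`: `event`, `start`, `end`
#'   (half-open frame indices), `dwell_ms`, `mean_I0`..`mean_I135`,
#'   `theta_deg`, `phi_deg`, `itot`, `n_photons`, `snr`, `flag`.
#' @export
build_event_table <- function(photons, transitions, params,
                              frame_interval = NULL, bleach_frame = Inf,
                              resolve = TRUE) {
  if (inherits(photons, "photon_trace")) {
    if (is.null(frame_interval)) frame_interval <- photons$frame_interval
    mat <- photons$photons
  } else {
    mat <- photons
    if (is.null(frame_interval)) frame_interval <- 0.01
  }
  cps <- if (inherits(transitions, "transition_set")) transitions$changepoints
         else as.integer(transitions)
  nf <- min(nrow(mat), bleach_frame)
  cps <- cps[cps > 0 & cps < nf]
  bounds <- c(0L, sort(unique(as.integer(cps))), as.integer(nf))
  ne <- length(bounds) - 1
  rows <- vector("list", ne)
  for (e in seq_len(ne)) {
    a <- bounds[e] + 1L; b <- bounds[e + 1L]
    if (b < a) next
    seg <- mat[a:b, , drop = FALSE]
    mI <- colMeans(seg)
    npho <- sum(seg)
    sol <- tryCatch(solve_orientation(mI, params, n_photons = npho,
                                      propagate_sigma = TRUE),
                    error = function(e) NULL)
    if (is.null(sol)) next
    sig2d <- sqrt(sol$sigma_theta^2 +
                    (sol$sigma_phi * sin(deg2rad(sol$theta_deg)))^2)
    rows[[e]] <- data.frame(
      event = e, start = a - 1L, end = b, dwell_ms = (b - a + 1L) * frame_interval * 1000,
      mean_I0 = mI[1], mean_I45 = mI[2], mean_I90 = mI[3], mean_I135 = mI[4],
      theta_deg = sol$theta_deg, phi_deg = sol$phi_deg, itot = sol$itot,
      n_photons = npho, snr = sqrt(max(mean(rowSums(seg)), 0) / 2),
      sigma_theta = sol$sigma_theta, sigma_phi = sol$sigma_phi,
      sigma_2d = sig2d, flag = sol$flag, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (resolve && nrow(tab) > 1) {
    res <- resolve_degeneracy(tab$theta_deg, tab$phi_deg)
    tab$theta_deg <- res$theta_deg
    tab$phi_deg <- res$phi_deg
  }
  class(tab) <- c("event_table", "data.frame")
  tab
}
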