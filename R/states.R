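# Sorting dwell events into conformational states on the unit sphere.
# Events are embedded as unit vectors (equal weighting of all three spatial
# dimensions) and partitioned by nearest-neighbor distance
# d_{i,k} = || x_i - m_k || minimized over k cluster means; the summed
# squared distance is optimized by k-means under simulated annealing
# restarts with Nelder-Mead refinement. The number of resolvable states is
# the largest k for which every pair of state populations is separated by at
# least 2.5 pooled sigma; consecutive same-state events are merged as
# changepoint false positives.

#' Embed event orientations on the unit sphere
#' @param theta_deg,phi_deg Event angles, degrees.
#' @return n x 3 matrix of unit vectors.
#' @export
embed_events <- function(theta_deg, phi_deg) sph_to_cart(theta_deg, phi_deg)

# Squared Euclidean distance between unit vectors: ||x - m||^2 = 2 - 2<x, m>,
# so nearest-mean assignment reduces to one inner-product matrix.
cluster_objective <- function(X, means) {
  S <- X %*% t(means)
  a <- max.col(S, ties.method = "first")
  list(obj = sum(2 - 2 * S[cbind(seq_len(nrow(X)), a)]), assign = a)
}

lloyd_steps <- function(X, means, max_iter = 50) {
  k <- nrow(means)
  for (it in seq_len(max_iter)) {
    a <- max.col(X %*% t(means), ties.method = "first")
    Mp <- rowsum(X, a)
    M <- matrix(0, k, 3)
    M[as.integer(rownames(Mp)), ] <- Mp
    nrm <- sqrt(rowSums(M^2))
    new_means <- means
    ok <- is.finite(nrm) & nrm > 1e-12
    new_means[ok, ] <- M[ok, , drop = FALSE] / nrm[ok]
    if (max(abs(new_means - means)) < 1e-12) break
    means <- new_means
  }
  means
}

means_from_par <- function(par) {
  k <- length(par) / 2
  sph_to_cart(rad2deg(par[seq_len(k)]), rad2deg(par[k + seq_len(k)]))
}

#' k-means clustering of events on the unit sphere
#'
#' Minimizes the summed squared Euclidean distance between event unit
#' vectors and unit-norm cluster means (centroids are renormalized after
#' each update). The optimization runs k-means from simulated-annealing
#' restarts (geometric cooling, factor 0.95 over 50 temperatures, 20
#' restarts by default) and refines the best solution with a Nelder-Mead
#' simplex over the means' spherical coordinates. Deterministic given
#' `seed`.
#'
#' @param X n x 3 matrix of event unit vectors (see [embed_events()]).
#' @param k Number of states (1 <= k <= n).
#' @param seed RNG seed.
#' @param n_restarts,n_temps,cool Annealing schedule controls.
#' @return Object of class `state_model`: list with `k`, `means` (k x 3 unit
#'   vectors), `assignments`, `objective`, per-state `sigma_deg` (RMS
#'   angular deviation), `n` per state.
#' @export
cluster_states <- function(X, k, seed = 1, n_restarts = 20, n_temps = 50,
                           cool = 0.95) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of events")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best_means <- NULL; best_obj <- Inf
  if (k == 1) {
    best_means <- matrix(unit(colMeans(X)), 1, 3)
    best_obj <- cluster_objective(X, best_means)$obj
  } else {
    # k-means++ seeding: subsequent centers drawn with probability
    # proportional to squared distance from the nearest chosen center
    kpp_init <- function() {
      centers <- matrix(0, k, 3)
      centers[1, ] <- X[sample.int(n, 1), ]
      if (k > 1) {
        for (j in 2:k) {
          S <- X %*% t(centers[seq_len(j - 1), , drop = FALSE])
          d2 <- 2 - 2 * apply(S, 1, max)
          d2 <- pmax(d2, 1e-12)
          centers[j, ] <- X[sample.int(n, 1, prob = d2), ]
        }
      }
      centers
    }
    for (r in seq_len(n_restarts)) {
      init <- kpp_init()
      means <- lloyd_steps(X, init)
      cur_obj <- cluster_objective(X, means)$obj
      if (cur_obj < best_obj) { best_obj <- cur_obj; best_means <- means }
      # annealed perturbation walk around the current solution; accepted
      # moves are polished by a short Lloyd descent; the walk stops once
      # it stagnates
      temp <- 0.1
      stagnant <- 0L
      for (t in seq_len(n_temps)) {
        if (stagnant >= 25L) break
        j <- sample.int(k, 1)
        prop <- means
        ax <- stats::rnorm(3)
        prop[j, ] <- as.numeric(
          rotation_about_axis(ax, stats::rnorm(1, 0, rad2deg(temp) / 4)) %*% means[j, ])
        prop_obj <- cluster_objective(X, prop)$obj
        if (prop_obj < cur_obj) {
          # improving move: polish with a short Lloyd descent
          prop <- lloyd_steps(X, prop, max_iter = 5)
          means <- prop
          cur_obj <- cluster_objective(X, prop)$obj
        } else if (stats::runif(1) < exp((cur_obj - prop_obj) / max(temp, 1e-9))) {
          means <- prop
          cur_obj <- prop_obj
        }
        if (cur_obj < best_obj - 1e-12) {
          best_obj <- cur_obj; best_means <- means; stagnant <- 0L
        } else {
          stagnant <- stagnant + 1L
        }
        temp <- temp * cool
      }
    }
    # Nelder-Mead refinement of the best means in spherical coordinates
    sph <- cart_to_sph(best_means)
    par0 <- c(deg2rad(sph$theta_deg), deg2rad(sph$phi_deg))
    nm <- stats::optim(par0, function(p) cluster_objective(X, means_from_par(p))$obj,
                       method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-10))
    if (nm$value <= best_obj) {
      best_means <- means_from_par(nm$par)
      best_means <- lloyd_steps(X, best_means, max_iter = 20)
      best_obj <- cluster_objective(X, best_means)$obj
    }
  }
  ca <- cluster_objective(X, best_means)
  sigma <- vapply(seq_len(k), function(j) {
    idx <- ca$assign == j
    nj <- sum(idx)
    if (nj < 2) return(NA_real_)
    sqrt(sum(angular_distance(X[idx, , drop = FALSE], best_means[j, ])^2) /
           (nj - 1))
  }, numeric(1))
  structure(list(k = k, means = best_means, assignments = ca$assign,
                 objective = ca$obj, sigma_deg = sigma,
                 n = tabulate(ca$assign, k), seed = seed),
            class = "state_model")
}

# Tangent-plane axes at a point m on the unit sphere: unit vectors along
# increasing theta and increasing phi.
tangent_axes <- function(m) {
  zc <- cross3(c(0, 0, 1), m)
  if (sqrt(sum(zc^2)) < 1e-9) zc <- c(0, 1, 0)   # at the pole: any direction
  phi_hat <- unit(zc)
  theta_hat <- unit(cross3(phi_hat, m))
  list(theta_hat = theta_hat, phi_hat = phi_hat)
}

# Measurement-noise floor for one state along a direction, by parametric
# Monte Carlo through the orientation solver: simulate photon-noise
# replicates of a typical member event (Poisson rates with EMCCD excess
# noise), re-solve, fold each estimate onto the branch nearest the state
# mean, and take the spread of the projections. This captures the true
# sampling spread of the estimator, including the compression where the
# inclination solution saturates at theta = 90.
measurement_floor_mc <- function(rates, n_frames, m_vec, u_hat, params,
                                 coeffs, n_sim = 60) {
  lam <- pmax(rates, 1e-9) * n_frames
  N <- matrix(stats::rpois(n_sim * 4, rep(lam, each = n_sim)), n_sim, 4)
  amp <- matrix(0, n_sim, 4)
  pos <- N > 0
  amp[pos] <- stats::rgamma(sum(pos), shape = N[pos], scale = 1)
  mI <- amp / n_frames
  ok <- rowSums(mI) > 0
  if (sum(ok) < 10) return(NA_real_)
  sol <- solve_orientation_batch(mI[ok, , drop = FALSE], params, coeffs)
  V <- sph_to_cart(sol$theta_deg, sol$phi_deg)
  # fold each estimate onto the degeneracy branch nearest the state mean
  sx <- sign(V[, 1] * m_vec[1] + V[, 2] * m_vec[2])
  sz <- sign(V[, 3] * m_vec[3])
  sx[sx == 0] <- 1; sz[sz == 0] <- 1
  Vb <- cbind(V[, 1] * sx, V[, 2] * sx, V[, 3] * sz)
  dev <- Vb - matrix(m_vec, nrow(Vb), 3, byrow = TRUE)
  proj <- rad2deg(dev %*% u_hat)
  stats::sd(proj)
}

#' Pairwise state separations in units of pooled sigma
#'
#' For each pair of states, the great-circle separation Omega of the two
#' means divided by the pooled width of the two populations. When a
#' measurement model is supplied (`X`, `event_channels`, `event_frames`,
#' `params`), the width is measured along the direction connecting the two
#' means: theta and phi are measured with very different precision (the
#' inclination loses sensitivity near the sample plane), and a pair cleanly
#' separated along the precise direction must not be vetoed by noise in the
#' orthogonal one. Per state the directional width is a tail-robust
#' (median-absolute-deviation) spread of the events' projected deviations,
#' floored at the Monte-Carlo measurement spread of a typical member event
#' along that direction; the floor keeps chance-tight sub-clusters of a
#' single true state from passing the criterion.
#'
#' Without a measurement model, the pooled width is estimated isotropically
#' and without using the assignment boundaries: the mean squared angular
#' deviation of all events about the global centroid decomposes into the
#' between-means term and the pooled within-state variance, and subtracting
#' the former avoids the truncation bias of per-state spreads (events are
#' assigned to the nearest mean, which clips each state's distribution at
#' the midplanes and understates sigma whenever a single population is cut
#' into pieces). `X` is required in this mode too; without it the
#' per-state `sigma_deg` values stored in the model are pooled.
#'
#' @param model A `state_model`.
#' @param X Optional n x 3 matrix of the clustered event unit vectors.
#' @param event_channels Optional n x 4 matrix of per-event mean photon
#'   counts per frame per channel; together with `event_frames` and
#'   `params` it enables the Monte-Carlo measurement floor.
#' @param event_frames Optional per-event frame counts.
#' @param params Optional [system_params()] for the measurement floor.
#' @param floor_seed RNG seed for the Monte-Carlo floor (deterministic
#'   criterion evaluation).
#' @return Data.frame with `i`, `j`, `omega_deg`, `pooled_sigma_deg`, `ratio`.
#' @export
state_separations <- function(model, X = NULL, event_channels = NULL,
                              event_frames = NULL, params = NULL,
                              floor_seed = 1) {
  k <- model$k
  if (k < 2) return(data.frame(i = integer(0), j = integer(0),
                               omega_deg = numeric(0),
                               pooled_sigma_deg = numeric(0), ratio = numeric(0)))
  use_floor <- !is.null(event_channels) && !is.null(event_frames) &&
    !is.null(params)
  coeffs <- if (use_floor) system_coefficients(params)
  if (use_floor) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(floor_seed)
  }
  pairs <- utils::combn(k, 2)
  sigma_global <- NA_real_
  if (!use_floor && !is.null(X)) {
    ctr <- unit(colMeans(X))
    msd <- mean(angular_distance(X, ctr)^2)
    between <- sum(model$n * angular_distance(model$means, ctr)^2) / sum(model$n)
    sigma_global <- sqrt(max(msd - between, 1e-6))
  }
  proj_sigma <- function(s, u_hat) {
    idx <- which(model$assignments == s)
    m <- model$means[s, ]
    dev <- X[idx, , drop = FALSE] - matrix(m, length(idx), 3, byrow = TRUE)
    proj <- rad2deg(dev %*% u_hat)
    rob <- 1.4826 * stats::median(abs(proj - stats::median(proj)))
    rates <- apply(event_channels[idx, , drop = FALSE], 2, stats::median)
    nf <- stats::median(event_frames[idx])
    fl <- measurement_floor_mc(rates, nf, m, u_hat, params, coeffs)
    if (is.finite(fl)) rob <- max(rob, fl)
    rob
  }
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    om <- angular_distance(model$means[i, ], model$means[j, ])
    ni <- model$n[i]; nj <- model$n[j]
    if (use_floor) {
      d <- model$means[j, ] - model$means[i, ]
      si <- {
        m <- model$means[i, ]
        u <- d - sum(d * m) * m
        proj_sigma(i, unit(u))
      }
      sj <- {
        m <- model$means[j, ]
        u <- d - sum(d * m) * m
        proj_sigma(j, unit(u))
      }
      ps <- if (is.na(si) || is.na(sj)) NA_real_
            else sqrt((ni * si^2 + nj * sj^2) / (ni + nj))
    } else if (!is.null(X)) {
      ps <- sigma_global
    } else {
      si <- model$sigma_deg[i]; sj <- model$sigma_deg[j]
      ps <- if (is.na(si) || is.na(sj)) NA_real_
            else sqrt((ni * si^2 + nj * sj^2) / (ni + nj))
    }
    c(i, j, om, ps, om / ps)
  })
  out <- as.data.frame(t(out))
  names(out) <- c("i", "j", "omega_deg", "pooled_sigma_deg", "ratio")
  out
}

#' Select the number of resolvable states by the 2.5-sigma criterion
#'
#' Fits k = 1 .. `k_max` state models one at a time and returns the largest
#' k for which every state is populated (>= `min_state_events` events) and
#' every pair of state means is separated by at least `sigma_mult` pooled
#' sigma. A state population cannot be narrower than the angle-measurement
#' noise of its events, so when per-event measurement sigmas are supplied
#' each state's sigma is floored at the median measurement sigma of its
#' members; this stops chance-tight sub-clusters of a true state from
#' passing the criterion at too-large k. The returned model is ordered by
#' the shortest-path rule when k >= 2.
#'
#' @param X n x 3 matrix of event unit vectors.
#' @param k_max Largest k examined (default 6).
#' @param seed RNG seed.
#' @param sigma_mult Separation criterion multiplier (default 2.5).
#' @param min_state_events Minimum events per state (default 3, needed for a
#'   meaningful spread estimate).
#' @param event_channels,event_frames,params Optional per-event mean channel
#'   photon counts (n x 4), frame counts, and the [system_params()]: when
#'   supplied, the separation criterion floors each state's directional
#'   width at its Monte-Carlo measurement spread (see
#'   [state_separations()]).
#' @param max_outlier_frac Largest fraction of events that may be set aside
#'   as stray (contaminated) events when a fit strands a cluster on fewer
#'   than `min_state_events` events.
#' @param ... Passed to [cluster_states()].
#' @return The selected `state_model` (with `$separations` attached).
#' @export
select_k <- function(X, k_max = 6, seed = 1, sigma_mult = 2.5,
                     min_state_events = 3, event_channels = NULL,
                     event_frames = NULL, params = NULL,
                     max_outlier_frac = 0.25, ...) {
  X <- as.matrix(X)
  n_all <- nrow(X)
  k_max <- min(k_max, n_all)
  # Fit k states; when a fit spends a cluster on a handful of stray events
  # (contaminated dwells), drop those events and refit so real states are
  # not starved of a cluster. At most `max_outlier_frac` of events may be
  # set aside.
  fit_k <- function(k) {
    keep <- rep(TRUE, n_all)
    for (round in 1:5) {
      if (k > sum(keep)) return(NULL)
      m <- cluster_states(X[keep, , drop = FALSE], k, seed = seed + k, ...)
      small <- which(m$n < min_state_events)
      if (length(small) == 0) {
        m$kept <- which(keep)
        return(m)
      }
      drop_idx <- which(keep)[m$assignments %in% small]
      if ((n_all - sum(keep) + length(drop_idx)) > max_outlier_frac * n_all) {
        return(NULL)
      }
      keep[drop_idx] <- FALSE
    }
    NULL
  }
  sep_for <- function(m) {
    idx <- m$kept
    state_separations(
      m, X = X[idx, , drop = FALSE],
      event_channels = if (is.null(event_channels)) NULL
                       else event_channels[idx, , drop = FALSE],
      event_frames = event_frames[idx],
      params = params, floor_seed = seed + 1000L)
  }
  best <- cluster_states(X, 1, seed = seed, ...)
  best$kept <- seq_len(n_all)
  for (k in 2:k_max) {
    if (k > n_all) break
    m <- fit_k(k)
    if (is.null(m)) next
    sep <- sep_for(m)
    if (any(!is.finite(sep$ratio))) next
    if (all(sep$ratio >= sigma_mult)) best <- m
  }
  kept <- best$kept
  if (best$k >= 2) best <- order_states(best)
  best$kept <- kept
  best$separations <- sep_for(best)
  # assign every event (outliers included) to the final means
  d2 <- vapply(seq_len(best$k), function(j) {
    rowSums((X - matrix(best$means[j, ], n_all, 3, byrow = TRUE))^2)
  }, numeric(n_all))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  best$assignments <- max.col(-d2, ties.method = "first")
  best$n <- tabulate(best$assignments, best$k)
  best
}

#' Merge consecutive same-state events
#'
#' Transitions between two consecutive events assigned to the same state are
#' changepoint false positives; the events are merged (photon totals and
#' dwells summed, channel means dwell-weighted) and the orientation re-solved
#' from the merged means.
#'
#' @param events An [build_event_table()] data.frame.
#' @param assignments State label per event.
#' @param params [system_params()] used to re-solve merged orientations.
#' @param frame_interval Frame interval, s (for the per-event SNR).
#' @return List with `events` (merged table, including `state`) and
#'   `assignments`.
#' @export
merge_consecutive_events <- function(events, assignments, params,
                                     frame_interval = 0.01) {
  stopifnot(nrow(events) == length(assignments))
  run <- cumsum(c(1L, diff(assignments) != 0))
  idx <- split(seq_len(nrow(events)), run)
  rows <- lapply(idx, function(ii) {
    e <- events[ii, , drop = FALSE]
    w <- e$dwell_ms
    mI <- c(sum(e$mean_I0 * w), sum(e$mean_I45 * w),
            sum(e$mean_I90 * w), sum(e$mean_I135 * w)) / sum(w)
    sol <- solve_orientation(mI, params)
    data.frame(event = e$event[1], start = min(e$start), end = max(e$end),
               dwell_ms = sum(e$dwell_ms),
               mean_I0 = mI[1], mean_I45 = mI[2], mean_I90 = mI[3],
               mean_I135 = mI[4], theta_deg = sol$theta_deg,
               phi_deg = sol$phi_deg, itot = sol$itot,
               n_photons = sum(e$n_photons),
               snr = sqrt(sum(e$n_photons) /
                            (sum(e$dwell_ms) / (frame_interval * 1000)) / 2),
               flag = sol$flag,
               state = assignments[ii[1]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$event <- seq_len(nrow(out))
  rownames(out) <- NULL
  list(events = out, assignments = out$state)
}

#' Repair per-state degeneracy branches after clustering
#'
#' Event-level degeneracy resolution can trap an entire state in the wrong
#' branch when states are tens of degrees apart: the state is internally
#' consistent but sits at the mirrored position relative to the molecule's
#' other states. Since all true states of one molecule lie within a
#' quarter sphere, each state's events are re-folded through the branch
#' (identity, z-mirror, 180-degree in-plane rotation, antipode) that brings
#' the state mean closest to the resultant of the other states' means,
#' iterating until stable.
#'
#' @param theta_deg,phi_deg Event orientations (degrees).
#' @param states State label per event.
#' @param k Number of states.
#' @return List with repaired `theta_deg`, `phi_deg`, and `means`
#'   (k x 3 unit vectors recomputed from the repaired events).
#' @export
repair_state_branches <- function(theta_deg, phi_deg, states, k) {
  V <- embed_events(theta_deg, phi_deg)
  branch_op <- function(W, b) {
    switch(b,
           W,
           cbind(W[, 1], W[, 2], -W[, 3]),
           cbind(-W[, 1], -W[, 2], W[, 3]),
           -W)
  }
  state_mean <- function(W, idx) {
    m <- colMeans(W[idx, , drop = FALSE])
    n <- sqrt(sum(m^2))
    if (n < 1e-12) c(0, 0, 1) else m / n
  }
  if (k >= 2) {
    for (pass in 1:3) {
      means <- t(vapply(seq_len(k), function(s) state_mean(V, states == s),
                        numeric(3)))
      changed <- FALSE
      for (s in seq_len(k)) {
        idx <- which(states == s)
        if (length(idx) == 0) next
        others <- colSums(means[-s, , drop = FALSE])
        if (sqrt(sum(others^2)) < 1e-9) next
        others <- others / sqrt(sum(others^2))
        scores <- vapply(1:4, function(b) {
          sum(state_mean(branch_op(V, b), idx) * others)
        }, numeric(1))
        b <- which.max(scores)
        if (b != 1L) {
          V[idx, ] <- branch_op(V[idx, , drop = FALSE], b)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  means <- t(vapply(seq_len(k), function(s) state_mean(V, states == s),
                    numeric(3)))
  sph <- cart_to_sph(V)
  list(theta_deg = sph$theta_deg, phi_deg = sph$phi_deg, means = means)
}

path_delta <- function(means, ord) {
  k <- length(ord)
  d <- function(i, j) sqrt(sum((means[i, ] - means[j, ])^2))
  tot <- sum(vapply(seq_len(k - 1), function(t) d(ord[t], ord[t + 1]), numeric(1)))
  tot - d(ord[1], ord[k])
}

#' Index states by the shortest-path rule
#'
#' Among all orderings of the k state means, chooses the one minimizing the
#' excess of the cumulative adjacent-state path length over the end-to-end
#' distance (`delta_d = sum d_{i,i+1} - d_{1,k}`). The two traversal
#' directions tie exactly; the direction is fixed by the handedness of the
#' state geometry itself — the one that puts the intermediate states above
#' the local C1/C4 plane (positive local z) is chosen, so that indexing is
#' consistent across molecules no matter how each sits in the lab frame.
#' For (near-)planar geometries the endpoint with the larger lab-frame
#' z-component becomes state 1 instead. Biological identity is assigned
#' later by structure matching.
#'
#' @param model A `state_model` with k >= 2.
#' @return The model with means, sigmas, counts and assignments relabelled,
#'   plus `order_delta_d`.
#' @export
order_states <- function(model) {
  k <- model$k
  stopifnot(k >= 2)
  perms <- all_permutations(k)
  deltas <- apply(perms, 1, function(ord) path_delta(model$means, ord))
  best <- perms[which.min(deltas), ]
  # direction: handedness of the geometry in its own frame
  mid_z <- function(ord) {
    F <- tryCatch(build_local_frame(model$means[ord, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(F) || k < 3) return(0)
    sum((model$means[ord[2:(k - 1)], , drop = FALSE] %*% unclass(F)["Z", ]))
  }
  zf <- mid_z(best)
  zr <- mid_z(rev(best))
  if (zr > zf + 1e-9) {
    best <- rev(best)
  } else if (abs(zr - zf) <= 1e-9 &&
             model$means[best[1], 3] < model$means[best[k], 3]) {
    best <- rev(best)
  }
  relabel <- match(seq_len(k), best)
  out <- model
  out$means <- model$means[best, , drop = FALSE]
  out$sigma_deg <- model$sigma_deg[best]
  out$n <- model$n[best]
  out$assignments <- relabel[model$assignments]
  out$order_delta_d <- min(deltas)
  out
}
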