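# Shared fixtures built in code. The changepoint threshold table is
# calibrated once per test run and reused (null-simulation calibration is
# the expensive step).

reference_params <- function() system_params(alpha = 70)

the <- new.env()

cp_config_snr7 <- function() {
  if (is.null(the$cp7)) {
    the$cp7 <- calibrate_threshold_table(7, n_sim = 1000, seed = 7101)
  }
  the$cp7
}

cp_config_snr7_1ch <- function() {
  if (is.null(the$cp7_1)) {
    the$cp7_1 <- calibrate_threshold_table(7, n_sim = 1000, seed = 7201, h = 1)
  }
  the$cp7_1
}

# Four-channel Poisson counts with EMCCD excess noise at constant rates.
sim_counts <- function(rates, n_frames, seed = 1) {
  withr::with_seed(seed, {
    N <- matrix(stats::rpois(n_frames * length(rates),
                             rep(rates, each = n_frames)),
                n_frames, length(rates))
    pos <- N > 0
    N[pos] <- stats::rgamma(sum(pos), shape = N[pos], scale = 1)
    N
  })
}

# Exhaustive best 2-partition of unit vectors under the clustering
# objective (normalized centroids, summed squared distances).
brute_force_2partition <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (!any(grp) || all(grp)) next
    obj <- 0
    for (g in list(grp, !grp)) {
      m <- colMeans(X[g, , drop = FALSE])
      m <- m / sqrt(sum(m^2))
      obj <- obj + sum((X[g, , drop = FALSE] -
                          matrix(m, sum(g), 3, byrow = TRUE))^2)
    }
    best <- min(best, obj)
  }
  best
}

# Events drawn on the sphere around given state means. `sigma_deg` is the
# RMS angular deviation: isotropic Gaussian noise in the tangent plane with
# per-axis sd sigma/sqrt(2).
sim_sphere_events <- function(means, n_per_state, sigma_deg, seed = 1) {
  withr::with_seed(seed, {
    out <- lapply(seq_len(nrow(means)), function(s) {
      m <- means[s, ]
      ax <- polstates:::tangent_axes(m)
      s_rad <- sigma_deg * pi / 180 / sqrt(2)
      t(vapply(seq_len(n_per_state), function(i) {
        d <- stats::rnorm(2, 0, s_rad)
        v <- as.numeric(m + d[1] * ax$theta_hat + d[2] * ax$phi_hat)
        v / sqrt(sum(v^2))
      }, numeric(3)))
    })
    list(X = do.call(rbind, out),
         labels = rep(seq_len(nrow(means)), each = n_per_state))
  })
}
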