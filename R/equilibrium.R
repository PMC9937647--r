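# Eight-state ligand-binding equilibrium model: four apo conformations
# C1..C4 and four ligand-bound ones C1.L..C4.L. With C1 as reference,
# K_{i,1} = [Ci]/[C1], LK_{i,1} = [Ci.L]/[C1.L], K_{Di} = [Ci][L]/[Ci.L],
# and K_{1,1} = LK_{1,1} = 1 by definition. The probability of conformation i
# (bound or not) at ligand concentration [L] is
#
#   p_i = ( K_{i,1} + LK_{i,1} [L]/K_{D1} ) / ( sum_j K_{j,1} + sum_j LK_{j,1} [L]/K_{D1} )
#
# so p_i(0) = K_{i,1}/sum K and p_i(Inf) = LK_{i,1}/sum LK, and the
# thermodynamic cycle gives K_{Di} = K_{D1} K_{i,1} / LK_{i,1}.

#' Equilibrium parameters of the eight-state model
#'
#' @param K Apo equilibrium constants `K_{2,1}, K_{3,1}, K_{4,1}` (length 3;
#'   `K_{1,1} = 1` is implicit) or length 4 starting with 1.
#' @param LK Ligand-bound constants, same convention.
#' @param KD1 Dissociation constant of state 1, in the concentration unit of
#'   the data (micromolar throughout this package).
#' @return Object of class `equilibrium_params` with fields `K`, `LK`
#'   (length-4, leading 1), `KD1`, and derived `KD` (per-state dissociation
#'   constants) and limiting probabilities `p0`, `pinf`.
#' @export
equilibrium_params <- function(K, LK, KD1) {
  fix <- function(x, nm) {
    if (length(x) == 3) x <- c(1, x)
    if (length(x) != 4 || abs(x[1] - 1) > 1e-12) {
      stop(nm, " must be 3 constants relative to state 1, or length 4 starting with 1")
    }
    if (any(x <= 0)) stop(nm, " must be positive")
    x
  }
  K <- fix(K, "K"); LK <- fix(LK, "LK")
  stopifnot(KD1 > 0)
  structure(list(K = K, LK = LK, KD1 = KD1,
                 KD = KD1 * K / LK,
                 p0 = K / sum(K), pinf = LK / sum(LK)),
            class = "equilibrium_params")
}

#' Reference equilibrium parameters
#'
#' The apo constants (2.566, 0.923, 0.729), bound constants
#' (1.795, 1.782, 1.250) and `KD1 = 49` uM used as the synthetic ground truth
#' throughout the package.
#' @return An [equilibrium_params()] object.
#' @export
reference_equilibrium_params <- function() {
  equilibrium_params(K = c(2.566, 0.923, 0.729),
                     LK = c(1.795, 1.782, 1.250),
                     KD1 = 49)
}

#' State probabilities at given ligand concentrations
#'
#' @param params An [equilibrium_params()] object.
#' @param concentration_uM Ligand concentration(s), >= 0; `Inf` gives the
#'   saturating limit.
#' @return Matrix (concentrations x 4) of probabilities summing to 1 by row.
#' @export
state_probabilities <- function(params, concentration_uM) {
  stopifnot(inherits(params, "equilibrium_params"), all(concentration_uM >= 0))
  out <- t(vapply(concentration_uM, function(L) {
    if (is.infinite(L)) {
      params$LK / sum(params$LK)
    } else {
      w <- params$K + params$LK * L / params$KD1
      w / sum(w)
    }
  }, numeric(4)))
  colnames(out) <- paste0("p", 1:4)
  out
}

#' Build an occupancy table from per-concentration event tables
#'
#' Summarizes state assignments into per-concentration counts and
#' probabilities. Probabilities are dwell-time-weighted occupancies by
#' default (an event's weight is its dwell), with plain event-count
#' fractions as an option.
#'
#' @param assignments List over recordings: each element a data.frame with
#'   columns `state` (1..4), `dwell_ms`, and a `concentration_uM` attribute
#'   or column.
#' @param dwell_weighted Weight events by dwell time (default TRUE).
#' @return Data.frame of class `occupancy_table`: `concentration_uM`,
#'   `state`, `n_events`, `total_dwell_ms`, `probability`, `sem`, and
#'   `n_eff` (effective count used by the multinomial likelihood).
#' @export
occupancy_table <- function(assignments, dwell_weighted = TRUE) {
  rows <- lapply(assignments, function(a) {
    conc <- if (!is.null(a$concentration_uM)) a$concentration_uM[1]
            else attr(a, "concentration_uM")
    data.frame(concentration_uM = conc, state = a$state, dwell_ms = a$dwell_ms)
  })
  ev <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(ev, ev$concentration_uM), function(d) {
    w <- if (dwell_weighted) d$dwell_ms else rep(1, nrow(d))
    tot <- sum(w)
    p <- vapply(1:4, function(s) sum(w[d$state == s]) / tot, numeric(1))
    n <- vapply(1:4, function(s) sum(d$state == s), numeric(1))
    dw <- vapply(1:4, function(s) sum(d$dwell_ms[d$state == s]), numeric(1))
    data.frame(concentration_uM = d$concentration_uM[1], state = 1:4,
               n_events = n, total_dwell_ms = dw, probability = p,
               sem = sqrt(pmax(p * (1 - p), 0) / nrow(d)),
               n_eff = p * nrow(d))
  }))
  rownames(out) <- NULL
  class(out) <- c("occupancy_table", "data.frame")
  out
}

occupancy_counts <- function(data) {
  concs <- sort(unique(data$concentration_uM))
  counts <- t(vapply(concs, function(L) {
    d <- data[data$concentration_uM == L, ]
    vapply(1:4, function(s) sum(d$n_eff[d$state == s]), numeric(1))
  }, numeric(4)))
  list(concs = concs, counts = counts)
}

eq_negloglik <- function(logpar, concs, counts) {
  K <- c(1, exp(logpar[1:3]))
  LK <- c(1, exp(logpar[4:6]))
  KD1 <- exp(logpar[7])
  nll <- 0
  for (j in seq_along(concs)) {
    w <- K + LK * concs[j] / KD1
    p <- w / sum(w)
    nll <- nll - sum(counts[j, ] * log(pmax(p, 1e-300)))
  }
  nll
}

#' Global maximum-likelihood fit of the eight-state model
#'
#' Fits the seven free parameters (three apo constants, three bound
#' constants, `K_D1`) by maximizing the multinomial log-likelihood of the
#' per-concentration state counts under the model, simultaneously across all
#' concentrations. Parameters are fitted in log space (positivity), from
#' multiple random starts. Because the model is overdetermined by the four
#' binding curves jointly, the `K_D` of states whose probability is nearly
#' flat in ligand remains constrained by the curved states.
#'
#' @param data An [occupancy_table()] (or data.frame with
#'   `concentration_uM`, `state`, `n_eff` columns).
#' @param seed RNG seed for the multistart.
#' @param n_starts Number of random initializations (default 20).
#' @return An [equilibrium_params()] with attributes `logLik` and
#'   `convergence`.
#' @export
fit_global <- function(data, seed = 1, n_starts = 20) {
  oc <- occupancy_counts(data)
  if (length(oc$concs) < 3) {
    stop("global fit requires >= 3 ligand concentrations (insufficient constraints)")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  kd_guess <- stats::median(oc$concs[oc$concs > 0])
  best <- NULL
  p0 <- oc$counts[which.min(oc$concs), ]; p0 <- p0 / sum(p0)
  pinf <- oc$counts[which.max(oc$concs), ]; pinf <- pinf / sum(pinf)
  informed <- c(log(pmax(p0[2:4] / p0[1], 1e-3)),
                log(pmax(pinf[2:4] / pinf[1], 1e-3)), log(kd_guess))
  starts <- rbind(informed,
                  matrix(stats::rnorm(7 * (n_starts - 1), mean = rep(informed, each = n_starts - 1),
                                      sd = 1), n_starts - 1, 7, byrow = FALSE))
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], eq_negloglik, concs = oc$concs,
                   counts = oc$counts, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    fit <- tryCatch(
      stats::optim(fit$par, eq_negloglik, concs = oc$concs,
                   counts = oc$counts, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) fit)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("global fit failed to converge from any start")
  par <- best$par
  out <- equilibrium_params(K = exp(par[1:3]), LK = exp(par[4:6]),
                            KD1 = exp(par[7]))
  attr(out, "logLik") <- -best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Parametric bootstrap confidence intervals for the equilibrium fit
#'
#' Simulates `n_boot` datasets from the fitted model, keeping the observed
#' per-concentration event totals, refits each, and reports percentile 95%
#' intervals for every fitted and derived constant and for the limiting
#' state probabilities.
#'
#' @param data The [occupancy_table()] that was fitted.
#' @param fit The [fit_global()] result.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param n_starts Multistart count per refit (smaller than the main fit,
#'   seeded from the point estimate).
#' @return Data.frame with `parameter`, `estimate`, `lower`, `upper`
#'   (2.5/97.5 percentiles) and attribute `n_failed`.
#' @export
bootstrap_ci <- function(data, fit, n_boot = 1000, seed = 1, n_starts = 3) {
  oc <- occupancy_counts(data)
  totals <- round(rowSums(oc$counts))
  P <- state_probabilities(fit, oc$concs)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  start0 <- c(log(fit$K[2:4]), log(fit$LK[2:4]), log(fit$KD1))
  refit <- function(counts) {
    best <- NULL
    for (s in seq_len(n_starts)) {
      init <- if (s == 1) start0 else start0 + stats::rnorm(7, sd = 0.3)
      f <- tryCatch(
        stats::optim(init, eq_negloglik, concs = oc$concs, counts = counts,
                     method = "BFGS", control = list(maxit = 500)),
        error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
    }
    best
  }
  par_vec <- function(ep) {
    c(K21 = ep$K[2], K31 = ep$K[3], K41 = ep$K[4],
      LK21 = ep$LK[2], LK31 = ep$LK[3], LK41 = ep$LK[4],
      KD1 = ep$KD1, KD2 = ep$KD[2], KD3 = ep$KD[3], KD4 = ep$KD[4])
  }
  nm <- names(par_vec(fit))
  draws <- matrix(NA_real_, n_boot, length(nm), dimnames = list(NULL, nm))
  n_failed <- 0
  for (b in seq_len(n_boot)) {
    counts <- t(vapply(seq_along(totals), function(j) {
      as.numeric(stats::rmultinom(1, totals[j], P[j, ]))
    }, numeric(4)))
    f <- refit(counts)
    if (is.null(f)) { n_failed <- n_failed + 1; next }
    par <- f$par
    ep <- equilibrium_params(exp(par[1:3]), exp(par[4:6]), exp(par[7]))
    draws[b, ] <- par_vec(ep)
  }
  if (n_failed > 0.05 * n_boot) {
    warning(sprintf("%d of %d bootstrap refits failed", n_failed, n_boot))
  }
  est <- par_vec(fit)
  qs <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE))
  out <- data.frame(parameter = nm, estimate = est,
                    lower = qs[, 1], upper = qs[, 2])
  attr(out, "n_failed") <- n_failed
  rownames(out) <- NULL
  out
}
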