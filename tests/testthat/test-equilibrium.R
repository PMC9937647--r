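# Eight-state equilibrium model: probabilities, limits, global fit,
# bootstrap intervals.

test_that("state probabilities are symmetric when all constants are equal", {
  ep <- equilibrium_params(c(1, 1, 1), c(1, 1, 1), KD1 = 10)
  for (L in c(0, 1, 49, 1e4, Inf)) {
    expect_equal(as.numeric(state_probabilities(ep, L)), rep(0.25, 4))
  }
})

test_that("reference constants reproduce the tabulated limiting probabilities", {
  ep <- reference_equilibrium_params()
  p0 <- as.numeric(state_probabilities(ep, 0))
  expect_equal(round(p0, 3), c(0.192, 0.492, 0.177, 0.140))
  pinf <- as.numeric(state_probabilities(ep, Inf))
  expect_equal(round(pinf[1:3], 3), c(0.172, 0.308, 0.306))
  expect_lt(abs(pinf[4] - 0.214), 0.0015)
})

test_that("probabilities normalize and interpolate monotonically in ligand", {
  ep <- equilibrium_params(c(2.566, 0.923, 0.729), c(1.795, 1.782, 1.25), 49)
  L <- c(0, 10^seq(-1, 5, length.out = 40), Inf)
  P <- state_probabilities(ep, L)
  expect_equal(rowSums(P), rep(1, length(L)), tolerance = 1e-12)
  for (i in 1:4) {
    d <- diff(P[, i])
    expect_true(all(d >= -1e-12) || all(d <= 1e-12))
  }
})

test_that("derived dissociation constants close the thermodynamic cycle", {
  ep <- reference_equilibrium_params()
  expect_equal(ep$KD, ep$KD1 * ep$K / ep$LK)
  # rounded reference inputs land near the tabulated per-state KD values
  expect_equal(round(ep$KD[3]), 25)
  expect_equal(round(ep$KD[2]), 70, tolerance = 2)
})

make_occupancy <- function(ep, concs, n_events, seed = NULL) {
  P <- state_probabilities(ep, concs)
  rows <- lapply(seq_along(concs), function(j) {
    n <- if (is.null(seed)) n_events * P[j, ]
         else as.numeric(stats::rmultinom(1, n_events, P[j, ]))
    data.frame(concentration_uM = concs[j], state = 1:4, n_events = round(n),
               total_dwell_ms = n * 200, probability = n / sum(n),
               sem = NA_real_, n_eff = n)
  })
  do.call(rbind, rows)
}

test_that("global fit recovers parameters from noiseless occupancies", {
  ep <- reference_equilibrium_params()
  concs <- c(0, 10, 25, 50, 100, 250, 750, 3000)
  occ <- make_occupancy(ep, concs, 1e5)
  fit <- fit_global(occ, seed = 1)
  expect_equal(fit$K, ep$K, tolerance = 1e-4)
  expect_equal(fit$LK, ep$LK, tolerance = 1e-4)
  expect_equal(fit$KD1, ep$KD1, tolerance = 1e-3)
})

test_that("global fit requires at least three concentrations", {
  ep <- reference_equilibrium_params()
  occ <- make_occupancy(ep, 50, 500)
  expect_error(fit_global(occ), "concentrations")
})

test_that("bootstrap intervals cover the truth and shrink with event count", {
  ep <- reference_equilibrium_params()
  concs <- c(0, 10, 25, 50, 100, 250, 750, 3000)
  set.seed(41)
  occ1 <- make_occupancy(ep, concs, 500, seed = TRUE)
  fit1 <- fit_global(occ1, seed = 2)
  ci1 <- bootstrap_ci(occ1, fit1, n_boot = 120, seed = 3)
  truth <- c(ep$K[2:4], ep$LK[2:4], ep$KD1, ep$KD[2:4])
  covered <- truth >= ci1$lower & truth <= ci1$upper
  expect_gte(mean(covered), 0.8)

  occ2 <- make_occupancy(ep, concs, 2000, seed = TRUE)
  fit2 <- fit_global(occ2, seed = 2)
  ci2 <- bootstrap_ci(occ2, fit2, n_boot = 120, seed = 3)
  w1 <- ci1$upper - ci1$lower
  w2 <- ci2$upper - ci2$lower
  # 4x the events: interval widths should drop by roughly half overall
  expect_lt(stats::median(w2 / w1), 0.75)
})

test_that("occupancy table aggregates dwell-weighted probabilities", {
  a1 <- data.frame(state = c(1, 2, 2), dwell_ms = c(100, 100, 200),
                   concentration_uM = 0)
  a2 <- data.frame(state = c(3, 4), dwell_ms = c(50, 50),
                   concentration_uM = 10)
  occ <- occupancy_table(list(a1, a2))
  p0 <- occ$probability[occ$concentration_uM == 0]
  expect_equal(p0, c(0.25, 0.75, 0, 0))
  expect_equal(sum(occ$probability[occ$concentration_uM == 10]), 1)
  occ_ev <- occupancy_table(list(a1), dwell_weighted = FALSE)
  expect_equal(occ_ev$probability[1:2], c(1 / 3, 2 / 3))
})
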