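# Forward intensity model and closed-form orientation inversion.

test_that("collection coefficients take their closed-form limits", {
  co90 <- system_coefficients(system_params(alpha = 90, delta = 0))
  expect_equal(co90$X1, 7 * pi / 12)
  expect_equal(co90$X2, 0)
  expect_equal(co90$X3, 2 * pi / 3)
  expect_equal(co90$X4, 1)
  co <- system_coefficients(system_params(alpha = 70, delta = 22.5))
  cd <- cos(22.5 * pi / 180)
  expect_equal(co$X4, cd * (1 + cd) / 2)
  expect_equal(co$X4, 0.889, tolerance = 1e-3)
})

test_that("forward model has the expected channel symmetries", {
  p <- ideal_system_params()
  I <- polarized_intensity(90, 0, 100, p)
  expect_gt(I[1, "I0"], I[1, "I90"])
  expect_equal(unname(I[1, "I45"]), unname(I[1, "I135"]))
  # channel sum independent of phi (circular excitation)
  sums <- vapply(seq(0, 170, by = 10), function(ph) {
    sum(polarized_intensity(63, ph, 100, p))
  }, numeric(1))
  expect_equal(max(sums) - min(sums), 0, tolerance = 1e-9)
})

test_that("orientations round trip through the forward model at 1e-6", {
  p <- system_params(alpha = 70, f_psi = c(0.95, 0.9, 0.97, 0.92),
                     delta = 22.5, g_psi = c(1.05, 0.98, 1, 1.02))
  co <- system_coefficients(p)
  for (th in c(1, 15, 30, 45, 60, 75, 89)) {
    for (ph in c(0, 22, 45, 90, 135, 179)) {
      I <- polarized_intensity(th, ph, 437, p, co)
      sol <- solve_orientation(I, p, co)
      expect_equal(sol$theta_deg, th, tolerance = 1e-6)
      dphi <- (sol$phi_deg - ph + 90) %% 180 - 90
      expect_equal(dphi, 0, tolerance = 1e-6)
      expect_equal(sol$itot, 437, tolerance = 1e-4)
    }
  }
})

test_that("degenerate ideal-pattern inputs resolve by convention", {
  p <- ideal_system_params()
  flat <- solve_orientation(c(100, 100, 100, 100), p)
  expect_equal(flat$theta_deg, 0, tolerance = 1e-6)
  expect_equal(flat$phi_deg, 0)
  expect_match(flat$flag, "phi_undefined")
  inplane <- solve_orientation(c(1, 0.5, 0, 0.5) * 100, p)
  expect_equal(inplane$theta_deg, 90)
  expect_equal(inplane$phi_deg, 0)
  expect_error(solve_orientation(c(0, 0, 0, 0), p), "undefined")
})

test_that("scaling a channel and its g factor together leaves the solution unchanged", {
  base <- system_params(alpha = 70)
  I <- polarized_intensity(55, 70, 200, base)
  scaled <- I
  scaled[, "I0"] <- scaled[, "I0"] * 1.37
  p2 <- system_params(alpha = 70, g_psi = c(1.37, 1, 1, 1))
  s1 <- solve_orientation(I, base)
  s2 <- solve_orientation(scaled, p2)
  expect_equal(s2$theta_deg, s1$theta_deg, tolerance = 1e-9)
  expect_equal(s2$phi_deg, s1$phi_deg, tolerance = 1e-9)
})

test_that("noise-driven sin^2 overshoot clips theta to 90 with a flag", {
  p <- ideal_system_params()
  # exaggerated anisotropy beyond any physical orientation
  sol <- solve_orientation(c(300, 100, 1, 100), p)
  expect_equal(sol$theta_deg, 90)
  expect_match(sol$flag, "theta_clipped")
})

test_that("degeneracy resolution maps mirrored clusters into one quarter sphere", {
  set.seed(71)
  true_th <- c(50, 52, 55, 48, 51, 53)
  true_ph <- c(40, 44, 38, 42, 41, 39)
  # mirror half of the events through the theta branch
  th <- true_th; ph <- true_ph
  th[c(2, 4, 6)] <- 180 - th[c(2, 4, 6)]
  th2 <- pmin(th, 180 - th)   # solver reports theta in [0, 90]
  flip <- th > 90
  res <- resolve_degeneracy(th2, ph, exhaustive = FALSE)
  expect_true(any(flip))
  spread <- max(res$theta_deg) - min(res$theta_deg)
  expect_lt(spread, 10)
  # exhaustive search agrees with the iterative heuristic here
  res_ex <- resolve_degeneracy(th2, ph, exhaustive = TRUE)
  expect_equal(res$theta_deg, res_ex$theta_deg, tolerance = 1e-9)
  # single event passes through unchanged
  one <- resolve_degeneracy(60, 30)
  expect_equal(one$theta_deg, 60)
})

test_that("event table averages tile the trace and match the whole-trace solution", {
  p <- reference_params()
  I <- polarized_intensity(65, 40, 1, p)
  counts <- matrix(rep(as.numeric(I) * 50, each = 100), 100, 4)
  ev <- build_event_table(counts, integer(0), p, frame_interval = 0.01)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$theta_deg, 65, tolerance = 1e-6)
  expect_equal(ev$phi_deg, 40, tolerance = 1e-6)
  expect_equal(ev$dwell_ms, 1000)
  # with a changepoint, segments tile [0, n)
  ev2 <- build_event_table(counts, 40L, p, frame_interval = 0.01)
  expect_equal(ev2$start, c(0L, 40L))
  expect_equal(ev2$end, c(40L, 100L))
})

test_that("event averaging shrinks angle noise roughly as 1/sqrt(frames)", {
  p <- reference_params()
  co <- system_coefficients(p)
  I <- as.numeric(polarized_intensity(55, 30, 1, p))
  I <- I * 92 / sum(I)
  sd_for <- function(nf, seed) {
    est <- vapply(1:300, function(r) {
      cnt <- sim_counts(I, nf, seed = seed + r)
      polstates:::solve_orientation_one(colMeans(cnt), p, co)$theta_deg
    }, numeric(1))
    stats::sd(est)
  }
  s1 <- sd_for(4, 9000)
  s2 <- sd_for(36, 20000)
  expect_lt(s2, s1 / 1.8)   # expect about 1/3
})
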