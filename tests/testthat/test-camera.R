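# EMCCD calibration and photon conversion.

test_that("gain/offset fit inverts a noiseless calibration line", {
  cam <- camera_model(G = 100, offset = 50)
  tab <- simulate_calibration_series(cam, levels = c(10, 50, 200), noise = FALSE)
  expect_equal(tab$I_dt, 2 * 100 * tab$snr^2 + 50)
  fit <- fit_gain_offset(tab)
  expect_equal(fit$G, 100, tolerance = 1e-10)
  expect_equal(fit$offset, 50, tolerance = 1e-8)
})

test_that("simulated calibration at the reference camera recovers gain and offset within 2%", {
  cam <- camera_model(G = 146, offset = 220)
  # dim levels: the 220-count offset is resolvable only where it is not
  # swamped by shot noise of a bright signal
  levels <- c(1, 2, 3, 4, 6, 8, 10, 13, 16, 20)
  tab <- simulate_calibration_series(cam, levels, frames_per_level = 50000,
                                     seed = 21)
  fit <- fit_gain_offset(tab)
  expect_lt(abs(fit$G - 146) / 146, 0.02)
  expect_lt(abs(fit$offset - 220) / 220, 0.02)
})

test_that("degenerate calibration input errors", {
  flat <- data.frame(I_dt = c(220, 220), snr = c(0, 0))
  expect_error(fit_gain_offset(flat), "calibration error")
  expect_error(simulate_calibration_series(camera_model(), levels = 5),
               "at least 2")
})

test_that("counts_to_photons inverts the camera relation", {
  cam <- camera_model(G = 146, offset = 220, QE = 1, N_bak = 0)
  counts <- matrix(146 * 100 + 220, nrow = 20, ncol = 4)
  ph <- counts_to_photons(counts, cam)
  expect_equal(unname(ph$photons[1, ]), rep(100, 4))
  # QE scaling: detected photons below incident
  cam95 <- camera_model(G = 146, offset = 220, QE = 0.95)
  ph95 <- counts_to_photons(counts, cam95)
  expect_equal(ph95$photons[1, 1], 100 / 0.95, tolerance = 1e-12)
  expect_equal(100 / 0.95, 105.26, tolerance = 1e-3)
})

test_that("per-frame SNR is sqrt(N/2) over summed channels and scales as sqrt(rate)", {
  cam <- camera_model(G = 1, offset = 0, QE = 1)
  counts <- matrix(23, nrow = 5, ncol = 4)   # 92 photons per frame
  ph <- counts_to_photons(counts, cam)
  expect_equal(ph$snr, rep(sqrt(92 / 2), 5))
  expect_equal(ph$snr[1], 6.78, tolerance = 0.01)
  counts2 <- counts * 2
  ph2 <- counts_to_photons(counts2, cam)
  expect_equal(ph2$snr[1] / ph$snr[1], sqrt(2))
})

test_that("round trip through the simulated camera preserves mean photon rates", {
  p <- reference_params()
  truth <- ground_truth_model(dwell_means = rep(Inf, 4))
  path <- simulate_state_path(truth, 0, 20, seed = 5)
  cam <- camera_model(G = 146, offset = 220, QE = 1)
  tr <- emit_photon_trace(path, truth, p, cam, seed = 6)
  ph <- counts_to_photons(tr, cam)
  lam <- tr$rates[path[1], ]
  est <- colMeans(ph$photons)
  expect_equal(unname(est), unname(lam), tolerance = 0.05)
})

test_that("mis-calibrated offset triggers a warning", {
  cam <- camera_model(G = 10, offset = 500)
  counts <- matrix(300, 50, 4)
  expect_warning(counts_to_photons(counts, cam), "offset exceeds")
})
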