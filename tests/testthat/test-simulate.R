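# Synthetic-data generator: state paths, photon emission, calibration
# series, dataset plumbing.

test_that("ground-truth invariants hold and separations are reported", {
  truth <- ground_truth_model()
  expect_equal(sqrt(rowSums(truth$state_orientations^2)), rep(1, 4),
               tolerance = 1e-9)
  sep <- truth$pairwise_separation_deg
  expect_length(sep, 6)
  expect_true(all(sep >= 10 & sep <= 40 + 1e-6))
  expect_error(ground_truth_model(state_orientations = diag(4)[, 1:3]),
               "unit")
  expect_error(ground_truth_model(dwell_means = c(0, 1, 1, 1)))
})

test_that("infinite dwells give a constant path; symmetric constants give uniform occupancy", {
  truth <- ground_truth_model(dwell_means = rep(Inf, 4))
  path <- simulate_state_path(truth, 0, 5, seed = 2)
  expect_length(unique(path), 1)
  expect_length(attr(path, "jump_times"), 0)

  sym <- ground_truth_model(
    dwell_means = rep(50, 4),
    equilibrium_params = equilibrium_params(c(1, 1, 1), c(1, 1, 1), 10))
  path2 <- simulate_state_path(sym, 123, 400, seed = 3)
  frac <- as.numeric(table(factor(path2, 1:4))) / length(path2)
  expect_equal(frac, rep(0.25, 4), tolerance = 0.05)
  expect_error(simulate_state_path(sym, 0, 0.001), "one frame")
})

test_that("long-run occupancies match the reference apo probabilities", {
  truth <- ground_truth_model(dwell_means = rep(50, 4))
  path <- simulate_state_path(truth, 0, 1000, seed = 7)   # 1e5 frames
  frac <- as.numeric(table(factor(path, 1:4))) / length(path)
  target <- c(0.192, 0.492, 0.177, 0.140)
  # 3 standard errors with an effective sample of ~2e4 dwells
  se <- 3 * sqrt(target * (1 - target) / 2e4)
  expect_true(all(abs(frac - target) < pmax(se, 0.02)))
})

test_that("dark frames record exactly the offset", {
  truth <- ground_truth_model(mean_total_photons = 1e-12,
                              dwell_means = rep(Inf, 4))
  cam <- camera_model(G = 100, offset = 220)
  path <- simulate_state_path(truth, 0, 1, seed = 4)
  tr <- emit_photon_trace(path, truth, reference_params(), cam, seed = 5)
  expect_true(all(tr$counts == 220))
})

test_that("emitted photon statistics show the EMCCD excess variance", {
  p <- reference_params()
  truth <- ground_truth_model(dwell_means = rep(Inf, 4))
  cam <- camera_model(G = 146, offset = 220, QE = 1)
  path <- simulate_state_path(truth, 0, 60, seed = 8)
  tr <- emit_photon_trace(path, truth, p, cam, seed = 9)
  lam <- tr$rates[path[1], ]
  for (ch in 1:4) {
    v <- stats::var(tr$counts[, ch])
    expect_equal(v, unname(2 * 146^2 * lam[ch]), tolerance = 0.15)
  }
})

test_that("default photon scale delivers ~92 photons/frame and SNR ~7", {
  p <- reference_params()
  truth <- ground_truth_model(dwell_means = rep(30, 4))
  cam <- camera_model(QE = 1)
  path <- simulate_state_path(truth, 0, 60, seed = 10)
  tr <- emit_photon_trace(path, truth, p, cam, seed = 11)
  ph <- counts_to_photons(tr, cam)
  expect_equal(mean(rowSums(ph$photons)), 92, tolerance = 0.05)
  expect_equal(mean(ph$snr), sqrt(92 / 2), tolerance = 0.05)
})

test_that("channel sum is independent of the in-plane angle", {
  p <- reference_params()
  sums <- vapply(seq(0, 160, by = 20), function(phi) {
    sum(polarized_intensity(58, phi, 300, p))
  }, numeric(1))
  expect_lt(max(sums) - min(sums), 1e-9)
})

test_that("identical seeds reproduce identical datasets", {
  ds1 <- simulate_dataset(2, concentrations_uM = c(0, 100), duration_s = 1,
                          seed = 33)
  ds2 <- simulate_dataset(2, concentrations_uM = c(0, 100), duration_s = 1,
                          seed = 33)
  expect_identical(ds1$traces[[3]]$counts, ds2$traces[[3]]$counts)
  expect_identical(ds1$traces[[2]]$true_state, ds2$traces[[2]]$true_state)
  ds3 <- simulate_dataset(2, concentrations_uM = c(0, 100), duration_s = 1,
                          seed = 34)
  expect_false(identical(ds1$traces[[1]]$counts, ds3$traces[[1]]$counts))
})

test_that("datasets round trip through the CSV/JSON writers", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(1, concentrations_uM = c(0, 50), duration_s = 0.5,
                         seed = 35)
  manifest <- write_dataset(ds, dir)
  expect_equal(nrow(manifest), 2)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  tr <- utils::read.csv(file.path(dir, manifest$path[1]))
  expect_equal(nrow(tr), 50)
  expect_equal(tr$I0, ds$traces[[1]]$counts[, 1])
  sidecar <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(sidecar$seed, 35)
})

test_that("noiseless calibration series flags degenerate configurations", {
  cam <- camera_model()
  expect_warning(simulate_calibration_series(cam, levels = c(10, 20),
                                             noise = FALSE), "fragile")
})
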