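# Binned-photon LLR changepoint detection.

test_that("LLR matches hand-evaluated values and is additive over channels", {
  seg <- matrix(c(10, 20), 2, 1)
  expect_equal(llr(seg, tau = 1), 1.699, tolerance = 1e-3)
  seg4 <- matrix(rep(c(10, 20), 4), 2, 4)
  expect_equal(llr(seg4, tau = 1), 4 * llr(seg, tau = 1))
})

test_that("constant-rate counts give zero LLR and zero counts contribute zero", {
  seg <- matrix(5, nrow = 10, ncol = 4)   # exactly proportional to time
  expect_equal(max(abs(llr(seg))), 0, tolerance = 1e-12)
  seg[, 2] <- 0                            # empty channel: no NaN
  expect_true(all(is.finite(llr(seg))))
})

test_that("LLR scales linearly under common count scaling", {
  set.seed(11)
  seg <- matrix(rpois(80, 10), 20, 4)
  for (k in c(2L, 5L)) {
    expect_equal(llr(seg * k), k * llr(seg), tolerance = 1e-9)
  }
})

test_that("recursive detector's first changepoint matches an exhaustive scan", {
  cfg <- cp_config_snr7()
  set.seed(13)
  for (rep in 1:8) {
    n <- sample(40:200, 1)
    step <- sample(10:(n - 10), 1)
    rates1 <- c(30, 20, 10, 15)
    rates2 <- c(15, 25, 20, 12)
    counts <- rbind(sim_counts(rates1, step, seed = rep),
                    sim_counts(rates2, n - step, seed = rep + 100))
    vals <- llr(counts, tau = 2:(n - 2))
    brute <- (2:(n - 2))[which.max(vals)]
    ts <- detect_transitions(counts, cfg)
    if (length(ts$changepoints) > 0) {
      first_llr <- ts$changepoints[which.max(ts$llr)]
      expect_equal(first_llr, brute)
    }
  }
})

test_that("a clear orientation step is located within two frames", {
  cfg <- cp_config_snr7()
  p <- reference_params()
  r1 <- polarized_intensity(80, 10, 1, p)
  r2 <- polarized_intensity(80, 40, 1, p)   # ~30 degree in-plane step
  sc <- 92 / sum(r1)
  hits <- 0
  for (rep in 1:10) {
    counts <- rbind(sim_counts(as.numeric(r1) * sc, 360, seed = 400 + rep),
                    sim_counts(as.numeric(r2) * sc, 360, seed = 500 + rep))
    ts <- detect_transitions(counts, cfg)
    if (length(ts$changepoints) > 0 &&
        min(abs(ts$changepoints - 360)) <= 2) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("an all-zero trace yields no transitions", {
  cfg <- cp_config_snr7()
  ts <- detect_transitions(matrix(0, 100, 4), cfg)
  expect_length(ts$changepoints, 0)
})

test_that("too-short traces warn and return an empty transition set", {
  cfg <- cp_config_snr7()
  expect_warning(ts <- detect_transitions(matrix(5, 3, 4), cfg), "shorter")
  expect_length(ts$changepoints, 0)
})

test_that("thresholds increase with trace length at fixed confidence", {
  tt <- cp_config_snr7()$threshold_table
  expect_true(all(diff(tt$threshold) >= 0))
  expect_gt(tt$threshold[nrow(tt)], tt$threshold[1])
})

test_that("median-confidence threshold equals the null max-LLR median", {
  thr50 <- calibrate_threshold(snr = 5, length_frames = 100, confidence = 0.5,
                               n_sim = 400, seed = 31)
  mx <- withr::with_seed(31, {
    polstates:::null_max_llr(400, 100, 2 * 25 / 4)
  })
  expect_equal(thr50, stats::median(mx), tolerance = 1e-9)
})

test_that("segments tile the trace exactly", {
  cfg <- cp_config_snr7()
  counts <- rbind(sim_counts(c(40, 20, 10, 22), 200, seed = 61),
                  sim_counts(c(10, 30, 25, 27), 200, seed = 62))
  ts <- detect_transitions(counts, cfg)
  expect_true(all(diff(ts$changepoints) > 0))
  expect_equal(nrow(ts$segment_means), length(ts$changepoints) + 1)
})
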