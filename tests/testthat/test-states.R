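# Spherical clustering, state-count selection, event merging, shortest-path
# indexing.

test_that("embedding maps angles to the expected unit vectors", {
  expect_equal(as.numeric(embed_events(0, 123)), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(as.numeric(embed_events(90, 0)), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(as.numeric(embed_events(60, 30)),
               c(0.75, 0.4330127, 0.5), tolerance = 1e-6)
  nrm <- sqrt(rowSums(embed_events(runif(20, 0, 90), runif(20, 0, 180))^2))
  expect_equal(nrm, rep(1, 20), tolerance = 1e-9)
})

test_that("two point masses cluster exactly with zero objective", {
  X <- rbind(matrix(rep(c(0, 0, 1), 5), ncol = 3, byrow = TRUE),
             matrix(rep(c(1, 0, 0), 5), ncol = 3, byrow = TRUE))
  m <- cluster_states(X, 2, seed = 1)
  expect_equal(m$objective, 0, tolerance = 1e-12)
  means <- m$means[order(m$means[, 1]), ]
  expect_equal(means[1, ], c(0, 0, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(means[2, ], c(1, 0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(cluster_states(X, 11, seed = 1), "exceed")
})

test_that("clustering matches the exhaustive best 2-partition on small inputs", {
  for (rep in 1:6) {
    ev <- sim_sphere_events(embed_events(c(50, 70), c(20, 60)),
                            n_per_state = 5, sigma_deg = 8, seed = 80 + rep)
    m <- cluster_states(ev$X, 2, seed = rep)
    expect_equal(m$objective, brute_force_2partition(ev$X), tolerance = 1e-6)
  }
})

test_that("clustering recovers a four-state geometry from low-noise events", {
  truthV <- default_state_geometry()
  ev <- sim_sphere_events(truthV, n_per_state = 12, sigma_deg = 2, seed = 5)
  m <- cluster_states(ev$X, 4, seed = 9)
  # match fitted means to truth greedily
  for (s in 1:4) {
    d <- angular_distance(m$means, truthV[s, ])
    expect_lt(min(d), 3)
  }
})

test_that("select_k keeps one state for a single tight cluster", {
  ev <- sim_sphere_events(embed_events(60, 40), n_per_state = 25,
                          sigma_deg = 3, seed = 3)
  m <- select_k(ev$X, k_max = 4, seed = 2)
  expect_equal(m$k, 1)
})

test_that("select_k refuses clusters separated by only 2 sigma", {
  sep <- 8
  sigma <- 4   # separation = 2 sigma < 2.5 sigma
  means <- embed_events(c(60, 60), c(40, 40 + sep / sin(60 * pi / 180)))
  ev <- sim_sphere_events(means, n_per_state = 30, sigma_deg = sigma, seed = 13)
  m <- select_k(ev$X, k_max = 3, seed = 4)
  expect_equal(m$k, 1)
})

test_that("select_k resolves four well-separated states", {
  truthV <- default_state_geometry()
  ev <- sim_sphere_events(truthV, n_per_state = 10, sigma_deg = 2.5, seed = 17)
  m <- select_k(ev$X, k_max = 6, seed = 6)
  expect_equal(m$k, 4)
})

test_that("consecutive same-state events merge and orientations re-solve", {
  p <- reference_params()
  I1 <- as.numeric(polarized_intensity(60, 20, 100, p))
  I2 <- as.numeric(polarized_intensity(45, 60, 100, p))
  counts <- rbind(matrix(rep(I1, each = 20), 20, 4),
                  matrix(rep(I1, each = 10), 10, 4),
                  matrix(rep(I2, each = 30), 30, 4))
  ev <- build_event_table(counts, c(20L, 30L), p)
  merged <- merge_consecutive_events(ev, c(1L, 1L, 2L), p)
  expect_equal(nrow(merged$events), 2)
  expect_equal(merged$events$dwell_ms[1], 300)
  expect_equal(merged$events$theta_deg[1], 60, tolerance = 1e-6)
  expect_true(all(diff(merged$assignments) != 0))
})

test_that("shortest-path ordering matches the exhaustive 24-permutation minimum", {
  brute_order <- function(means) {
    perms <- polstates:::all_permutations(4)
    deltas <- apply(perms, 1, function(ord) {
      d <- function(i, j) sqrt(sum((means[i, ] - means[j, ])^2))
      sum(vapply(1:3, function(t) d(ord[t], ord[t + 1]), numeric(1))) -
        d(ord[1], ord[4])
    })
    min(deltas)
  }
  set.seed(23)
  for (rep in 1:8) {
    V <- sim_sphere_events(default_state_geometry(), 1, 15,
                           seed = 300 + rep)$X
    model <- structure(list(k = 4, means = V, sigma_deg = rep(1, 4),
                            n = rep(5, 4), assignments = rep(1:4, each = 5)),
                       class = "state_model")
    ordered <- order_states(model)
    expect_equal(ordered$order_delta_d, brute_order(V), tolerance = 1e-12)
    # reversal symmetry: reversing the chosen order keeps the path length
    d <- function(i, j) sqrt(sum((ordered$means[i, ] - ordered$means[j, ])^2))
    fwd <- d(1, 2) + d(2, 3) + d(3, 4)
    rev_ <- d(4, 3) + d(3, 2) + d(2, 1)
    expect_equal(fwd, rev_)
  }
})

test_that("collinear states order along the line with zero excess path", {
  line <- t(vapply(c(0, 1, 2, 3), function(t) c(t, 0.2 * t, 1), numeric(3)))
  model <- structure(list(k = 4, means = line[c(3, 1, 4, 2), ],
                          sigma_deg = rep(1, 4), n = rep(3, 4),
                          assignments = rep(1:4, each = 3)),
                     class = "state_model")
  ordered <- order_states(model)
  expect_equal(ordered$order_delta_d, 0, tolerance = 1e-12)
  steps <- vapply(1:3, function(i) {
    sqrt(sum((ordered$means[i, ] - ordered$means[i + 1, ])^2))
  }, numeric(1))
  expect_equal(steps, rep(steps[1], 3), tolerance = 1e-9)
})

test_that("re-assigning events to the fitted means reproduces stored assignments", {
  ev <- sim_sphere_events(default_state_geometry(), 8, 3, seed = 31)
  m <- cluster_states(ev$X, 4, seed = 11)
  d2 <- vapply(1:4, function(j) {
    rowSums((ev$X - matrix(m$means[j, ], nrow(ev$X), 3, byrow = TRUE))^2)
  }, numeric(nrow(ev$X)))
  expect_equal(max.col(-d2, ties.method = "first"), m$assignments)
})
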