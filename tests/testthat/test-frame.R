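# Local-frame construction, rotation into it, direct angles, chord
# displacements, ensemble pooling.

test_that("local frame axes follow the C1/C4 construction", {
  F <- build_local_frame(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 1, 0)))
  expect_equal(unname(F["X", ]), c(1, 0, 0))
  expect_equal(unname(F["Y", ]), c(0, 1, 0))
  expect_equal(unname(F["Z", ]), c(0, 0, 1))
  # orthonormal, right-handed for a generic model
  set.seed(5)
  V <- sim_sphere_events(default_state_geometry(), 1, 10, seed = 5)$X
  F2 <- build_local_frame(V)
  G <- unclass(F2)
  expect_equal(G %*% t(G), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(polstates:::cross3(G[1, ], G[2, ]), G[3, ], tolerance = 1e-12)
  expect_error(build_local_frame(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                                       c(-1, 0, 0))), "degenerate")
})

test_that("C1 and C4 land at phi1 = 0 and theta = 90 in their own frame", {
  set.seed(9)
  for (rep in 1:5) {
    R <- polstates:::random_rotation()
    V <- default_state_geometry() %*% t(R)
    F <- build_local_frame(V)
    loc <- to_local(V, F)
    expect_equal(loc$theta_deg[1], 90, tolerance = 1e-6)
    expect_equal(loc$phi_deg[1], 0, tolerance = 1e-6)
    expect_equal(loc$theta_deg[4], 90, tolerance = 1e-6)
  }
})

test_that("local-frame angles are invariant to lab-frame rotations", {
  set.seed(11)
  V <- default_state_geometry()
  F <- build_local_frame(V)
  ref <- to_local(V, F)
  for (rep in 1:6) {
    R <- polstates:::random_rotation()
    Vr <- V %*% t(R)
    Fr <- build_local_frame(Vr)
    got <- to_local(Vr, Fr)
    expect_equal(got$theta_deg, ref$theta_deg, tolerance = 1e-9)
    expect_equal(got$phi_deg, ref$phi_deg, tolerance = 1e-9)
  }
})

test_that("to_local maps the frame axes to their defining angles", {
  V <- default_state_geometry()
  F <- build_local_frame(V)
  G <- unclass(F)
  expect_equal(to_local(G["Z", ], F)$theta_deg, 0, tolerance = 1e-9)
  x <- to_local(G["X", ], F)
  expect_equal(x$theta_deg, 90, tolerance = 1e-9)
  expect_equal(x$phi_deg, 0, tolerance = 1e-9)
  diag45 <- (G["X", ] + G["Y", ]) / sqrt(2)
  expect_equal(to_local(diag45, F)$phi_deg, 45, tolerance = 1e-9)
})

test_that("direct angles are symmetric and match definitions", {
  expect_equal(direct_angle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(direct_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  V <- default_state_geometry()
  M <- omega_matrix(V)
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(0, 4), tolerance = 1e-4)
  expect_equal(M[1, 2], angular_distance(V[1, ], V[2, ]))
})

test_that("chord displacement reproduces the 20-Angstrom worked values", {
  expect_equal(chord_displacement(5, 20), 1.7, tolerance = 0.05)
  expect_equal(chord_displacement(10, 20), 3.5, tolerance = 0.02)
  expect_equal(chord_displacement(0, 7), 0)
})

make_molecule <- function(R, n_per_state = 6, sigma = 2, seed = 1) {
  V <- default_state_geometry() %*% t(R)
  ev <- sim_sphere_events(V, n_per_state, sigma, seed = seed)
  sph <- cart_to_sph(ev$X)
  list(events = data.frame(theta_deg = sph$theta_deg, phi_deg = sph$phi_deg,
                           dwell_ms = rep(200, nrow(ev$X)),
                           state = ev$labels),
       frame = build_local_frame(V))
}

test_that("a single molecule pools to its own distribution and sem shrinks with copies", {
  set.seed(3)
  m1 <- make_molecule(polstates:::random_rotation(), seed = 21)
  pooled1 <- pool_ensemble(list(m1))
  expect_equal(nrow(pooled1), 4)
  expect_equal(pooled1$n, rep(6, 4))
  pooled2 <- pool_ensemble(list(m1, m1))
  expect_equal(pooled2$theta_mean, pooled1$theta_mean, tolerance = 1e-9)
  # sqrt(2) shrink up to the small-sample Bessel factor
  expect_equal(pooled2$theta_sem, pooled1$theta_sem / sqrt(2),
               tolerance = 0.05)
})

test_that("pooled local-frame statistics are invariant to per-molecule lab rotations", {
  set.seed(7)
  mols_id <- lapply(1:5, function(i) make_molecule(diag(3), seed = 30 + i))
  mols_rot <- lapply(1:5, function(i) {
    m <- make_molecule(diag(3), seed = 30 + i)
    R <- polstates:::random_rotation()
    V <- embed_events(m$events$theta_deg, m$events$phi_deg) %*% t(R)
    sph <- cart_to_sph(V)
    m$events$theta_deg <- sph$theta_deg
    m$events$phi_deg <- sph$phi_deg
    m$frame <- structure(unclass(m$frame) %*% t(R), class = class(m$frame))
    m
  })
  p1 <- pool_ensemble(mols_id)
  p2 <- pool_ensemble(mols_rot)
  expect_equal(p2$theta_mean, p1$theta_mean, tolerance = 1e-6)
  expect_equal(p2$phi_mean, p1$phi_mean, tolerance = 1e-6)
  expect_equal(p2$phi_sd, p1$phi_sd, tolerance = 1e-6)
})

test_that("per-molecule pooling reports molecule-to-molecule scatter", {
  set.seed(19)
  mols <- lapply(1:6, function(i) {
    m <- make_molecule(polstates:::random_rotation(), sigma = 2, seed = 50 + i)
    # inject molecule-level heterogeneity: a small random offset rotation
    R <- polstates:::rotation_about_axis(stats::rnorm(3), stats::rnorm(1, 0, 9))
    V <- embed_events(m$events$theta_deg, m$events$phi_deg) %*% t(R)
    sph <- cart_to_sph(V)
    m$events$theta_deg <- sph$theta_deg
    m$events$phi_deg <- sph$phi_deg
    m
  })
  pooled <- pool_ensemble(mols, per_molecule = TRUE)
  expect_equal(pooled$n, rep(6, 4))
  # scatter should reflect the injected ~9 degree heterogeneity, not the
  # 2 degree event noise
  expect_gt(stats::median(pooled$theta_sd, na.rm = TRUE), 3)
})
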