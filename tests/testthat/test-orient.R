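test_that("water vectors: bisector dipole, H-H direction, periodic images", {
  o <- c(0, 0, 0); h1 <- c(0.76, 0.59, 0); h2 <- c(-0.76, 0.59, 0)
  wv <- water_vectors(o, h1, h2)
  expect_equal(wv$d, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(wv$r_hh, c(-1, 0, 0), tolerance = 1e-12)

  # equivariance under a known rotation
  set.seed(1)
  R <- random_rotation()
  wvR <- water_vectors(as.numeric(R %*% o), as.numeric(R %*% h1),
                       as.numeric(R %*% h2))
  expect_equal(wvR$d, as.numeric(R %*% wv$d), tolerance = 1e-12)
  expect_equal(wvR$r_hh, as.numeric(R %*% wv$r_hh), tolerance = 1e-12)

  # molecule split across the periodic boundary gives the same dipole as
  # the whole-molecule image
  box <- c(20, 20, 20)
  wv_split <- water_vectors(o, h1 + c(20, 0, 0), h2, box = box)
  expect_equal(wv_split$d, wv$d, tolerance = 1e-12)

  expect_error(water_vectors(o, c(3, 0, 0), h2), "O-H distance")
  expect_error(water_vectors(o, h1, h1), "degenerate")
})

test_that("orientation angles match their geometric definition", {
  n <- c(1, 0, 0)
  # dipole perpendicular to the normal, H-H parallel to d x n
  d <- c(0, 1, 0)
  u <- c(d[2] * n[3] - d[3] * n[2], d[3] * n[1] - d[1] * n[3],
         d[1] * n[2] - d[2] * n[1])
  ang <- orientation_angles(d, u / sqrt(sum(u^2)), n)
  expect_equal(ang$theta, 90)
  expect_equal(ang$phi, 0)
  # dipole at the pole: theta 0, phi undefined
  angp <- orientation_angles(c(1, 0, 0), c(0, 1, 0), n)
  expect_equal(angp$theta, 0)
  expect_true(is.na(angp$phi))
  # brute-force check via explicit rotation construction: build d at
  # known (theta0, psi) and r_hh at known angle phi0 from d x n
  set.seed(6)
  for (rep in 1:20) {
    theta0 <- runif(1, 5, 175)
    psi <- runif(1, 0, 2 * pi)
    phi0 <- runif(1, 0, 90)
    tr <- theta0 * pi / 180
    d <- c(cos(tr), sin(tr) * cos(psi), sin(tr) * sin(psi))
    u <- c(0, d[3], -d[2]); u <- u / sqrt(sum(u^2))   # ~ d x n direction
    v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
           d[1] * u[2] - d[2] * u[1])
    rhh <- cos(phi0 * pi / 180) * u + sin(phi0 * pi / 180) * v
    ang <- orientation_angles(d, rhh, n)
    expect_equal(ang$theta, theta0, tolerance = 1e-9)
    expect_equal(ang$phi, phi0, tolerance = 1e-9)
    # folding: flipping the H labels changes nothing
    ang2 <- orientation_angles(d, -rhh, n)
    expect_equal(ang2$phi, ang$phi, tolerance = 1e-9)
  }
})

test_that("Jacobian-corrected theta histogram is flat for isotropy", {
  set.seed(10)
  n <- 1e5
  theta <- acos(runif(n, -1, 1)) * 180 / pi
  h <- jacobian_corrected_hist(theta, bins = 36)
  expect_true(h$corrected)
  # unit integral
  expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-9)
  # chi-square flatness test on the raw counts against the sin-theta
  # expectation, alpha = 0.01
  br <- h$breaks * pi / 180
  p_bin <- (cos(br[-length(br)]) - cos(br[-1])) / 2
  chi2 <- sum((h$counts - n * p_bin)^2 / (n * p_bin))
  expect_lt(chi2, qchisq(0.99, df = 35))

  # all samples in one bin
  h1 <- jacobian_corrected_hist(rep(90, 100), bins = 36)
  expect_identical(sum(h1$counts > 0), 1L)
  expect_error(jacobian_corrected_hist(numeric(0)), "no orientation samples")
})

test_that("corrected histogram recovers a planted Boltzmann bias", {
  # cos(theta) ~ density prop. to exp(kappa * cos(theta)), sampled by
  # inverse transform; corrected P(theta) must match the planted density
  kappa <- 1.5
  set.seed(11)
  u <- runif(2e5)
  c0 <- log(u * exp(kappa) + (1 - u) * exp(-kappa)) / kappa
  theta <- acos(c0) * 180 / pi
  h <- jacobian_corrected_hist(theta, bins = 30)
  # after the sin-theta correction the density is prop. to exp(kappa cos)
  want <- exp(kappa * cos(h$mids * pi / 180))
  want <- want / sum(want * diff(h$breaks))
  expect_lt(max(abs(h$density - want) / max(want)), 0.05)
})

test_that("conditional phi histograms window correctly and stay flat for isotropy", {
  sp <- gap_spec(n_molecules = 200L, n_frames = 100L, seed = 15)
  tr <- brownian_gap_trajectory(sp)
  ang <- traj_orientations(tr)
  ph <- phi_hist_conditional(ang, c(60, 120), bins = 18)
  expect_false(ph$corrected)
  expect_equal(sum(ph$density * diff(ph$breaks)), 1, tolerance = 1e-9)
  # isotropic: flat phi histogram within multinomial 3-sigma bounds
  nsel <- sum(ph$counts)
  p0 <- 1 / 18
  expect_true(all(abs(ph$counts - nsel * p0) <
                  4 * sqrt(nsel * p0 * (1 - p0))))
  expect_error(phi_hist_conditional(ang, c(179.5, 180)), "no samples")
})

test_that("planted lying-down population peaks at theta ~ 90 and phi ~ 0", {
  sp <- cnc_gap_spec("B", seed = 16)
  sp$n_frames <- 200L
  tr <- brownian_gap_trajectory(sp)
  ang <- traj_orientations(tr, slab = sp$slab)
  h <- jacobian_corrected_hist(ang$theta, bins = 36)
  peak <- h$mids[which.max(h$density)]
  expect_gte(peak, 85); expect_lte(peak, 105)
  ph <- phi_hist_conditional(ang, c(80, 100), bins = 18)
  expect_equal(ph$mids[which.max(ph$density)], 2.5)
})

test_that("theta distribution is invariant under rotations about the normal", {
  # molecules with random orientations well inside a large box (no
  # wrapping), rotated rigidly by 70 degrees about x (the normal)
  set.seed(17)
  nm <- 200
  cth <- runif(nm, -1, 1); sth <- sqrt(1 - cth^2)
  psi <- runif(nm, 0, 2 * pi); chi <- runif(nm, 0, 2 * pi)
  d <- cbind(cth, sth * cos(psi), sth * sin(psi))
  u <- cbind(0, d[, 3], -d[, 2]); u <- u / sqrt(rowSums(u^2))
  v <- cbind(d[, 2] * u[, 3] - d[, 3] * u[, 2],
             d[, 3] * u[, 1] - d[, 1] * u[, 3],
             d[, 1] * u[, 2] - d[, 2] * u[, 1])
  e <- cos(chi) * u + sin(chi) * v
  r_oh <- 0.9572; beta <- 104.52 / 2 * pi / 180
  O <- matrix(runif(nm * 3, 200, 300), nm, 3)
  coords <- array(NA_real_, c(1, 3 * nm, 3))
  oi <- 3 * (seq_len(nm) - 1) + 1
  coords[1, oi, ] <- O
  coords[1, oi + 1, ] <- O + r_oh * (cos(beta) * d + sin(beta) * e)
  coords[1, oi + 2, ] <- O + r_oh * (cos(beta) * d - sin(beta) * e)
  tr <- trajectory(0, c(500, 500, 500), coords)
  ang <- traj_orientations(tr)
  a <- 70 * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3,
              byrow = TRUE)
  co <- tr$coords
  co[1, , ] <- co[1, , ] %*% t(R)
  tr2 <- trajectory(tr$times, tr$box, co)
  ang2 <- traj_orientations(tr2)
  expect_equal(sort(ang2$theta), sort(ang$theta), tolerance = 1e-9)
})
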