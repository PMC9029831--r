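test_that("gap residency is strict and matches a brute-force check", {
  # 3 molecules, 5 frames; molecule 2 leaves for exactly one frame
  ox <- cbind(rep(-18, 5), c(-18, -18, -15.2, -18, -18), rep(-17, 5))
  tr <- toy_trajectory(ox, matrix(5, 5, 3), matrix(5, 5, 3))
  slab <- c(-21, -16)
  expect_identical(gap_residents(tr, slab), c(1L, 3L))
  expect_identical(gap_residents(tr, slab, allow_excursions = 1), 1:3)
  # all molecules inside: all ids
  expect_identical(gap_residents(tr, c(-30, 0)), 1:3)
  expect_warning(ids <- gap_residents(tr, c(10, 20)), "no gap-resident")
  expect_length(ids, 0)
  # brute-force per-frame check
  inside <- apply(ox, 2, function(v) all(v >= slab[1] & v <= slab[2]))
  expect_identical(gap_residents(tr, slab), which(inside))
  # window restriction: molecule 2 is resident in frames 1-2 only
  expect_identical(gap_residents(tr, slab, window = c(0, 1)), 1:3)
})

test_that("planted leavers in the generator are excluded from residency", {
  sp <- gap_spec(n_molecules = 20L, n_frames = 51L, n_leavers = 5L,
                 seed = 19)
  tr <- brownian_gap_trajectory(sp)
  truth <- attr(tr, "truth")
  ids <- gap_residents(tr, sp$slab)
  expect_identical(ids, truth$resident_ids)
  expect_length(intersect(ids, truth$leaver_ids), 0)
})

test_that("periodic unwrapping restores continuous paths", {
  # steady drift across the y boundary
  nf <- 50
  y_true <- 35 + 0.4 * (0:(nf - 1))           # crosses y = 40
  ox <- matrix(-18, nf, 1)
  tr <- toy_trajectory(ox, matrix(y_true %% 40, nf, 1), matrix(5, nf, 1))
  un <- unwrap_pbc(tr)
  oy <- un$coords[, 1, 2]
  expect_true(all(diff(oy) > 0))
  expect_equal(oy, y_true, tolerance = 1e-9)
  # already-continuous trajectory: identity
  tr2 <- toy_trajectory(ox, matrix(20 + 0.05 * (0:(nf - 1)), nf, 1),
                        matrix(5, nf, 1))
  expect_equal(unwrap_pbc(tr2)$coords, tr2$coords)
  # wrap/unwrap round trip on a random walk
  set.seed(20)
  walk <- apply(matrix(rnorm(nf * 4, 0, 1.5), nf, 4), 2, cumsum) + 20
  trw <- toy_trajectory(matrix(-18, nf, 4), walk %% 40, matrix(5, nf, 4))
  unw <- unwrap_pbc(trw)
  oi <- 3 * (1:4 - 1) + 1
  expect_equal(unw$coords[, oi, 2], walk, tolerance = 1e-9)
  # ambiguous jumps are refused with frame and atom named
  bad <- toy_trajectory(matrix(-18, 3, 1), matrix(c(1, 21, 1), 3, 1),
                        matrix(5, 3, 1))
  expect_error(unwrap_pbc(bad), "frame 2")
})

test_that("MSD curves obey closed forms and the brute-force double loop", {
  nf <- 21
  # stationary molecules: zero MSD
  tr0 <- toy_trajectory(matrix(-18, nf, 2), matrix(5, nf, 2),
                        matrix(7, nf, 2))
  c0 <- msd_curve(tr0, 1:2, max_lag = 8)
  expect_true(all(c0$msd == 0))
  expect_equal(c0$lag[1], 0)
  # deterministic drift: MSD_a(t) = (v_a t)^2 exactly
  v <- c(0.1, 0.2, 0.05)
  t_ <- 0:(nf - 1)
  trd <- toy_trajectory(matrix(-30 + v[1] * t_, nf, 1),
                        matrix(10 + v[2] * t_, nf, 1),
                        matrix(10 + v[3] * t_, nf, 1), box = c(500, 500, 500))
  cd <- msd_curve(trd, 1, max_lag = 8)
  for (ax in 1:3)
    expect_equal(cd$msd[, ax], (v[ax] * cd$lag)^2, tolerance = 1e-9)
  # n_pairs decreasing, msd(0) = 0
  expect_true(all(diff(cd$n_pairs) <= 0))
  # brute-force double loop over (molecule, origin) on a random fixture
  set.seed(22)
  nm <- 3
  pos <- array(rnorm(nf * nm * 3), c(nf, nm, 3))
  coords <- array(0, c(nf, 3 * nm, 3))
  oi <- 3 * (seq_len(nm) - 1) + 1
  coords[, oi, ] <- pos
  coords[, oi + 1, ] <- pos + 0.1
  coords[, oi + 2, ] <- pos - 0.1
  trb <- trajectory(0:(nf - 1), c(1e3, 1e3, 1e3), coords)
  cb <- msd_curve(trb, 1:nm, max_lag = 10)
  for (k in 1:10) {
    acc <- matrix(0, 1, 3); cnt <- 0
    for (i in seq_len(nm)) for (t0 in seq_len(nf - k)) {
      acc <- acc + (pos[t0 + k, i, ] - pos[t0, i, ])^2
      cnt <- cnt + 1
    }
    expect_equal(unname(cb$msd[k + 1, ]), as.numeric(acc / cnt),
                 tolerance = 1e-9)
    expect_equal(cb$n_pairs[k + 1], cnt, ignore_attr = TRUE)
  }
  # per-axis additivity against total displacement
  tot_brute <- sum((pos[11, 1, ] - pos[1, 1, ])^2)
  expect_equal(sum((trb$coords[11, 1, ] - trb$coords[1, 1, ])^2), tot_brute)
})

test_that("diffusion fitting halves the slope and clamps at zero", {
  lag <- 0:100
  curve <- structure(list(
    lag = lag,
    msd = cbind(x = 2 * 0.17 * lag, y = 0 * lag, z = 4 - 0.02 * lag),
    n_pairs = rep(1000L, 101), n_molecules = 10L), class = "msd_curve")
  expect_warning(d <- fit_diffusion(curve), "clamped")
  expect_equal(unname(d$D["x"]), 0.17, tolerance = 1e-12)
  expect_equal(unname(d$D["y"]), 0)
  expect_equal(unname(d$D["z"]), 0)
  expect_error(fit_diffusion(curve, fit_window = c(0, 1)), "fewer than 3")
})

test_that("confined walks plateau below the slab bound; free walks recover D", {
  # reflective confinement of width L: MSD_x plateau <= L^2/6 (+ slack)
  sp <- gap_spec(slab = c(-20, -15), n_molecules = 150L, n_frames = 401L,
                 D = c(0.1, 0.1, 0.1), seed = 23)
  tr <- brownian_gap_trajectory(sp)
  cur <- msd_curve(tr, seq_len(150), max_lag = 200)
  L <- 5
  plateau <- mean(cur$msd[cur$lag >= 100, "x"])
  expect_lt(plateau, L^2 / 6 * 1.15)

  # free isotropic diffusion: planted D recovered within 3 standard
  # errors across 5 seeds (wide slab so walls are irrelevant)
  D0 <- 0.27
  rec <- vapply(1:5, function(sd) {
    spf <- gap_spec(slab = c(-60, 60), box = c(140, 40, 41.4),
                    n_molecules = 60L, n_frames = 251L,
                    D = c(D0, D0, D0), seed = sd)
    trf <- brownian_gap_trajectory(spf)
    fit_diffusion(msd_curve(trf, 1:60))$D[["y"]]
  }, numeric(1))
  se <- sd(rec) / sqrt(5)
  expect_lt(abs(mean(rec) - D0), 3 * se + 0.01)
})

test_that("the bulk-water fixture recovers D = 0.27 within 10 percent", {
  spf <- gap_spec(slab = c(-75, 75), box = c(160, 60, 60),
                  n_molecules = 148L, n_frames = 501L,
                  D = c(0.27, 0.27, 0.27), seed = 24)
  trf <- brownian_gap_trajectory(spf)
  d <- fit_diffusion(msd_curve(trf, 1:148), fit_window = c(5, 125))
  # each axis within 15%; the isotropic average (the quantity the bulk
  # reference value describes) within 10%
  for (ax in c("x", "y", "z"))
    expect_lt(abs(d$D[[ax]] - 0.27) / 0.27, 0.15)
  expect_lt(abs(mean(d$D) - 0.27) / 0.27, 0.10)
})
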