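test_that("line integration of the mean force follows the trapezoid rule", {
  cg <- coarse_grid()
  # constant fx = -1 kcal/mol/A over 60 A rises to +60 kcal/mol
  fld <- const_field(cg, fx_val = -1)
  prof <- line_integrate_x(fld, 1)
  expect_equal(prof[1], 0)
  expect_equal(prof[cg$nx], 60)
  # zero force: flat profile
  expect_equal(line_integrate_x(const_field(cg), 3), rep(0, cg$nx))
  # quadratic free energy F = a x^2 has linear fx, for which the
  # trapezoid rule is exact at the nodes
  a <- 0.05
  fx <- outer(cg$x, cg$theta, function(x, th) -2 * a * x)
  fld2 <- gradient_field(cg, fx, matrix(0, cg$nx, cg$ntheta))
  prof2 <- line_integrate_x(fld2, 5)
  expect_equal(prof2, a * cg$x^2 - a * cg$x_min^2, tolerance = 1e-12)
})

test_that("boundary fixing averages the per-row transfer integrals", {
  g <- grid_spec(-10, 10, 5, 0, 180, 60, theta_periodic = TRUE)
  # rows integrating to exactly 1, 2, 3 -> dFw2o = 2
  fx <- matrix(0, g$nx, g$ntheta)
  for (j in 1:3) fx[, j] <- -j / (g$x_max - g$x_min)
  fld <- gradient_field(g, fx, matrix(0, g$nx, g$ntheta))
  bnd <- set_boundaries(fld)
  expect_equal(bnd$row_integrals, c(1, 2, 3), tolerance = 1e-12)
  expect_equal(bnd$dFw2o, 2)
  expect_equal(bnd$left, rep(0, 3))
  expect_equal(bnd$right, rep(2, 3))
})

test_that("transfer free energy tracks the planted end-to-end offset", {
  # three-well benchmark with gradient noise: recovered dFw2o within
  # 3 propagated sem of the planted 318 kcal/mol
  surf <- make_surface(cnc_surface_spec())
  cg <- coarse_grid()
  sem <- 0.05
  fld <- sample_gradient_field(surf, cg,
                               noise_spec(sigma_f = sem * 10, sigma_T = sem * 10,
                                          n_samples = 100, seed = 21))
  bnd <- set_boundaries(fld)
  # row integral sd: sem per node, trapezoid weights dx*(1/2,1,...,1,1/2)
  wts <- c(0.5, rep(1, cg$nx - 2), 0.5) * cg$dx
  sd_row <- sem * sqrt(sum(wts^2))
  expect_lt(abs(bnd$dFw2o - 318), 3 * sd_row / sqrt(cg$ntheta))
  # symmetric (flat) surface: zero transfer free energy
  flat <- make_surface(surface_spec(ramp_height = 0))
  fld0 <- sample_gradient_field(flat, cg, noise_spec())
  expect_equal(set_boundaries(fld0)$dFw2o, 0, tolerance = 1e-12)
})

test_that("relaxation recovers planted surfaces exactly for curl-free data", {
  # zero gradients, zero boundaries: identically zero surface
  cg <- coarse_grid()
  s0 <- fes(const_field(cg), sweep = "ordered")
  expect_lt(max(abs(s0$F)), 1e-12)
  expect_true(s0$converged)

  # grid-consistent gradients of the planted three-well surface
  surf <- make_surface(cnc_surface_spec())
  fld <- sample_gradient_field(surf, cg, noise_spec())
  truth <- attr(fld, "truth")$F
  for (sw in c("ordered", "random")) {
    s <- fes(fld, sweep = sw, seed = 5)
    expect_lt(max(abs(s$F - truth)), 1e-8)
  }
})

test_that("the relaxation fixed point matches the direct sparse solve", {
  surf <- make_surface(cnc_surface_spec())
  cg <- coarse_grid()
  fld <- sample_gradient_field(surf, cg,
                               noise_spec(1, 1, 1e4, seed = 31))
  s <- fes(fld, sweep = "random", seed = 1)
  o <- solve_fes_exact(fld)
  expect_lt(max(abs(s$F - o$F)), 1e-8)

  # seed / sweep-order invariance of the fixed point
  s2 <- fes(fld, sweep = "random", seed = 999)
  s3 <- fes(fld, sweep = "ordered")
  expect_lt(max(abs(s$F - s2$F)), 1e-8)
  expect_lt(max(abs(s$F - s3$F)), 1e-8)

  # random non-periodic 20 x 20 grid
  g20 <- grid_spec(0, 19, 1, 0, 95, 5)
  set.seed(8)
  fld20 <- gradient_field(g20, matrix(rnorm(400), 20, 20),
                          matrix(rnorm(400), 20, 20))
  s20 <- fes(fld20, sweep = "ordered", max_iter = 5e6)
  o20 <- solve_fes_exact(fld20)
  expect_lt(max(abs(s20$F - o20$F)), 1e-8)
})

test_that("direct solver handles degenerate and 1D-like systems", {
  # 3 x 3 non-periodic grid, zero gradients, zero boundaries
  g3 <- grid_spec(0, 2, 1, 0, 30, 15)
  o3 <- solve_fes_exact(const_field(g3))
  expect_lt(max(abs(o3$F)), 1e-12)

  # two identical decoupled theta rows (zero torque): each row's solution
  # is exactly the cumulative trapezoid line integral
  g2 <- grid_spec(0, 10, 1, 0, 15, 15)
  set.seed(9)
  fx_row <- rnorm(g2$nx)
  fld2 <- gradient_field(g2, matrix(fx_row, g2$nx, 2),
                         matrix(0, g2$nx, 2))
  o2 <- solve_fes_exact(fld2)
  expect_equal(o2$F[, 1], line_integrate_x(fld2, 1), tolerance = 1e-10)
  expect_equal(o2$F[, 2], line_integrate_x(fld2, 1), tolerance = 1e-10)
})

test_that("gauge invariance: shifting both boundaries shifts F by a constant", {
  surf <- make_surface(cnc_surface_spec())
  cg <- coarse_grid()
  fld <- sample_gradient_field(surf, cg, noise_spec(1, 1, 1e4, seed = 12))
  bnd <- set_boundaries(fld)
  s <- fes(fld, boundaries = bnd, sweep = "ordered")
  bnd2 <- bnd
  bnd2$left <- bnd$left + 7.5
  bnd2$right <- bnd$right + 7.5
  s2 <- fes(fld, boundaries = bnd2, sweep = "ordered")
  expect_lt(max(abs((s2$F - s$F) - 7.5)), 1e-8)
})

test_that("torque loop integration closes for consistent fields", {
  cg <- coarse_grid()
  chk0 <- torque_integrate_check(const_field(cg), 4)
  expect_equal(chk0$profile, rep(0, cg$ntheta + 1))
  expect_equal(chk0$residual, 0)

  surf <- make_surface(cnc_surface_spec())
  fld <- sample_gradient_field(surf, cg, noise_spec())
  for (i in c(1, 5, 13))
    expect_lt(torque_integrate_check(fld, i)$residual, 1e-10)

  # far-field rows: mean torque essentially zero, closure at noise level
  sem <- 1e-3
  fldn <- sample_gradient_field(surf, cg,
                                noise_spec(sigma_f = 0.1, sigma_T = 0.1,
                                           n_samples = 1e4, seed = 14))
  expect_lt(max(abs(fldn$Tz[c(1, cg$nx), ])), 5 * sem)
  dthr <- cg$dtheta * pi / 180
  noise_bound <- 5 * sem * dthr * sqrt(cg$ntheta)
  expect_lt(torque_integrate_check(fldn, 1)$residual, noise_bound)
  expect_lt(torque_integrate_check(fldn, cg$nx)$residual, noise_bound)
  expect_error(torque_integrate_check(fes_field_nonper <- const_field(
    grid_spec(0, 5, 5, 0, 30, 15)), 1), "periodic")
})

test_that("fine-grid refinement is consistent and domain-checked", {
  surf <- make_surface(cnc_surface_spec())
  cg <- coarse_grid()
  fld <- sample_gradient_field(surf, cg, noise_spec())
  coarse <- fes(fld, sweep = "ordered")

  # noiseless planted truth is reproduced on the fine grid
  ff <- sample_gradient_field(surf, fine_grid(), noise_spec())
  fine <- refine_fes(coarse, ff, sweep = "ordered")
  expect_lt(max(abs(fine$F - attr(ff, "truth")$F)), 1e-6)

  # a fine grid that is a sub-block of the coarse one with identical
  # data reproduces the coarse values on shared nodes
  sub <- grid_spec(-30, 30, 5, 0, 165, 15)   # same nodes, non-periodic
  idx <- match(sub$theta, cg$theta)
  fld_sub <- gradient_field(sub, fld$fx[, idx], fld$Tz[, idx])
  fine_sub <- refine_fes(coarse, fld_sub, sweep = "ordered")
  expect_lt(max(abs(fine_sub$F - coarse$F[, idx])), 1e-7)

  # domain violation
  too_big <- grid_spec(-40, 0, 5, 75, 150, 5)
  fld_bad <- const_field(too_big)
  expect_error(refine_fes(coarse, fld_bad), "beyond")
})

test_that("reconstruction error scales as 1/sqrt(n_samples)", {
  surf <- make_surface(cnc_surface_spec())
  cg <- coarse_grid()
  rmse <- vapply(c(1e2, 1e4), function(n) {
    fld <- sample_gradient_field(surf, cg,
                                 noise_spec(1, 1, n_samples = n, seed = 77))
    s <- solve_fes_exact(fld)
    sqrt(mean((s$F - attr(fld, "truth")$F)^2))
  }, numeric(1))
  # sem ratio is 10; allow generous statistical slack
  expect_gt(rmse[1] / rmse[2], 3)
  expect_lt(rmse[1] / rmse[2], 30)
})

test_that("fitted surface methods expose predictions and residuals", {
  surf <- make_surface(cnc_surface_spec())
  fld <- sample_gradient_field(surf, coarse_grid(), noise_spec())
  s <- fes(fld, sweep = "ordered")
  # node prediction equals stored value; midpoint prediction is bounded
  p <- predict(s, data.frame(x = c(-30, -15), theta = c(0, 45)))
  expect_equal(p[1], 0, tolerance = 1e-9)
  expect_equal(p[2], s$F[4, 4], tolerance = 1e-9)
  # theta wrap: theta = 180 equals theta = 0
  expect_equal(predict(s, data.frame(x = -15, theta = 180)),
               predict(s, data.frame(x = -15, theta = 0)))
  expect_error(predict(s, data.frame(x = 100, theta = 0)), "outside")
  # curl-free input: residuals vanish
  r <- residuals(s)
  expect_lt(max(abs(r$x_edges)), 1e-8)
  expect_lt(max(abs(r$theta_edges)), 1e-8)
  expect_equal(unname(coef(s)["dFw2o"]), s$dFw2o)
  expect_output(print(s), "transfer free energy")
  expect_output(print(summary(s)), "Adsorption states")
})

test_that("surfaces round-trip through TSV files", {
  surf <- make_surface(cnc_surface_spec())
  fld <- sample_gradient_field(surf, coarse_grid(), noise_spec())
  s <- fes(fld, sweep = "ordered")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_fes(s, p)
  back <- read_fes(p, theta_periodic = TRUE, dFw2o = s$dFw2o)
  expect_equal(back$F, s$F, tolerance = 1e-9)
  expect_identical(back$grid$nx, s$grid$nx)
})
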