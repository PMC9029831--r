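#' @title Synthetic ground-truth generators
#' @description Every input of the analysis pipeline can be generated
#'   with known ground truth: analytic multi-well free-energy surfaces
#'   and their (optionally noisy) gradient samples, per-node AR(1)
#'   force/torque time series, and gap-confined water trajectories with
#'   prescribed anisotropic diffusion and orientational bias.  All
#'   generators are fully seeded and bit-reproducible.
#' @name synth
NULL

#' Specify an analytic benchmark surface
#'
#' The surface is a smooth sigmoidal ramp in x (the water-to-oil
#' solvation cost) plus a sum of negative Gaussian wells (adsorption
#' states), periodic in theta.  Well amplitudes are calibrated by a small
#' linear solve so that the surface value at each well centre equals the
#' requested depth exactly, despite ramp tails and well overlap.
#'
#' @param wells data.frame with columns `x` (Angstrom), `theta`
#'   (degrees), `depth` (kcal/mol, negative = bound state); optional
#'   per-well `width_x`, `width_theta` override the defaults.
#' @param ramp_height end-to-end free-energy rise across `x_range`
#'   (kcal/mol, default 318).
#' @param ramp_scale logistic width of the ramp (Angstrom, default 3).
#' @param x_range domain over which the ramp is referenced, default
#'   `c(-30, 30)`; the surface is 0 at `x_range[1]`.
#' @param width_x,width_theta default well widths (1.1 A, 10 deg).  The
#'   theta profile of a well is a wrapped Gaussian of width `width_theta`
#'   truncated to its first `n_harmonics` Fourier modes, so it is
#'   band-limited: torque loop sums around a coarse theta ring then close
#'   exactly.
#' @param n_harmonics harmonics kept in the theta well profile (default
#'   5, below the Nyquist mode of a 12-node ring).
#' @param theta_period periodicity of theta (180 deg for a twofold
#'   symmetric crystal cross-section).
#' @return an object of class `"surface_spec"`.
#' @export
surface_spec <- function(wells = NULL, ramp_height = 318, ramp_scale = 3,
                         x_range = c(-30, 30), width_x = 1.1,
                         width_theta = 10, n_harmonics = 5L,
                         theta_period = 180) {
  if (!is.null(wells)) {
    stopifnot(is.data.frame(wells),
              all(c("x", "theta", "depth") %in% names(wells)))
    if (is.null(wells$width_x)) wells$width_x <- width_x
    if (is.null(wells$width_theta)) wells$width_theta <- width_theta
    stopifnot(all(wells$width_x > 0), all(wells$width_theta > 0))
  }
  stopifnot(ramp_scale > 0, theta_period > 0, diff(x_range) > 0,
            n_harmonics >= 1)
  structure(list(wells = wells, ramp_height = ramp_height,
                 ramp_scale = ramp_scale, x_range = x_range,
                 n_harmonics = as.integer(n_harmonics),
                 theta_period = theta_period),
            class = "surface_spec")
}

#' Benchmark three-well adsorption surface
#'
#' The standard validation surface: three Gaussian wells emulating the
#' direct-contact state A at (-18 A, 95 deg, -3.586 kcal/mol), the
#' hydrophilic-surface/water/oil state B at (-21, 85, -3.460) and the
#' oleophilic/water/oil state C at (-17, 135, -2.384), on a 318 kcal/mol
#' water-to-oil ramp.
#' @return a [surface_spec()].
#' @export
cnc_surface_spec <- function() {
  surface_spec(wells = data.frame(
    x = c(-18, -21, -17), theta = c(95, 85, 135),
    depth = c(-3.586, -3.460, -2.384)))
}

#' Realise an analytic surface from its specification
#'
#' @param spec a [surface_spec()].
#' @return an object of class `"analytic_surface"` with vectorised
#'   functions `value(x, theta)` (kcal/mol), `fx(x, theta)` = -dF/dx
#'   (kcal/mol/A) and `Tz(x, theta)` = -dF/dtheta (kcal/mol/rad), all
#'   exact partial derivatives of `value`.
#' @export
make_surface <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  s <- spec$ramp_scale
  sig <- function(x) 1 / (1 + exp(-x / s))
  xlo <- spec$x_range[1]; xhi <- spec$x_range[2]
  A <- spec$ramp_height / (sig(xhi) - sig(xlo))
  ramp <- function(x) A * (sig(x) - sig(xlo))
  dramp <- function(x) { sg <- sig(x); A * sg * (1 - sg) / s }
  P <- spec$theta_period
  om <- 2 * pi / P                     # rad per degree of theta
  K <- spec$n_harmonics
  w <- spec$wells
  nw <- if (is.null(w)) 0L else nrow(w)
  ## theta profile: zero-mean wrapped Gaussian truncated to K harmonics,
  ## normalised to 1 at the well centre (band-limited, hence exactly
  ## summable on any ring with more than 2K nodes)
  tprof <- function(k) {
    b <- 2 * exp(-(seq_len(K) * om * w$width_theta[k])^2 / 2)
    list(b = b / sum(b))
  }
  profs <- if (nw > 0L) lapply(seq_len(nw), tprof)
  gth <- function(k, theta) {
    dd <- (theta - w$theta[k]) * om
    v <- 0
    for (q in seq_len(K)) v <- v + profs[[k]]$b[q] * cos(q * dd)
    v
  }
  dgth <- function(k, theta) {         # d/dtheta (per degree)
    dd <- (theta - w$theta[k]) * om
    v <- 0
    for (q in seq_len(K)) v <- v - profs[[k]]$b[q] * q * om * sin(q * dd)
    v
  }
  gx <- function(k, x) exp(-(x - w$x[k])^2 / (2 * w$width_x[k]^2))
  gk <- function(k, x, theta) gx(k, x) * gth(k, theta)
  amp <- numeric(0)
  if (nw > 0L) {
    G <- outer(seq_len(nw), seq_len(nw),
               Vectorize(function(m, k) gk(k, w$x[m], w$theta[m])))
    amp <- solve(G, ramp(w$x) - w$depth)
  }
  value <- function(x, theta) {
    v <- ramp(x) + 0 * theta
    for (k in seq_len(nw)) v <- v - amp[k] * gk(k, x, theta)
    v
  }
  dFdx <- function(x, theta) {
    v <- dramp(x) + 0 * theta
    for (k in seq_len(nw))
      v <- v - amp[k] * gth(k, theta) * gx(k, x) * (-(x - w$x[k]) / w$width_x[k]^2)
    v
  }
  dFdth <- function(x, theta) {   # per degree
    v <- 0 * x + 0 * theta
    for (k in seq_len(nw))
      v <- v - amp[k] * gx(k, x) * dgth(k, theta)
    v
  }
  structure(list(
    spec = spec, amplitudes = amp,
    value = value,
    fx = function(x, theta) -dFdx(x, theta),
    Tz = function(x, theta) -dFdth(x, theta) * 180 / pi),
    class = "analytic_surface")
}

#' @export
print.analytic_surface <- function(x, ...) {
  nw <- if (is.null(x$spec$wells)) 0L else nrow(x$spec$wells)
  cat(sprintf("Analytic surface: %d well(s), ramp %g kcal/mol over x in [%g, %g]\n",
              nw, x$spec$ramp_height, x$spec$x_range[1], x$spec$x_range[2]))
  invisible(x)
}

#' Specify gradient-sampling noise
#'
#' @param sigma_f,sigma_T per-sample fluctuation scale of the force
#'   (kcal/mol/A) and torque (kcal/mol/rad); node means get standard
#'   error sigma/sqrt(n_samples).
#' @param n_samples samples behind each node mean.
#' @param seed integer RNG seed.
#' @param ac_time optional AR(1) autocorrelation time (ps) for the
#'   time-series mode of [sample_gradient_field()].
#' @return an object of class `"noise_spec"`.
#' @export
noise_spec <- function(sigma_f = 0, sigma_T = 0, n_samples = 1L,
                       seed = NULL, ac_time = NULL) {
  stopifnot(sigma_f >= 0, sigma_T >= 0, n_samples >= 1)
  structure(list(sigma_f = sigma_f, sigma_T = sigma_T,
                 n_samples = as.integer(n_samples), seed = seed,
                 ac_time = ac_time), class = "noise_spec")
}

## minimally perturb a gradient sampled on an open chain so that the
## trapezoidal edge works reproduce the planted free-energy differences
## exactly; the one-parameter freedom (an alternating vector, which every
## pair-mean annihilates) is used to stay closest to the analytic values
.consistent_chain <- function(g_an, F, h) {
  n <- length(F)
  if (n < 2L) return(g_an)
  g <- numeric(n)
  g[1L] <- g_an[1L]
  for (i in seq_len(n - 1L)) g[i + 1L] <- 2 * (F[i] - F[i + 1L]) / h - g[i]
  a <- (-1)^(seq_len(n) - 1L)
  g + a * sum(a * (g_an - g)) / n
}

## ring analogue; solvable for even rings iff the alternating sum of F
## vanishes (guaranteed for band-limited theta profiles)
.consistent_ring <- function(g_an, F, h) {
  n <- length(F)
  if (n < 3L) return(g_an)
  if (n %% 2L == 1L) {
    ## odd ring: the pair-mean system is invertible
    M <- matrix(0, n, n)
    d <- numeric(n)
    for (j in seq_len(n)) {
      jp <- if (j == n) 1L else j + 1L
      M[j, j] <- M[j, jp] <- h / 2
      d[j] <- F[j] - F[jp]
    }
    return(solve(M, d))
  }
  g <- numeric(n)
  g[1L] <- g_an[1L]
  for (j in seq_len(n - 1L)) g[j + 1L] <- 2 * (F[j] - F[j + 1L]) / h - g[j]
  a <- (-1)^(seq_len(n) - 1L)
  g + a * sum(a * (g_an - g)) / n
}

#' Sample a (noisy) gradient field from an analytic surface
#'
#' Evaluates the mean force and torque of the surface at every grid node
#' and perturbs them with Gaussian noise of standard deviation
#' `sigma / sqrt(n_samples)` (the standard error a finite time average
#' would carry).  In the default `"discrete"` mode the noiseless node
#' values are the grid-consistent effective gradients: minimally adjusted
#' from the analytic derivatives so that the trapezoidal edge works
#' reproduce the planted free-energy differences exactly, making the
#' field exactly curl-free on the grid and the benchmark free of
#' quadrature bias.  `"analytic"` samples the pointwise derivatives
#' instead (carrying ordinary O(dx^2) integration error for features
#' narrower than the grid).  When `out_dir` is given, a stationary AR(1)
#' series of instantaneous samples (marginal sd `sigma`, autocorrelation
#' time `ac_time`) is written per node as TSV, the node means become the
#' sample means of those series, and a `manifest.tsv` plus a `truth.json`
#' sidecar are written alongside.
#'
#' @param surface an [make_surface()] result.
#' @param grid a [grid_spec()].
#' @param noise a [noise_spec()].
#' @param consistency `"discrete"` (default) or `"analytic"`; see above.
#' @param out_dir optional directory for the time-series mode.
#' @param dt sampling interval of written series (ps, default 0.005).
#' @return a [gradient_field()] with `fx_sem`/`Tz_sem` set; attributes
#'   `truth` (planted surface values at the nodes) and, in time-series
#'   mode, `manifest` (path).
#' @export
sample_gradient_field <- function(surface, grid, noise = noise_spec(),
                                  consistency = c("discrete", "analytic"),
                                  out_dir = NULL, dt = 0.005) {
  stopifnot(inherits(surface, "analytic_surface"), inherits(grid, "grid_spec"),
            inherits(noise, "noise_spec"))
  consistency <- match.arg(consistency)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  fx_true <- outer(grid$x, grid$theta, surface$fx)
  Tz_true <- outer(grid$x, grid$theta, surface$Tz)
  if (consistency == "discrete") {
    F_true <- outer(grid$x, grid$theta, surface$value)
    for (j in seq_len(grid$ntheta))
      fx_true[, j] <- .consistent_chain(fx_true[, j], F_true[, j], grid$dx)
    if (grid$ntheta > 1L) {
      hr <- grid$dtheta * pi / 180
      for (i in seq_len(grid$nx))
        Tz_true[i, ] <- if (grid$theta_periodic)
          .consistent_ring(Tz_true[i, ], F_true[i, ], hr)
        else .consistent_chain(Tz_true[i, ], F_true[i, ], hr)
    }
  }
  n <- noise$n_samples
  sem_f <- noise$sigma_f / sqrt(n)
  sem_T <- noise$sigma_T / sqrt(n)
  manifest <- NULL
  if (is.null(out_dir)) {
    fx <- fx_true + stats::rnorm(length(fx_true), 0, sem_f)
    Tz <- Tz_true + stats::rnorm(length(Tz_true), 0, sem_T)
  } else {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    phi <- if (is.null(noise$ac_time) || noise$ac_time <= 0) 0
           else exp(-dt / noise$ac_time)
    ar1 <- function(mu, sigma) {
      if (sigma == 0) return(rep(mu, n))
      e <- stats::rnorm(n, 0, sigma * sqrt(1 - phi^2))
      e[1L] <- stats::rnorm(1, 0, sigma)
      mu + as.numeric(stats::filter(e, phi, method = "recursive"))
    }
    fx <- Tz <- matrix(NA_real_, grid$nx, grid$ntheta)
    rows <- list()
    tvec <- dt * (seq_len(n) - 1L)
    for (j in seq_len(grid$ntheta)) for (i in seq_len(grid$nx)) {
      sf <- ar1(fx_true[i, j], noise$sigma_f)
      st <- ar1(Tz_true[i, j], noise$sigma_T)
      fn <- sprintf("node_x%+05.1f_th%05.1f.tsv", grid$x[i], grid$theta[j])
      .write_tsv(data.frame(t = tvec, fx = sf, Tz = st), file.path(out_dir, fn))
      fx[i, j] <- mean(sf); Tz[i, j] <- mean(st)
      rows[[length(rows) + 1L]] <- data.frame(x = grid$x[i],
                                              theta = grid$theta[j], path = fn)
    }
    manifest <- file.path(out_dir, "manifest.tsv")
    .write_tsv(do.call(rbind, rows), manifest)
    jsonlite::write_json(
      list(ramp_height = surface$spec$ramp_height,
           wells = surface$spec$wells, sigma_f = noise$sigma_f,
           sigma_T = noise$sigma_T, n_samples = n, dt = dt,
           ac_time = noise$ac_time, seed = noise$seed),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  field <- gradient_field(grid, fx, Tz,
                          matrix(sem_f, grid$nx, grid$ntheta),
                          matrix(sem_T, grid$nx, grid$ntheta))
  attr(field, "truth") <- list(F = outer(grid$x, grid$theta, surface$value),
                               fx = fx_true, Tz = Tz_true)
  attr(field, "manifest") <- manifest
  field
}

#' Specify a gap-confined water trajectory
#'
#' Emulates the thin water layer between the crystal surface and the oil
#' phase: anisotropic Brownian oxygen motion with reflective walls at the
#' slab bounds in x and periodic wrapping in y and z, rigid water
#' geometry, and an orientational bias favouring dipoles lying in the
#' interface plane (theta ~ 90 deg) with a slight tilt toward the
#' crystal.
#'
#' @param slab `c(x_min, x_max)` reflective wall positions (Angstrom).
#' @param box length-3 box (Angstrom); the slab must lie inside `box[1]`.
#' @param n_molecules number of resident water molecules.
#' @param D per-axis diffusion coefficients `c(Dx, Dy, Dz)` in
#'   Angstrom^2/ps (= 1e-8 m^2/s).
#' @param dt frame spacing (ps).
#' @param n_frames number of frames.
#' @param kappa_theta strength of the sin(theta) orientational bias
#'   (0 = isotropic).
#' @param kappa_shift strength of the dipole-toward-crystal tilt (shifts
#'   the theta peak slightly above 90 deg).
#' @param phi_kappa concentration of the H-H axis around the interface
#'   plane (phi ~ 0); 0 = uniform.
#' @param n_leavers molecules planted with a single-frame excursion just
#'   outside the slab, to exercise strict residency filtering.
#' @param seed integer RNG seed.
#' @return an object of class `"gap_spec"`.
#' @export
gap_spec <- function(slab = c(-21, -16), box = c(60, 40, 41.4),
                     n_molecules = 100L, D = c(0.02, 0.17, 0.12),
                     dt = 1, n_frames = 501L, kappa_theta = 0,
                     kappa_shift = 0, phi_kappa = 0, n_leavers = 0L,
                     seed = NULL) {
  stopifnot(length(slab) == 2, slab[1] < slab[2], length(box) == 3,
            all(box > 0), length(D) == 3, all(D >= 0), dt > 0,
            n_frames >= 2, n_molecules >= 1, n_leavers >= 0)
  structure(list(slab = slab, box = box, n_molecules = as.integer(n_molecules),
                 D = D, dt = dt, n_frames = as.integer(n_frames),
                 kappa_theta = kappa_theta, kappa_shift = kappa_shift,
                 phi_kappa = phi_kappa, n_leavers = as.integer(n_leavers),
                 seed = seed), class = "gap_spec")
}

#' Benchmark gap specifications for the two water-layer states
#'
#' Type B (hydrophilic surface / water / oil): 101 resident molecules
#' with planted D = (0.02, 0.17, 0.12) A^2/ps.  Type C (oleophilic
#' surface / water / oil): 148 molecules with D = (0.005, 0.078, 0.085).
#' Both use a 5 A reflective gap, 0.5 ns of frames at 1 ps spacing, and
#' an orientational bias peaking slightly above theta = 90 deg.
#'
#' @param type `"B"` or `"C"`.
#' @param seed RNG seed.
#' @return a [gap_spec()].
#' @export
cnc_gap_spec <- function(type = c("B", "C"), seed = NULL) {
  type <- match.arg(type)
  if (type == "B")
    gap_spec(slab = c(-21, -16), n_molecules = 101L,
             D = c(0.02, 0.17, 0.12), dt = 1, n_frames = 501L,
             kappa_theta = 4, kappa_shift = 0.2, phi_kappa = 40, seed = seed)
  else
    gap_spec(slab = c(-20, -15), n_molecules = 148L,
             D = c(0.005, 0.078, 0.085), dt = 1, n_frames = 501L,
             kappa_theta = 4, kappa_shift = 0.2, phi_kappa = 40, seed = seed)
}

## biased polar angle sampler: density prop. to
## exp(kappa_s * sin(theta) - kappa_c * cos(theta)) on cos(theta) ~ U(-1,1)
.sample_costheta <- function(m, ks, kc) {
  if (ks == 0 && kc == 0) return(stats::runif(m, -1, 1))
  M <- sqrt(ks^2 + kc^2)            # bound on the exponent
  out <- numeric(0)
  while (length(out) < m) {
    c0 <- stats::runif(2L * (m - length(out)), -1, 1)
    w <- exp(ks * sqrt(1 - c0^2) - kc * c0 - M)
    out <- c(out, c0[stats::runif(length(c0)) < w])
  }
  out[seq_len(m)]
}

#' Generate a gap-confined Brownian water trajectory
#'
#' Oxygen positions take independent Gaussian steps of per-axis variance
#' `2 * D * dt`, reflected at the slab walls in x and wrapped into the
#' periodic box in y and z.  Hydrogens are placed at rigid TIP3P-like
#' geometry (O-H 0.9572 A, H-O-H 104.52 deg) with dipole orientations
#' drawn each frame from the kappa-biased distribution.  Leaver molecules
#' (appended after the residents) are displaced just outside the slab for
#' exactly one mid-trajectory frame.
#'
#' @param spec a [gap_spec()].
#' @return a [trajectory()] with attribute `truth`: the planted `D`,
#'   `slab`, `resident_ids` and `leaver_ids`.
#' @export
brownian_gap_trajectory <- function(spec) {
  stopifnot(inherits(spec, "gap_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  nm <- spec$n_molecules + spec$n_leavers
  nf <- spec$n_frames
  sd_step <- sqrt(2 * spec$D * spec$dt)
  ox <- matrix(NA_real_, nf, nm)
  oy <- matrix(NA_real_, nf, nm)
  oz <- matrix(NA_real_, nf, nm)
  ox[1L, ] <- stats::runif(nm, spec$slab[1], spec$slab[2])
  oy[1L, ] <- stats::runif(nm, 0, spec$box[2])
  oz[1L, ] <- stats::runif(nm, 0, spec$box[3])
  reflect <- function(p, lo, hi) {
    span <- hi - lo
    q <- (p - lo) %% (2 * span)
    lo + ifelse(q > span, 2 * span - q, q)
  }
  for (f in 2:nf) {
    ox[f, ] <- reflect(ox[f - 1L, ] + stats::rnorm(nm, 0, sd_step[1]),
                       spec$slab[1], spec$slab[2])
    oy[f, ] <- (oy[f - 1L, ] + stats::rnorm(nm, 0, sd_step[2])) %% spec$box[2]
    oz[f, ] <- (oz[f - 1L, ] + stats::rnorm(nm, 0, sd_step[3])) %% spec$box[3]
  }
  if (spec$n_leavers > 0L) {
    mid <- nf %/% 2L + 1L
    leavers <- spec$n_molecules + seq_len(spec$n_leavers)
    ox[mid, leavers] <- spec$slab[2] + 0.5
  }
  ## rigid water geometry
  r_oh <- 0.9572
  beta <- 104.52 / 2 * pi / 180
  coords <- array(NA_real_, c(nf, 3L * nm, 3L))
  oi <- 3L * (seq_len(nm) - 1L) + 1L
  for (f in seq_len(nf)) {
    cth <- .sample_costheta(nm, spec$kappa_theta, spec$kappa_shift)
    sth <- sqrt(pmax(0, 1 - cth^2))
    psi <- stats::runif(nm, 0, 2 * pi)
    d <- cbind(cth, sth * cos(psi), sth * sin(psi))
    ## orthonormal frame perpendicular to d: u ~ d x n (n = +x), v = d x u
    u <- cbind(0, d[, 3], -d[, 2])
    lu <- sqrt(rowSums(u^2))
    pole <- lu < 1e-12
    u[pole, ] <- matrix(rep(c(0, 1, 0), sum(pole)), ncol = 3, byrow = TRUE)
    lu[pole] <- 1
    u <- u / lu
    v <- cbind(d[, 2] * u[, 3] - d[, 3] * u[, 2],
               d[, 3] * u[, 1] - d[, 1] * u[, 3],
               d[, 1] * u[, 2] - d[, 2] * u[, 1])
    chi <- if (spec$phi_kappa > 0) stats::rnorm(nm, 0, 1 / sqrt(spec$phi_kappa))
           else stats::runif(nm, 0, 2 * pi)
    e <- cos(chi) * u + sin(chi) * v
    O <- cbind(ox[f, ], oy[f, ], oz[f, ])
    H1 <- O + r_oh * (cos(beta) * d + sin(beta) * e)
    H2 <- O + r_oh * (cos(beta) * d - sin(beta) * e)
    ## wrap hydrogens into the periodic box (y, z) like the oxygens
    for (ax in 2:3) {
      H1[, ax] <- H1[, ax] %% spec$box[ax]
      H2[, ax] <- H2[, ax] %% spec$box[ax]
    }
    coords[f, oi, ] <- O
    coords[f, oi + 1L, ] <- H1
    coords[f, oi + 2L, ] <- H2
  }
  traj <- trajectory(spec$dt * (seq_len(nf) - 1L), spec$box, coords)
  attr(traj, "truth") <- list(
    D = spec$D, slab = spec$slab,
    resident_ids = seq_len(spec$n_molecules),
    leaver_ids = spec$n_molecules + seq_len(spec$n_leavers))
  traj
}

#' Cellulose nanocrystal bookkeeping
#'
#' Geometry counters for the simulated crystal: 4 x 4 cellulose chains,
#' eight anhydroglucose units per chain under periodic chain bonding, 21
#' atoms per unit (C6H10O5), and the cross-section widths of the two
#' inequivalent faces.
#'
#' @param chains_x,chains_y chains across the crystal cross-section.
#' @param units_per_chain glucose units per (periodically bonded) chain.
#' @param atoms_per_unit atoms per anhydroglucose unit.
#' @param width_oleophil,width_hydrophil face widths in Angstrom.
#' @return an object of class `"crystal_spec"`.
#' @export
crystal_spec <- function(chains_x = 4L, chains_y = 4L, units_per_chain = 8L,
                         atoms_per_unit = 21L, width_oleophil = 36,
                         width_hydrophil = 20) {
  stopifnot(chains_x > 0, chains_y > 0, units_per_chain > 0,
            atoms_per_unit > 0, width_oleophil > 0, width_hydrophil > 0)
  structure(list(chains_x = as.integer(chains_x),
                 chains_y = as.integer(chains_y),
                 units_per_chain = as.integer(units_per_chain),
                 atoms_per_unit = as.integer(atoms_per_unit),
                 width_oleophil = width_oleophil,
                 width_hydrophil = width_hydrophil),
            class = "crystal_spec")
}

#' Total atom count of the crystal
#' @param spec a [crystal_spec()].
#' @return integer: chains_x * chains_y * units_per_chain * atoms_per_unit.
#' @export
crystal_atom_count <- function(spec = crystal_spec()) {
  stopifnot(inherits(spec, "crystal_spec"))
  spec$chains_x * spec$chains_y * spec$units_per_chain * spec$atoms_per_unit
}

#' Oleophilic-to-hydrophilic face width ratio
#' @param spec a [crystal_spec()].
#' @return scalar ratio (1.8 for the default 36 A : 20 A crystal).
#' @export
surface_width_ratio <- function(spec = crystal_spec()) {
  stopifnot(inherits(spec, "crystal_spec"))
  spec$width_oleophil / spec$width_hydrophil
}
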