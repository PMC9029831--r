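#' @title Anisotropic self-diffusion of gap water
#' @description Water confined in the few-Angstrom gap between the
#'   crystal surface and the oil phase diffuses anisotropically: motion
#'   normal to the surface (x) is wall-limited while in-plane motion
#'   (y, z) is slowed relative to bulk.  The per-axis mean-square
#'   displacement MSD_a(t) = <(a_i(t0+t) - a_i(t0))^2>, averaged over all
#'   time origins t0 and gap-resident molecules i, gives the diffusion
#'   coefficient D_a as half the long-time slope.
#' @name msd
NULL

#' Identify gap-resident molecules
#'
#' Returns the molecules whose oxygen x coordinate lies inside the slab
#' at every frame of the sampling window (strict residency).  An optional
#' tolerance admits molecules with at most `allow_excursions` frames
#' outside.
#'
#' @param traj a [trajectory()].
#' @param slab `c(x_min, x_max)` in Angstrom.
#' @param window optional `c(t_min, t_max)` in ps; default the full
#'   trajectory.
#' @param allow_excursions maximum number of frames a molecule may spend
#'   outside the slab and still count as resident (default 0).
#' @return integer vector of molecule ids (possibly empty, with a
#'   warning).
#' @export
gap_residents <- function(traj, slab, window = NULL, allow_excursions = 0L) {
  stopifnot(inherits(traj, "trajectory"), length(slab) == 2)
  frames <- if (is.null(window)) seq_len(traj$n_frames)
            else which(traj$times >= window[1] & traj$times <= window[2])
  if (!length(frames)) stop("window contains no frames", call. = FALSE)
  ox <- traj$coords[frames, .o_idx(seq_len(traj$n_molecules)), 1, drop = FALSE]
  ox <- array(ox, dim(ox)[1:2])
  outside <- colSums(ox < slab[1] | ox > slab[2])
  ids <- which(outside <= allow_excursions)
  if (!length(ids)) warning("no gap-resident molecules in the window", call. = FALSE)
  ids
}

#' Per-axis mean-square displacement with multiple time origins
#'
#' MSD per lag and axis, averaged over every valid (molecule, origin)
#' pair.  Coordinates are defensively unwrapped across the periodic
#' boundaries first; oxygen positions represent the molecules.
#'
#' @param traj a [trajectory()] with uniform frame spacing.
#' @param ids molecule ids to include (e.g. from [gap_residents()]).
#' @param max_lag largest lag in ps; default (and cap, with a warning)
#'   half the trajectory duration, keeping the pair counts meaningful.
#' @return an object of class `"msd_curve"`: `lag` (ps, starting at 0),
#'   `msd` (matrix, columns `x`, `y`, `z`, Angstrom^2), `n_pairs` per
#'   lag, `n_molecules`.
#' @export
msd_curve <- function(traj, ids, max_lag = NULL) {
  stopifnot(inherits(traj, "trajectory"), length(ids) >= 1)
  traj <- unwrap_pbc(traj)
  dts <- diff(traj$times)
  if (max(abs(dts - dts[1])) > 1e-9 * dts[1])
    stop("msd_curve requires uniform frame spacing", call. = FALSE)
  dt <- dts[1]
  nf <- traj$n_frames
  span <- traj$times[nf] - traj$times[1]
  if (is.null(max_lag)) max_lag <- span / 2
  if (max_lag >= span) {
    warning("max_lag >= trajectory duration; truncating", call. = FALSE)
    max_lag <- span - dt
  }
  nlag <- floor(max_lag / dt + 1e-9)
  oi <- .o_idx(ids)
  msd <- matrix(0, nlag + 1L, 3, dimnames = list(NULL, c("x", "y", "z")))
  n_pairs <- integer(nlag + 1L)
  n_pairs[1L] <- nf * length(ids)
  for (ax in 1:3) {
    X <- array(traj$coords[, oi, ax], c(nf, length(ids)))
    for (k in seq_len(nlag)) {
      d <- X[(1L + k):nf, , drop = FALSE] - X[1L:(nf - k), , drop = FALSE]
      msd[k + 1L, ax] <- mean(d^2)
      if (ax == 1L) n_pairs[k + 1L] <- length(d)
    }
  }
  structure(list(lag = dt * (0:nlag), msd = msd, n_pairs = n_pairs,
                 n_molecules = length(ids)),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d molecules, lags 0..%g ps (%d points)\n",
              x$n_molecules, max(x$lag), length(x$lag)))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::matplot(x$lag, x$msd, type = "l", lty = 1,
                    xlab = "lag [ps]", ylab = "MSD [A^2]", ...)
  graphics::legend("topleft", legend = colnames(x$msd), lty = 1, col = 1:3)
}

#' Diffusion coefficients from the long-time MSD slope
#'
#' Ordinary least-squares fit of MSD versus lag inside the fit window;
#' the one-dimensional diffusion coefficient is half the slope.  Values
#' are reported in 1e-8 m^2/s, numerically equal to Angstrom^2/ps.
#'
#' @param curve an [msd_curve()].
#' @param fit_window `c(t_min, t_max)` in ps; default the 25--50% span of
#'   the computed lags, where the displacement statistics are still well
#'   averaged but short-time transients have decayed.
#' @return an object of class `"diffusion_fit"`: `D` (named vector,
#'   1e-8 m^2/s), `fit_window`, `n_molecules`.  Negative fitted slopes
#'   are clamped to 0 with a warning.
#' @export
fit_diffusion <- function(curve, fit_window = NULL) {
  stopifnot(inherits(curve, "msd_curve"))
  if (is.null(fit_window)) fit_window <- max(curve$lag) * c(0.25, 0.5)
  sel <- curve$lag >= fit_window[1] & curve$lag <= fit_window[2]
  if (sum(sel) < 3) stop("fewer than 3 lags in the fit window", call. = FALSE)
  D <- vapply(1:3, function(ax) {
    fit <- stats::lm.fit(cbind(1, curve$lag[sel]), curve$msd[sel, ax])
    unname(fit$coefficients[2L]) / 2
  }, numeric(1))
  names(D) <- colnames(curve$msd)
  if (any(D < 0)) {
    warning("negative fitted slope clamped to 0 for axis ",
            paste(names(D)[D < 0], collapse = ", "), call. = FALSE)
    D[D < 0] <- 0
  }
  structure(list(D = D, fit_window = fit_window,
                 n_molecules = curve$n_molecules),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("Diffusion coefficients [1e-8 m^2/s], fit window %g..%g ps (n = %d molecules):\n",
              x$fit_window[1], x$fit_window[2], x$n_molecules))
  cat(sprintf("  Dx = %.4g  Dy = %.4g  Dz = %.4g\n", x$D[1], x$D[2], x$D[3]))
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) object$D
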