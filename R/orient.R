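#' @title Orientation of interfacial water
#' @description Each water molecule carries two orientation angles with
#'   respect to the interface normal n (the +x unit vector, pointing from
#'   the water phase into the oil): the polar angle theta between the
#'   dipole direction d and n, and the rotation angle phi around d,
#'   measured between the H-H vector and d x n.  phi = 0 means the H-H
#'   axis lies parallel to the interface; theta distributions require the
#'   sin(theta) Jacobian correction to be flat for isotropic orientations.
#' @name orient
NULL

.cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

## minimum-image of a displacement vector in an orthorhombic box
.min_image <- function(v, box) if (is.null(box)) v else v - box * round(v / box)

#' Dipole and H-H unit vectors of one water molecule
#'
#' The dipole direction is computed geometrically as the unit bisector
#' from the oxygen through the H,H midpoint (identical to the charge
#' dipole for rigid 3-site water).  Intramolecular vectors are
#' minimum-imaged, so molecules split across a periodic boundary are
#' handled correctly.
#'
#' @param o,h1,h2 length-3 coordinates (Angstrom).
#' @param box optional length-3 box for the minimum-image convention.
#' @return list with unit vectors `d` (dipole direction) and `r_hh`
#'   (H1 -> H2).
#' @export
water_vectors <- function(o, h1, h2, box = NULL) {
  v1 <- .min_image(h1 - o, box)
  v2 <- .min_image(h2 - o, box)
  for (v in list(v1, v2)) {
    len <- sqrt(sum(v^2))
    if (len < 0.5 || len > 1.5)
      stop("O-H distance ", format(len), " A outside sanity window [0.5, 1.5]",
           call. = FALSE)
  }
  m <- (v1 + v2) / 2
  lm <- sqrt(sum(m^2))
  rhh <- v2 - v1
  lr <- sqrt(sum(rhh^2))
  if (lm < 1e-8 || lr < 1e-8)
    stop("degenerate water geometry (collinear or coincident hydrogens)",
         call. = FALSE)
  list(d = m / lm, r_hh = rhh / lr)
}

#' Orientation angles of a water molecule relative to the interface
#'
#' @param d unit dipole direction.
#' @param r_hh unit H-H vector.
#' @param n unit interface normal (default +x, water -> oil).
#' @return list with `theta` (degrees, 0..180) and `phi` (degrees,
#'   folded to 0..90 because hydrogen labels are arbitrary).  `phi` is
#'   `NA` when the dipole is at a pole (theta = 0 or 180), where the
#'   rotation angle is undefined.
#' @export
orientation_angles <- function(d, r_hh, n = c(1, 0, 0)) {
  clamp <- function(v) pmin(1, pmax(-1, v))
  theta <- acos(clamp(sum(d * n))) * 180 / pi
  u <- .cross3(d, n)
  lu <- sqrt(sum(u^2))
  phi <- if (lu < 1e-9) NA_real_
  else acos(clamp(abs(sum(r_hh * u)) / lu)) * 180 / pi
  list(theta = theta, phi = phi)
}

#' Orientation angles of all gap water in a trajectory
#'
#' Computes (theta, phi) for every molecule whose oxygen lies in the slab
#' (per frame), vectorised across molecules.
#'
#' @param traj a [trajectory()].
#' @param slab optional `c(x_min, x_max)` selecting gap molecules by
#'   oxygen x position; `NULL` takes all molecules.
#' @param n unit interface normal (default +x).
#' @return data.frame with columns `frame`, `molecule`, `theta`, `phi`
#'   (degrees; `phi` is `NA` at the poles).
#' @export
traj_orientations <- function(traj, slab = NULL, n = c(1, 0, 0)) {
  box <- traj$box
  res <- vector("list", traj$n_frames)
  oi <- .o_idx(seq_len(traj$n_molecules))
  for (f in seq_len(traj$n_frames)) {
    O <- traj$coords[f, oi, , drop = TRUE]
    H1 <- traj$coords[f, oi + 1L, , drop = TRUE]
    H2 <- traj$coords[f, oi + 2L, , drop = TRUE]
    if (is.null(dim(O))) { O <- matrix(O, 1); H1 <- matrix(H1, 1); H2 <- matrix(H2, 1) }
    sel <- if (is.null(slab)) seq_len(nrow(O))
           else which(O[, 1] >= slab[1] & O[, 1] <= slab[2])
    if (!length(sel)) next
    mi <- function(V) V - rep(box, each = nrow(V)) * round(V / rep(box, each = nrow(V)))
    v1 <- mi(H1[sel, , drop = FALSE] - O[sel, , drop = FALSE])
    v2 <- mi(H2[sel, , drop = FALSE] - O[sel, , drop = FALSE])
    m <- (v1 + v2) / 2
    d <- m / sqrt(rowSums(m^2))
    rhh <- v2 - v1
    rhh <- rhh / sqrt(rowSums(rhh^2))
    theta <- acos(pmin(1, pmax(-1, d %*% n))) * 180 / pi
    ## u = d x n, row-wise
    u <- cbind(d[, 2] * n[3] - d[, 3] * n[2],
               d[, 3] * n[1] - d[, 1] * n[3],
               d[, 1] * n[2] - d[, 2] * n[1])
    lu <- sqrt(rowSums(u^2))
    cphi <- abs(rowSums(rhh * u)) / lu
    phi <- acos(pmin(1, cphi)) * 180 / pi
    phi[lu < 1e-9] <- NA_real_
    res[[f]] <- data.frame(frame = f, molecule = sel,
                           theta = as.numeric(theta), phi = phi)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(frame = integer(0), molecule = integer(0),
                      theta = numeric(0), phi = numeric(0))
  out
}

#' Jacobian-corrected polar-angle distribution
#'
#' Histogram of theta over [0, 180] degrees with each bin divided by the
#' exact integral of sin(theta) over the bin (not the centre value, which
#' would be singular at the poles), then normalised to unit integral.
#' Isotropic orientations yield a flat corrected distribution.
#'
#' @param theta_samples polar angles in degrees, within [0, 180].
#' @param bins number of bins (>= 2, default 36).
#' @return an object of class `"angular_dist"`: `breaks`, `mids`
#'   (degrees), `density` (per degree, integrates to 1), `counts`,
#'   `corrected = TRUE`.
#' @export
jacobian_corrected_hist <- function(theta_samples, bins = 36) {
  theta_samples <- theta_samples[!is.na(theta_samples)]
  if (!length(theta_samples)) stop("no orientation samples", call. = FALSE)
  stopifnot(bins >= 2, all(theta_samples >= 0), all(theta_samples <= 180))
  breaks <- seq(0, 180, length.out = bins + 1L)
  counts <- graphics::hist(theta_samples, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  ## exact sin(theta) weight per bin: integral of sin over the bin (rad)
  br <- breaks * pi / 180
  w <- cos(br[-length(br)]) - cos(br[-1L])
  dens <- counts / w
  width <- diff(breaks)
  dens <- dens / sum(dens * width)
  structure(list(breaks = breaks, mids = (breaks[-1L] + breaks[-(bins + 1L)]) / 2,
                 density = dens, counts = counts, corrected = TRUE,
                 angle = "theta"),
            class = "angular_dist")
}

#' Conditional distribution of the rotation angle phi
#'
#' Histogram of phi over [0, 90] degrees for samples whose theta lies in
#' a window.  phi is a rotation about the dipole axis, whose uniform
#' measure is flat, so no Jacobian correction applies; pole samples
#' (phi undefined) are excluded.
#'
#' @param angles data.frame with columns `theta`, `phi` (degrees), e.g.
#'   from [traj_orientations()].
#' @param theta_window `c(min, max)` in degrees within [0, 180].
#' @param bins number of bins (default 18).
#' @return an object of class `"angular_dist"` (`corrected = FALSE`).
#' @export
phi_hist_conditional <- function(angles, theta_window, bins = 18) {
  stopifnot(all(c("theta", "phi") %in% names(angles)),
            length(theta_window) == 2,
            theta_window[1] >= 0, theta_window[2] <= 180)
  phi <- angles$phi[angles$theta >= theta_window[1] &
                    angles$theta <= theta_window[2] & !is.na(angles$phi)]
  if (!length(phi))
    stop("no samples with theta in [", theta_window[1], ", ",
         theta_window[2], "]", call. = FALSE)
  breaks <- seq(0, 90, length.out = bins + 1L)
  counts <- graphics::hist(phi, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  width <- diff(breaks)
  dens <- counts / sum(counts * width)
  structure(list(breaks = breaks, mids = (breaks[-1L] + breaks[-(bins + 1L)]) / 2,
                 density = dens, counts = counts, corrected = FALSE,
                 angle = "phi"),
            class = "angular_dist")
}

#' @export
print.angular_dist <- function(x, ...) {
  cat(sprintf("%s distribution: %d bins over [%g, %g] deg, %d samples%s\n",
              x$angle, length(x$mids), min(x$breaks), max(x$breaks),
              sum(x$counts),
              if (x$corrected) " (sin-theta Jacobian corrected)" else ""))
  cat(sprintf("  peak bin at %g deg\n", x$mids[which.max(x$density)]))
  invisible(x)
}

#' @export
plot.angular_dist <- function(x, ...) {
  graphics::plot(x$mids, x$density, type = "s",
                 xlab = sprintf("%s [deg]", x$angle),
                 ylab = "probability density [1/deg]", ...)
}
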