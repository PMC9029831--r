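#' @title Free-energy surface reconstruction from mean forces
#' @description The mean force fx and mean torque Tz on the restrained
#'   crystal are minus the partial derivatives of the free energy
#'   F(x, theta).  F is recovered by (i) thermodynamic integration of
#'   -fx along x at fixed theta to set Dirichlet boundaries, and (ii)
#'   iterative relaxation of the discrete gradient-consistency
#'   equations, in which each node is the mean of the four values
#'   predicted from its neighbours by trapezoidal force/torque work
#'   terms.  For noisy (non-curl-free) fields the fixed point is the
#'   least-squares-consistent surface; [solve_fes_exact()] computes the
#'   same fixed point by a direct sparse solve.
#' @name pmf
NULL

## trapezoidal work along +x from node (i,j) to (i+1,j): F gains -mean(fx)*dx
.work_x <- function(field, i, j)
  -0.5 * (field$fx[i, j] + field$fx[i + 1L, j]) * field$grid$dx

## trapezoidal work along +theta from (i,j) to (i,jp); dtheta in radians
.work_t <- function(field, i, j, jp)
  -0.5 * (field$Tz[i, j] + field$Tz[i, jp]) * field$grid$dtheta * pi / 180

#' Integrate the mean force along one theta row
#'
#' Cumulative trapezoidal integral of `-fx` along x at fixed theta, with
#' F(x_min) = 0: the thermodynamic-integration estimate of the free-energy
#' profile for that orientation.
#'
#' @param field a [gradient_field()].
#' @param theta_index row index (1-based).
#' @return numeric vector of F values (kcal/mol) at every x node.
#' @export
line_integrate_x <- function(field, theta_index) {
  g <- field$grid
  stopifnot(theta_index >= 1, theta_index <= g$ntheta)
  segs <- vapply(seq_len(g$nx - 1L), function(i)
    .work_x(field, i, theta_index), numeric(1))
  c(0, cumsum(segs))
}

#' Fix the Dirichlet boundaries of the surface from line integrals
#'
#' Sets F = 0 on the x_min edge (bulk water reference).  Each theta row is
#' integrated across the full x range; the per-row end values would all
#' equal the water-to-oil transfer free energy for noiseless data, so
#' their arithmetic mean is taken as `dFw2o` and imposed on the whole
#' x_max edge.
#'
#' @param field a [gradient_field()] covering the full x range.
#' @return an object of class `"fes_boundary"` with elements `left`,
#'   `right` (per-theta-row Dirichlet values), the scalar `dFw2o`, and the
#'   raw per-row integrals `row_integrals`.
#' @export
set_boundaries <- function(field) {
  g <- field$grid
  ends <- vapply(seq_len(g$ntheta), function(j)
    line_integrate_x(field, j)[g$nx], numeric(1))
  dFw2o <- mean(ends)
  structure(list(left = rep(0, g$ntheta), right = rep(dFw2o, g$ntheta),
                 bottom = NULL, top = NULL,
                 dFw2o = dFw2o, row_integrals = ends),
            class = "fes_boundary")
}

## ---- shared node topology for relaxation and the direct solver ----
## Free nodes get up to four neighbour slots; absent neighbours point at a
## phantom zero cell so the update is branch-free.
.fes_topology <- function(field, bnd) {
  g <- field$grid
  nx <- g$nx; nt <- g$ntheta
  ntot <- nx * nt
  idx <- function(i, j) (j - 1L) * nx + i
  full_ring <- !is.null(bnd$bottom)
  if (full_ring && g$theta_periodic)
    stop("theta-edge Dirichlet data on a periodic grid", call. = FALSE)

  fixed <- matrix(FALSE, nx, nt)
  F0 <- matrix(0, nx, nt)
  fixed[1L, ] <- TRUE;  F0[1L, ] <- bnd$left
  fixed[nx, ] <- TRUE;  F0[nx, ] <- bnd$right
  if (full_ring) {
    fixed[, 1L] <- TRUE; F0[, 1L] <- bnd$bottom
    fixed[, nt] <- TRUE; F0[, nt] <- bnd$top
  }
  ## initial guess: linear interpolation in x between the x-edges
  for (j in seq_len(nt)) {
    w <- (g$x - g$x_min) / (g$x_max - g$x_min)
    ini <- (1 - w) * F0[1L, j] + w * F0[nx, j]
    F0[!fixed[, j], j] <- ini[!fixed[, j]]
  }

  free <- which(!fixed)          # linear indices, column-major
  m <- length(free)
  P <- ntot + 1L                 # phantom cell
  n_idx <- matrix(P, m, 4L)
  offs <- matrix(0, m, 4L)
  fi <- ((free - 1L) %% nx) + 1L
  fj <- ((free - 1L) %/% nx) + 1L
  for (k in seq_len(m)) {
    i <- fi[k]; j <- fj[k]
    ## x neighbours always exist for free nodes (x edges are fixed)
    n_idx[k, 1L] <- idx(i - 1L, j); offs[k, 1L] <- .work_x(field, i - 1L, j)
    n_idx[k, 2L] <- idx(i + 1L, j); offs[k, 2L] <- -.work_x(field, i, j)
    jm <- j - 1L; jp <- j + 1L
    if (g$theta_periodic) { if (jm < 1L) jm <- nt; if (jp > nt) jp <- 1L }
    if (jm >= 1L) {
      n_idx[k, 3L] <- idx(i, jm); offs[k, 3L] <- .work_t(field, i, jm, j)
    }
    if (jp <= nt) {
      n_idx[k, 4L] <- idx(i, jp); offs[k, 4L] <- -.work_t(field, i, j, jp)
    }
  }
  deg <- rowSums(n_idx != P)
  list(grid = g, free = free, fixed = fixed, F0 = F0, n_idx = n_idx,
       offs = offs, bsum = rowSums(offs), deg = deg, phantom = P)
}

## max stationarity residual over free nodes (vectorised)
.fes_residual <- function(topo, Fv) {
  pred <- (Fv[topo$n_idx[, 1L]] + Fv[topo$n_idx[, 2L]] +
           Fv[topo$n_idx[, 3L]] + Fv[topo$n_idx[, 4L]] + topo$bsum) / topo$deg
  max(abs(pred - Fv[topo$free]))
}

#' Fit a free-energy surface by iterative relaxation
#'
#' The central fitting function.  Interior nodes are repeatedly replaced
#' by the mean of the values predicted from their neighbours via the
#' trapezoidal force/torque work terms, until the largest single-node
#' update in a full pass falls below `tol`.  The fixed point solves the
#' least-squares consistency system and is independent of sweep order and
#' seed.
#'
#' @param field a [gradient_field()].
#' @param boundaries a `"fes_boundary"` object; defaults to
#'   [set_boundaries()] of `field`.
#' @param tol convergence tolerance on the max node update per sweep,
#'   kcal/mol (default 1e-10).
#' @param max_iter maximum number of single-node updates (default 1e6).
#' @param sweep `"random"` visits the free nodes in a freshly shuffled
#'   order each pass (the reference procedure); `"ordered"` uses a fixed
#'   lexicographic Gauss-Seidel order.  Both reach the same fixed point.
#' @param seed optional integer seed for the random sweep order.
#' @return an object of class `"fes"`: fields `grid`, `F` (nx x ntheta
#'   matrix, kcal/mol), `boundaries`, `dFw2o`, `F0` (reference value of
#'   the bulk-water plane), `residual`, `iterations`, `converged`,
#'   `field`.  Methods: [print.fes()], [summary.fes()], [plot.fes()],
#'   [predict.fes()], [residuals.fes()], [coef.fes()].
#' @seealso [solve_fes_exact()] for the direct sparse solution,
#'   [refine_fes()] for fine-grid refinement.
#' @export
fes <- function(field, boundaries = NULL, tol = 1e-10, max_iter = 1e6,
                sweep = c("random", "ordered"), seed = NULL) {
  stopifnot(inherits(field, "gradient_field"))
  sweep <- match.arg(sweep)
  if (is.null(boundaries)) boundaries <- set_boundaries(field)
  topo <- .fes_topology(field, boundaries)
  m <- length(topo$free)
  Fv <- c(topo$F0, 0)                 # phantom cell last
  n1 <- topo$n_idx[, 1L]; n2 <- topo$n_idx[, 2L]
  n3 <- topo$n_idx[, 3L]; n4 <- topo$n_idx[, 4L]
  b <- topo$bsum; deg <- topo$deg; free <- topo$free
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  iters <- 0L
  converged <- FALSE
  max_sweeps <- ceiling(max_iter / max(m, 1L))
  for (s in seq_len(max_sweeps)) {
    ord <- if (sweep == "random") sample.int(m) else seq_len(m)
    dmax <- 0
    for (k in ord) {
      v <- (Fv[n1[k]] + Fv[n2[k]] + Fv[n3[k]] + Fv[n4[k]] + b[k]) / deg[k]
      d <- abs(v - Fv[free[k]])
      if (d > dmax) dmax <- d
      Fv[free[k]] <- v
    }
    iters <- iters + m
    if (dmax < tol) { converged <- TRUE; break }
  }
  res <- .fes_residual(topo, Fv)
  if (!converged)
    warning(sprintf("relaxation not converged after %d updates (residual %.3g kcal/mol)",
                    iters, res), call. = FALSE)
  Fm <- matrix(Fv[seq_len(topo$grid$nx * topo$grid$ntheta)],
               topo$grid$nx, topo$grid$ntheta)
  structure(list(grid = topo$grid, F = Fm, boundaries = boundaries,
                 dFw2o = boundaries$dFw2o, F0 = 0,
                 residual = res, iterations = iters, converged = converged,
                 method = "relax", field = field, call = match.call()),
            class = "fes")
}

#' Direct sparse solution of the surface-consistency equations
#'
#' Assembles the linear system whose stationarity conditions are exactly
#' the relaxation update at every free node and solves it with a sparse
#' direct factorisation.  Deterministic; intended as the independent
#' cross-check for [fes()] on small grids.
#'
#' @inheritParams fes
#' @return an object of class `"fes"` (with `method = "direct"`).
#' @export
solve_fes_exact <- function(field, boundaries = NULL) {
  stopifnot(inherits(field, "gradient_field"))
  if (is.null(boundaries)) boundaries <- set_boundaries(field)
  topo <- .fes_topology(field, boundaries)
  g <- topo$grid
  m <- length(topo$free)
  row_of <- integer(g$nx * g$ntheta + 1L)   # grid index -> unknown number
  row_of[topo$free] <- seq_len(m)

  ## independent re-derivation of the work terms from fx/Tz
  dthr <- g$dtheta * pi / 180
  fi <- ((topo$free - 1L) %% g$nx) + 1L
  fj <- ((topo$free - 1L) %/% g$nx) + 1L
  trip_i <- trip_j <- integer(0); trip_x <- numeric(0)
  rhs <- numeric(m)
  Fv0 <- c(topo$F0, 0)
  add <- function(k, gidx, work) {
    ## neighbour predicts F_k = F_nbr + work
    if (row_of[gidx] > 0L) {
      trip_i <<- c(trip_i, k); trip_j <<- c(trip_j, row_of[gidx])
      trip_x <<- c(trip_x, -1)
    } else rhs[k] <<- rhs[k] + Fv0[gidx]
    rhs[k] <<- rhs[k] + work
  }
  for (k in seq_len(m)) {
    i <- fi[k]; j <- fj[k]
    add(k, (j - 1L) * g$nx + (i - 1L),
        -0.5 * (field$fx[i - 1L, j] + field$fx[i, j]) * g$dx)
    add(k, (j - 1L) * g$nx + (i + 1L),
        +0.5 * (field$fx[i, j] + field$fx[i + 1L, j]) * g$dx)
    jm <- j - 1L; jp <- j + 1L
    if (g$theta_periodic) { if (jm < 1L) jm <- g$ntheta; if (jp > g$ntheta) jp <- 1L }
    if (jm >= 1L)
      add(k, (jm - 1L) * g$nx + i,
          -0.5 * (field$Tz[i, jm] + field$Tz[i, j]) * dthr)
    if (jp <= g$ntheta)
      add(k, (jp - 1L) * g$nx + i,
          +0.5 * (field$Tz[i, j] + field$Tz[i, jp]) * dthr)
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(m), trip_i),
                            j = c(seq_len(m), trip_j),
                            x = c(topo$deg, trip_x), dims = c(m, m))
  sol <- as.numeric(Matrix::solve(A, rhs))
  Fv <- c(topo$F0, 0)
  Fv[topo$free] <- sol
  res <- .fes_residual(topo, Fv)
  Fm <- matrix(Fv[seq_len(g$nx * g$ntheta)], g$nx, g$ntheta)
  structure(list(grid = g, F = Fm, boundaries = boundaries,
                 dFw2o = boundaries$dFw2o, F0 = 0,
                 residual = res, iterations = NA_integer_, converged = TRUE,
                 method = "direct", field = field, call = match.call()),
            class = "fes")
}

#' Refine a surface on a finer grid with coarse-fit boundaries
#'
#' All four edges of the fine grid take Dirichlet values from the coarse
#' surface; the interior is then relaxed against the fine gradient
#' field.  At boundary nodes shared with the coarse grid the coarse
#' values are used directly; between those anchors the boundary profile
#' is obtained by trapezoidal integration of the fine field along the
#' edge, with any closure defect spread linearly between anchors
#' (thermodynamic-integration stitching).  This preserves sub-coarse
#' structure of the fine data on the boundary; when an edge shares fewer
#' than two nodes with the coarse grid it falls back to bilinear
#' interpolation of the coarse surface.  The fine surface inherits the
#' coarse gauge, so its values are directly adsorption free energies
#' relative to bulk water.
#'
#' @param coarse a fitted [fes()] whose grid contains the fine domain.
#' @param fine_field a [gradient_field()] on the (non-periodic) fine grid.
#' @param ... passed on to [fes()] (`tol`, `max_iter`, `sweep`, `seed`).
#' @return an object of class `"fes"` on the fine grid.
#' @export
refine_fes <- function(coarse, fine_field, ...) {
  stopifnot(inherits(coarse, "fes"), inherits(fine_field, "gradient_field"))
  fg <- fine_field$grid
  cg <- coarse$grid
  if (fg$theta_periodic)
    stop("the fine grid must be non-periodic in theta", call. = FALSE)
  if (fg$x_min < cg$x_min - 1e-9 || fg$x_max > cg$x_max + 1e-9)
    stop("fine grid extends beyond the coarse x domain", call. = FALSE)
  if (!cg$theta_periodic &&
      (fg$theta_min < cg$theta_min - 1e-9 || fg$theta_max > cg$theta_max + 1e-9))
    stop("fine grid extends beyond the coarse theta domain", call. = FALSE)
  on_coarse_x <- function(x)
    vapply(x, function(v) any(abs(cg$x - v) < 1e-9), logical(1))
  on_coarse_th <- function(th) vapply(th, function(v) {
    if (cg$theta_periodic) {
      P <- cg$theta_max - cg$theta_min
      v <- cg$theta_min + (v - cg$theta_min) %% P
    }
    any(abs(cg$theta - v) < 1e-9)
  }, logical(1))
  edge <- function(coords_x, coords_th, works, shared) {
    ## Dirichlet values along one edge: coarse anchors + TI stitching
    n <- length(shared)
    anchors <- which(shared)
    if (length(anchors) < 2L)
      return(.fes_interp(coarse, coords_x, coords_th))
    cum <- c(0, cumsum(works))
    out <- numeric(n)
    aval <- .fes_interp(coarse, coords_x[anchors], coords_th[anchors])
    ## extend by pure integration outside the outermost anchors
    a1 <- anchors[1L]; aL <- anchors[length(anchors)]
    if (a1 > 1L) out[1:a1] <- aval[1L] + cum[1:a1] - cum[a1]
    if (aL < n) out[aL:n] <- aval[length(aval)] + cum[aL:n] - cum[aL]
    for (s in seq_len(length(anchors) - 1L)) {
      i0 <- anchors[s]; i1 <- anchors[s + 1L]
      base <- aval[s] + cum[i0:i1] - cum[i0]
      defect <- aval[s + 1L] - base[length(base)]
      out[i0:i1] <- base + defect * (0:(i1 - i0)) / (i1 - i0)
    }
    out
  }
  works_x <- function(j) vapply(seq_len(fg$nx - 1L), function(i)
    .work_x(fine_field, i, j), numeric(1))
  works_t <- function(i) vapply(seq_len(fg$ntheta - 1L), function(j)
    .work_t(fine_field, i, j, j + 1L), numeric(1))
  sx <- on_coarse_x(fg$x)
  sth <- on_coarse_th(fg$theta)
  bnd <- structure(list(
    left = edge(rep(fg$x_min, fg$ntheta), fg$theta, works_t(1L),
                if (on_coarse_x(fg$x_min)) sth else rep(FALSE, fg$ntheta)),
    right = edge(rep(fg$x_max, fg$ntheta), fg$theta, works_t(fg$nx),
                 if (on_coarse_x(fg$x_max)) sth else rep(FALSE, fg$ntheta)),
    bottom = edge(fg$x, rep(fg$theta_min, fg$nx), works_x(1L),
                  if (on_coarse_th(fg$theta_min)) sx else rep(FALSE, fg$nx)),
    top = edge(fg$x, rep(fg$theta[fg$ntheta], fg$nx), works_x(fg$ntheta),
               if (on_coarse_th(fg$theta[fg$ntheta])) sx else rep(FALSE, fg$nx)),
    dFw2o = coarse$dFw2o, row_integrals = NULL), class = "fes_boundary")
  out <- fes(fine_field, boundaries = bnd, ...)
  out$dFw2o <- coarse$dFw2o
  out$F0 <- coarse$F0
  out
}

## bilinear interpolation of a fitted surface, wrap-aware in theta
.fes_interp <- function(surface, x, theta) {
  g <- surface$grid
  Fm <- surface$F
  xs <- g$x
  if (g$theta_periodic) {
    ths <- c(g$theta, g$theta_max)
    Fm <- cbind(Fm, Fm[, 1L])
    period <- g$theta_max - g$theta_min
    theta <- g$theta_min + (theta - g$theta_min) %% period
  } else ths <- g$theta
  n <- max(length(x), length(theta))
  x <- rep_len(x, n); theta <- rep_len(theta, n)
  out <- numeric(n)
  for (q in seq_len(n)) {
    if (x[q] < xs[1] - 1e-9 || x[q] > xs[length(xs)] + 1e-9 ||
        theta[q] < ths[1] - 1e-9 || theta[q] > ths[length(ths)] + 1e-9)
      stop("interpolation point outside the surface domain", call. = FALSE)
    i <- min(max(findInterval(x[q], xs), 1L), length(xs) - 1L)
    j <- min(max(findInterval(theta[q], ths), 1L), length(ths) - 1L)
    tx <- (x[q] - xs[i]) / (xs[i + 1L] - xs[i])
    tt <- (theta[q] - ths[j]) / (ths[j + 1L] - ths[j])
    out[q] <- (1 - tx) * (1 - tt) * Fm[i, j] + tx * (1 - tt) * Fm[i + 1L, j] +
      (1 - tx) * tt * Fm[i, j + 1L] + tx * tt * Fm[i + 1L, j + 1L]
  }
  out
}

#' Closed-loop torque integration diagnostic
#'
#' Cumulative trapezoidal integral of `-Tz` around one full theta period
#' at fixed x.  For a curl-free (thermodynamically consistent) field the
#' profile closes on itself; the absolute closure defect is returned as a
#' consistency diagnostic and should be at noise level.
#'
#' @param field a [gradient_field()] on a theta-periodic grid.
#' @param x_index x row index (1-based).
#' @return list with `theta` (node angles plus the wrapped endpoint),
#'   `profile` (F values along the loop, starting at 0) and `residual`
#'   (absolute closure defect, kcal/mol).
#' @export
torque_integrate_check <- function(field, x_index) {
  g <- field$grid
  if (!g$theta_periodic)
    stop("torque closure requires a theta-periodic grid", call. = FALSE)
  stopifnot(x_index >= 1, x_index <= g$nx)
  jseq <- c(seq_len(g$ntheta), 1L)
  segs <- vapply(seq_len(g$ntheta), function(q)
    .work_t(field, x_index, jseq[q], jseq[q + 1L]), numeric(1))
  prof <- c(0, cumsum(segs))
  list(theta = c(g$theta, g$theta_max), profile = prof,
       residual = abs(prof[length(prof)] - prof[1L]))
}
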