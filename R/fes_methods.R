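#' @export
print.fes <- function(x, ...) {
  cat(sprintf("Free-energy surface (%s): %d x %d nodes, x in [%g, %g] A\n",
              x$method, x$grid$nx, x$grid$ntheta, x$grid$x_min, x$grid$x_max))
  if (!is.null(x$dFw2o))
    cat(sprintf("  water->oil transfer free energy: %.4g kcal/mol\n", x$dFw2o))
  cat(sprintf("  F range [%.4g, %.4g] kcal/mol; stationarity residual %.3g\n",
              min(x$F), max(x$F), x$residual))
  if (!x$converged) cat("  WARNING: relaxation did not converge\n")
  invisible(x)
}

#' Summarise a fitted free-energy surface
#'
#' Reports the transfer free energy, the adsorption states (local minima
#' of the adsorption free energy) and the solver diagnostics.
#'
#' @param object a fitted [fes()].
#' @param neighborhood connectivity for minima detection (4 or 8).
#' @param ... unused.
#' @return an object of class `"summary.fes"`.
#' @export
summary.fes <- function(object, neighborhood = 4, ...) {
  states <- find_local_minima(object, neighborhood = neighborhood)
  structure(list(grid = object$grid, dFw2o = object$dFw2o,
                 states = states, residual = object$residual,
                 iterations = object$iterations,
                 converged = object$converged, method = object$method),
            class = "summary.fes")
}

#' @export
print.summary.fes <- function(x, ...) {
  cat(sprintf("Free-energy surface fit (%s), %d x %d nodes\n",
              x$method, x$grid$nx, x$grid$ntheta))
  if (!is.null(x$dFw2o))
    cat(sprintf("  dF(water->oil) = %.4g kcal/mol\n", x$dFw2o))
  cat(sprintf("  stationarity residual %.3g kcal/mol; converged: %s\n",
              x$residual, x$converged))
  cat("Adsorption states (local minima of dF):\n")
  print(x$states)
  invisible(x)
}

#' Predict surface values at off-node configurations
#'
#' Bilinear interpolation of the fitted surface, wrap-aware in theta on
#' periodic grids.
#'
#' @param object a fitted [fes()].
#' @param newdata data.frame with columns `x` (Angstrom) and `theta`
#'   (degrees).
#' @param ... unused.
#' @return numeric vector of F values in kcal/mol.
#' @export
predict.fes <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata), all(c("x", "theta") %in% names(newdata)))
  .fes_interp(object, newdata$x, newdata$theta)
}

#' Gradient-consistency residuals of a fitted surface
#'
#' Per-edge defects between the discrete difference of the fitted F and
#' the trapezoidal work implied by the input field: `dx` edges give
#' `F[i+1,j] - F[i,j] + mean(fx)*dx`, `dtheta` edges the analogue with
#' the torque.  Zero everywhere for curl-free input.
#'
#' @param object a fitted [fes()].
#' @param ... unused.
#' @return list with matrices `x_edges` ((nx-1) x ntheta) and
#'   `theta_edges` (nx x ntheta or nx x (ntheta-1)), kcal/mol.
#' @export
residuals.fes <- function(object, ...) {
  field <- object$field
  g <- object$grid
  Fm <- object$F
  rx <- matrix(0, g$nx - 1L, g$ntheta)
  for (i in seq_len(g$nx - 1L))
    rx[i, ] <- Fm[i + 1L, ] - Fm[i, ] -
      vapply(seq_len(g$ntheta), function(j) .work_x(field, i, j), numeric(1))
  nseg <- if (g$theta_periodic) g$ntheta else g$ntheta - 1L
  rt <- matrix(0, g$nx, nseg)
  for (j in seq_len(nseg)) {
    jp <- if (j == g$ntheta) 1L else j + 1L
    rt[, j] <- Fm[, jp] - Fm[, j] -
      vapply(seq_len(g$nx), function(i) .work_t(field, i, j, jp), numeric(1))
  }
  list(x_edges = rx, theta_edges = rt)
}

#' @export
coef.fes <- function(object, ...) {
  c(dFw2o = if (is.null(object$dFw2o)) NA_real_ else object$dFw2o)
}

#' Plot a fitted free-energy surface
#'
#' Filled-contour map of the adsorption free energy over (x, theta).
#'
#' @param x a fitted [fes()].
#' @param main plot title.
#' @param ... passed to [graphics::filled.contour()].
#' @export
plot.fes <- function(x, main = "Adsorption free energy (kcal/mol)", ...) {
  graphics::filled.contour(x$grid$x, x$grid$theta, x$F - x$F0,
                           xlab = "x [A]", ylab = "theta [deg]",
                           main = main, ...)
}

#' Write / read a fitted surface as TSV
#'
#' Columns `x`, `theta`, `F`; numeric values are written at full double
#' precision, so files round-trip losslessly.
#' @param surface a fitted [fes()].
#' @param path file path.
#' @return `path` invisibly (write); an `"fes"` object (read, with no
#'   attached field or solver diagnostics).
#' @export
write_fes <- function(surface, path) {
  g <- surface$grid
  df <- data.frame(x = rep(g$x, times = g$ntheta),
                   theta = rep(g$theta, each = g$nx),
                   F = as.vector(surface$F))
  .write_tsv(df, path)
  invisible(path)
}

#' @rdname write_fes
#' @param theta_periodic grid periodicity flag for the reader.
#' @param dFw2o optional transfer free energy to attach on read.
#' @export
read_fes <- function(path, theta_periodic = FALSE, dFw2o = NULL) {
  dat <- utils::read.table(path, header = TRUE, comment.char = "#")
  if (!all(c("x", "theta", "F") %in% names(dat)))
    stop("surface file must have columns x, theta, F", call. = FALSE)
  xs <- sort(unique(dat$x)); ths <- sort(unique(dat$theta))
  dxs <- diff(xs); dth <- diff(ths)
  theta_max <- if (theta_periodic) max(ths) + dth[1] else max(ths)
  grid <- grid_spec(min(xs), max(xs), dxs[1], min(ths), theta_max, dth[1],
                    theta_periodic)
  o <- order(match(dat$theta, ths), match(dat$x, xs))
  Fm <- matrix(dat$F[o], length(xs), length(ths))
  structure(list(grid = grid, F = Fm, boundaries = NULL, dFw2o = dFw2o,
                 F0 = 0, residual = NA_real_, iterations = NA_integer_,
                 converged = NA, method = "file", field = NULL),
            class = "fes")
}
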