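#' Gridded mean-force / mean-torque field
#'
#' Holds the time-averaged force component `<fx>` (kcal/mol/A) and torque
#' component `<Tz>` (kcal/mol/rad) exerted on the restrained crystal at
#' every grid node, with optional standard errors.  Sign convention:
#' fx = -dF/dx and Tz = -dF/dtheta, i.e. the field is minus the gradient
#' of the free energy F(x, theta).
#'
#' @param grid a [grid_spec()].
#' @param fx,Tz numeric matrices of dimension `nx` x `ntheta` (x indexes
#'   rows), in kcal/mol/A and kcal/mol/rad.
#' @param fx_sem,Tz_sem optional matching matrices of standard errors.
#' @return an object of class `"gradient_field"`.
#' @export
gradient_field <- function(grid, fx, Tz, fx_sem = NULL, Tz_sem = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  chk <- function(m, nm, required = TRUE) {
    if (is.null(m)) { if (required) stop(nm, " is required", call. = FALSE); return(NULL) }
    m <- as.matrix(m)
    if (!all(dim(m) == c(grid$nx, grid$ntheta)))
      stop(nm, " must be a ", grid$nx, " x ", grid$ntheta, " matrix", call. = FALSE)
    if (!all(is.finite(m))) stop("non-finite values in ", nm, call. = FALSE)
    m
  }
  structure(list(grid = grid, fx = chk(fx, "fx"), Tz = chk(Tz, "Tz"),
                 fx_sem = chk(fx_sem, "fx_sem", FALSE),
                 Tz_sem = chk(Tz_sem, "Tz_sem", FALSE)),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("Gradient field on %d x %d grid; <fx> in [%.4g, %.4g] kcal/mol/A, <Tz> in [%.4g, %.4g] kcal/mol/rad\n",
              x$grid$nx, x$grid$ntheta, min(x$fx), max(x$fx), min(x$Tz), max(x$Tz)))
  invisible(x)
}

#' Read a pre-averaged gradient field from TSV
#'
#' Expects columns `x`, `theta`, `fx`, `Tz` and optionally `fx_sem`,
#' `Tz_sem`, one row per grid node, in internal units.  The grid is
#' inferred from the unique sorted node coordinates, which must form a
#' complete regular grid.
#'
#' @param path TSV file path.
#' @param theta_periodic passed to [grid_spec()]; default `FALSE`.
#' @return a [gradient_field()].
#' @export
read_gradient_field <- function(path, theta_periodic = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- utils::read.table(path, header = TRUE, comment.char = "#")
  need <- c("x", "theta", "fx", "Tz")
  if (!all(need %in% names(dat)))
    stop("field file must have columns x, theta, fx, Tz", call. = FALSE)
  xs <- sort(unique(dat$x)); ths <- sort(unique(dat$theta))
  if (nrow(dat) != length(xs) * length(ths))
    stop("incomplete grid in ", path, call. = FALSE)
  dxs <- diff(xs); dth <- diff(ths)
  if (length(xs) < 2 || length(ths) < 1)
    stop("degenerate grid in ", path, call. = FALSE)
  if (max(abs(dxs - dxs[1])) > 1e-9 || (length(dth) && max(abs(dth - dth[1])) > 1e-9))
    stop("irregular grid spacings in ", path, call. = FALSE)
  theta_max <- if (theta_periodic) max(ths) + dth[1] else max(ths)
  grid <- grid_spec(min(xs), max(xs), dxs[1], min(ths), theta_max,
                    if (length(dth)) dth[1] else 1, theta_periodic)
  o <- order(match(dat$theta, ths), match(dat$x, xs))
  shape <- function(v) matrix(v[o], nrow = length(xs), ncol = length(ths))
  gradient_field(grid, shape(dat$fx), shape(dat$Tz),
                 if ("fx_sem" %in% names(dat)) shape(dat$fx_sem),
                 if ("Tz_sem" %in% names(dat)) shape(dat$Tz_sem))
}

#' Write a gradient field to TSV
#' @param field a [gradient_field()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gradient_field <- function(field, path) {
  g <- field$grid
  df <- data.frame(x = rep(g$x, times = g$ntheta),
                   theta = rep(g$theta, each = g$nx),
                   fx = as.vector(field$fx), Tz = as.vector(field$Tz))
  if (!is.null(field$fx_sem)) df$fx_sem <- as.vector(field$fx_sem)
  if (!is.null(field$Tz_sem)) df$Tz_sem <- as.vector(field$Tz_sem)
  .write_tsv(df, path)
  invisible(path)
}

## deterministic TSV writer shared by all outputs
.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Assemble a gradient field from per-node time-series files
#'
#' Reads a manifest mapping grid nodes to sampling files, trims the
#' equilibration transient of each series, block-averages the force and
#' torque channels and converts them to internal units.
#'
#' @param manifest path to a headered TSV with columns `x`, `theta`,
#'   `path` (series files, relative paths resolved against the manifest
#'   directory).
#' @param grid a [grid_spec()]; every node must appear exactly once.
#' @param equilibration_ps equilibration cutoff in ps (default 1000, i.e.
#'   1 ns).
#' @param block_size block size for the standard error (default 100).
#' @param dialect,units passed to [read_timeseries()]; use `units` to
#'   declare SI inputs (`c(fx = "N", Tz = "N*m")`), which are converted
#'   to kcal/mol/A and kcal/mol/rad on entry.
#' @return a [gradient_field()] with per-node standard errors.
#' @export
assemble_gradient_field <- function(manifest, grid, equilibration_ps = 1000,
                                    block_size = 100L, dialect = list(),
                                    units = NULL) {
  if (!file.exists(manifest)) stop("file not found: ", manifest, call. = FALSE)
  man <- utils::read.table(manifest, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("x", "theta", "path") %in% names(man)))
    stop("manifest must have columns x, theta, path", call. = FALSE)
  base <- dirname(manifest)
  fx <- Tz <- fx_sem <- Tz_sem <- matrix(NA_real_, grid$nx, grid$ntheta)
  for (r in seq_len(nrow(man))) {
    i <- match(TRUE, abs(grid$x - man$x[r]) < 1e-9)
    j <- match(TRUE, abs(grid$theta - man$theta[r]) < 1e-9)
    if (is.na(i) || is.na(j))
      stop("manifest node (", man$x[r], ", ", man$theta[r],
           ") not on the grid", call. = FALSE)
    p <- man$path[r]
    if (!file.exists(p)) p <- file.path(base, man$path[r])
    ts <- read_timeseries(p, dialect = dialect, units = units)
    ts <- trim_equilibration(ts, equilibration_ps)
    ef <- mean_and_sem(ts, "fx", block_size)
    et <- mean_and_sem(ts, "Tz", block_size)
    fx[i, j] <- convert_units(ef$mean, ef$unit, "kcal/mol/A")
    Tz[i, j] <- convert_units(et$mean, et$unit, "kcal/mol/rad")
    fx_sem[i, j] <- convert_units(ef$sem, ef$unit, "kcal/mol/A")
    Tz_sem[i, j] <- convert_units(et$sem, et$unit, "kcal/mol/rad")
  }
  if (any(is.na(fx)))
    stop("manifest does not cover every grid node", call. = FALSE)
  gradient_field(grid, fx, Tz,
                 if (all(is.finite(fx_sem))) fx_sem,
                 if (all(is.finite(Tz_sem))) Tz_sem)
}
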