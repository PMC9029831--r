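#' Define a regular (x, theta) configuration grid
#'
#' The configuration space of the restrained crystal is the distance x
#' from the water-oil interface (Angstrom) and the rotation angle theta
#' around the crystal axis (degrees).  The crystal cross-section is
#' twofold symmetric, so theta has period 180 degrees; a periodic grid
#' covers exactly one period and omits the duplicate endpoint.
#'
#' @param x_min,x_max x range in Angstrom.
#' @param dx x spacing in Angstrom; must divide the range.
#' @param theta_min,theta_max theta range in degrees.
#' @param dtheta theta spacing in degrees; must divide the range.
#' @param theta_periodic logical; when `TRUE` the grid wraps in theta with
#'   period `theta_max - theta_min` (which must be 180) and the node at
#'   `theta_max` is excluded.
#' @return an object of class `"grid_spec"` with node vectors `x`,
#'   `theta` and counts `nx`, `ntheta`.
#' @examples
#' coarse_grid()   # 13 x 12 nodes
#' fine_grid()     # 16 x 16 nodes
#' @export
grid_spec <- function(x_min, x_max, dx, theta_min, theta_max, dtheta,
                      theta_periodic = FALSE) {
  .divisible <- function(range, step)
    abs(range / step - round(range / step)) < 1e-9
  if (x_max <= x_min || dx <= 0) stop("invalid x range/spacing", call. = FALSE)
  if (!.divisible(x_max - x_min, dx))
    stop("(x_max - x_min) not divisible by dx", call. = FALSE)
  if (theta_max <= theta_min || dtheta <= 0)
    stop("invalid theta range/spacing", call. = FALSE)
  if (!.divisible(theta_max - theta_min, dtheta))
    stop("(theta_max - theta_min) not divisible by dtheta", call. = FALSE)
  if (theta_periodic && abs((theta_max - theta_min) - 180) > 1e-9)
    stop("a periodic theta grid must cover exactly one 180-degree period",
         call. = FALSE)
  nx <- as.integer(round((x_max - x_min) / dx)) + 1L
  ntheta <- as.integer(round((theta_max - theta_min) / dtheta)) +
    (if (theta_periodic) 0L else 1L)
  structure(list(
    x_min = x_min, x_max = x_max, dx = dx,
    theta_min = theta_min, theta_max = theta_max, dtheta = dtheta,
    theta_periodic = theta_periodic,
    x = x_min + dx * (seq_len(nx) - 1L),
    theta = theta_min + dtheta * (seq_len(ntheta) - 1L),
    nx = nx, ntheta = ntheta), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "Grid: %d x %d nodes; x in [%g, %g] A (dx %g), theta in [%g, %g) deg (dtheta %g)%s\n",
    x$nx, x$ntheta, x$x_min, x$x_max, x$dx, x$theta_min, x$theta_max,
    x$dtheta, if (x$theta_periodic) ", periodic" else ""))
  invisible(x)
}

#' Default coarse sampling grid
#'
#' Covers the full approach of the crystal to the interface:
#' -30 <= x <= +30 A with dx = 5 A and 0 <= theta < 180 deg with
#' dtheta = 15 deg (periodic), i.e. 13 x 12 nodes.
#' @return a [grid_spec()].
#' @export
coarse_grid <- function()
  grid_spec(-30, 30, 5, 0, 180, 15, theta_periodic = TRUE)

#' Default fine refinement grid
#'
#' Zooms on the adsorption region: -25 <= x <= -10 A with dx = 1 A and
#' 75 <= theta <= 150 deg with dtheta = 5 deg (non-periodic), i.e.
#' 16 x 16 nodes.  All four edges take Dirichlet values from a coarse fit.
#' @return a [grid_spec()].
#' @export
fine_grid <- function()
  grid_spec(-25, -10, 1, 75, 150, 5, theta_periodic = FALSE)
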