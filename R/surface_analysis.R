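#' Adsorption free energy relative to the bulk-water plane
#'
#' dF(x, theta) = F(x, theta) - F(x_min), with the x_min row required to
#' be constant (theta-independent, as it must be far from the interface).
#'
#' @param surface a fitted [fes()] whose grid includes the bulk-water
#'   reference plane at x_min.
#' @return matrix of dF values (kcal/mol), same shape as `surface$F`.
#' @export
adsorption_free_energy <- function(surface) {
  stopifnot(inherits(surface, "fes"))
  ref_row <- surface$F[1L, ]
  if (max(ref_row) - min(ref_row) > 1e-9)
    stop("reference row F(x_min, theta) is not constant: ",
         "surface was not referenced to bulk water", call. = FALSE)
  surface$F - ref_row[1L]
}

#' Locate adsorption states (strict local minima) of a surface
#'
#' A node is a minimum iff it is strictly lower than every neighbour in
#' the chosen connectivity (nodes tied with a neighbour are excluded, so
#' flat plateaus are never reported).  Theta neighbours wrap on periodic
#' grids.  Boundary nodes are compared against their existing neighbours.
#'
#' @param surface a fitted [fes()].
#' @param neighborhood 4 (axial neighbours, default) or 8 (adds
#'   diagonals).
#' @param region optional list with `x = c(min, max)` and/or
#'   `theta = c(min, max)` restricting where minima are reported.
#' @return a data.frame of class `"adsorption_states"` with columns
#'   `label` ("A", "B", ... from the deepest), `x`, `theta`, `dF`
#'   (kcal/mol relative to the bulk-water reference), sorted ascending in
#'   `dF`.
#' @export
find_local_minima <- function(surface, neighborhood = 4, region = NULL) {
  stopifnot(inherits(surface, "fes"), neighborhood %in% c(4, 8))
  g <- surface$grid
  Fm <- surface$F
  nbrs <- .grid_neighbors(g, neighborhood)
  is_min <- vapply(seq_len(g$nx * g$ntheta), function(q)
    all(Fm[q] < Fm[nbrs[[q]]]), logical(1))
  qi <- ((which(is_min) - 1L) %% g$nx) + 1L
  qj <- ((which(is_min) - 1L) %/% g$nx) + 1L
  df <- data.frame(x = g$x[qi], theta = g$theta[qj],
                   dF = Fm[cbind(qi, qj)] - surface$F0)
  if (!is.null(region)) {
    keep <- rep(TRUE, nrow(df))
    if (!is.null(region$x))
      keep <- keep & df$x >= region$x[1] & df$x <= region$x[2]
    if (!is.null(region$theta))
      keep <- keep & df$theta >= region$theta[1] & df$theta <= region$theta[2]
    df <- df[keep, , drop = FALSE]
  }
  df <- df[order(df$dF), , drop = FALSE]
  rownames(df) <- NULL
  df <- cbind(label = make.unique(LETTERS[pmin(seq_len(nrow(df)), 26L)],
                                  sep = ""), df)
  if (nrow(df) == 0L)
    df <- data.frame(label = character(0), x = numeric(0),
                     theta = numeric(0), dF = numeric(0))
  class(df) <- c("adsorption_states", "data.frame")
  df
}

#' @export
print.adsorption_states <- function(x, ...) {
  cat(sprintf("%d adsorption state(s):\n", nrow(x)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

## neighbour linear indices for every node of a grid
.grid_neighbors <- function(g, neighborhood = 4) {
  nx <- g$nx; nt <- g$ntheta
  steps <- if (neighborhood == 4)
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  else
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  lapply(seq_len(nx * nt), function(q) {
    i <- ((q - 1L) %% nx) + 1L
    j <- ((q - 1L) %/% nx) + 1L
    out <- integer(0)
    for (s in steps) {
      ii <- i + s[1L]; jj <- j + s[2L]
      if (ii < 1L || ii > nx) next
      if (g$theta_periodic) {
        if (jj < 1L) jj <- nt else if (jj > nt) jj <- 1L
      } else if (jj < 1L || jj > nt) next
      out <- c(out, (jj - 1L) * nx + ii)
    }
    out
  })
}

#' Minimax barrier between two adsorption states
#'
#' The saddle value is the minimax over all grid paths from `a` to `b`
#' (8-connected by default) of the path's maximum F: the lowest crossing
#' of any connecting ridge, computed exactly by a widest-path variant of
#' Dijkstra's algorithm.  Barrier heights are reported from both wells.
#'
#' @param surface a fitted [fes()].
#' @param a,b states: either rows of [find_local_minima()] output or
#'   length-2 vectors `c(x, theta)` naming grid nodes.
#' @param neighborhood path connectivity, 8 (default) or 4.
#' @return an object of class `"barrier"`: `saddle_dF` (kcal/mol,
#'   relative to bulk water), `barrier_from_a`, `barrier_from_b` (both
#'   >= 0), and the endpoint states.
#' @export
barrier_height <- function(surface, a, b, neighborhood = 8) {
  stopifnot(inherits(surface, "fes"))
  g <- surface$grid
  node_of <- function(s) {
    if (is.data.frame(s)) s <- c(s$x[1], s$theta[1])
    i <- match(TRUE, abs(g$x - s[1]) < 1e-9)
    j <- match(TRUE, abs(g$theta - s[2]) < 1e-9)
    if (is.na(i) || is.na(j))
      stop("state (", s[1], ", ", s[2], ") is not a grid node", call. = FALSE)
    (j - 1L) * g$nx + i
  }
  qa <- node_of(a); qb <- node_of(b)
  if (qa == qb) stop("degenerate pair: a and b are the same node", call. = FALSE)
  Fv <- as.vector(surface$F)
  nbrs <- .grid_neighbors(g, neighborhood)
  n <- length(Fv)
  dist <- rep(Inf, n)
  done <- rep(FALSE, n)
  dist[qa] <- Fv[qa]
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) stop("states are not connected", call. = FALSE)
    if (u == qb) break
    done[u] <- TRUE
    for (v in nbrs[[u]]) {
      nd <- max(dist[u], Fv[v])
      if (nd < dist[v]) dist[v] <- nd
    }
  }
  saddle <- dist[qb]
  structure(list(saddle_dF = saddle - surface$F0,
                 barrier_from_a = saddle - Fv[qa],
                 barrier_from_b = saddle - Fv[qb],
                 a = a, b = b, neighborhood = neighborhood),
            class = "barrier")
}

#' @export
print.barrier <- function(x, ...) {
  cat(sprintf("Saddle dF = %.4g kcal/mol; barrier from a: %.4g, from b: %.4g (%d-connected paths)\n",
              x$saddle_dF, x$barrier_from_a, x$barrier_from_b, x$neighborhood))
  invisible(x)
}

#' Water-to-oil transfer free energy of a fitted surface
#'
#' The free-energy difference between the crystal immersed in bulk water
#' and in bulk oil: the end-to-end x offset fixed by [set_boundaries()]
#' during the fit.
#'
#' @param surface a fitted [fes()].
#' @return scalar, kcal/mol.
#' @export
transfer_free_energy <- function(surface) {
  stopifnot(inherits(surface, "fes"))
  if (is.null(surface$dFw2o))
    stop("surface carries no transfer free energy (boundaries not set by set_boundaries)",
         call. = FALSE)
  surface$dFw2o
}
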