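# shared in-code fixtures

# trajectory from bare oxygen paths: ox/oy/oz are nframes x nmol matrices;
# hydrogens at a fixed rigid orientation unless angles are supplied
toy_trajectory <- function(ox, oy, oz, box = c(60, 40, 40), dt = 1) {
  nf <- nrow(ox); nm <- ncol(ox)
  coords <- array(NA_real_, c(nf, 3L * nm, 3L))
  oi <- 3L * (seq_len(nm) - 1L) + 1L
  r_oh <- 0.9572; beta <- 104.52 / 2 * pi / 180
  d <- c(0, 1, 0); e <- c(1, 0, 0)
  h1 <- r_oh * (cos(beta) * d + sin(beta) * e)
  h2 <- r_oh * (cos(beta) * d - sin(beta) * e)
  for (f in seq_len(nf)) {
    O <- cbind(ox[f, ], oy[f, ], oz[f, ])
    coords[f, oi, ] <- O
    coords[f, oi + 1L, ] <- O + rep(h1, each = nm)
    coords[f, oi + 2L, ] <- O + rep(h2, each = nm)
  }
  trajectory(dt * (seq_len(nf) - 1L), box, coords)
}

# random 3D rotation matrix
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-6) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# gradient field with constant fx and zero torque on a given grid
const_field <- function(grid, fx_val = 0, Tz_val = 0) {
  gradient_field(grid,
                 matrix(fx_val, grid$nx, grid$ntheta),
                 matrix(Tz_val, grid$nx, grid$ntheta))
}

# minimax saddle by exhaustive simple-path enumeration (oracle)
brute_minimax <- function(Fm, grid, a, b, neighborhood = 8) {
  nbrs <- pmfsurf:::.grid_neighbors(grid, neighborhood)
  Fv <- as.vector(Fm)
  best <- Inf
  visit <- function(u, pathmax, seen) {
    pathmax <- max(pathmax, Fv[u])
    if (pathmax >= best) return()
    if (u == b) { best <<- pathmax; return() }
    for (v in nbrs[[u]]) if (!seen[v]) {
      seen[v] <- TRUE
      visit(v, pathmax, seen)
      seen[v] <- FALSE
    }
  }
  seen <- rep(FALSE, length(Fv)); seen[a] <- TRUE
  visit(a, -Inf, seen)
  best
}
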