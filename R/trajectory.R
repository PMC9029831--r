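#' Water trajectory container
#'
#' Frames of atomic coordinates in an orthorhombic periodic box, with a
#' fixed O,H,H atom triplet per water molecule in a stable order.
#'
#' @param times numeric vector of frame times (ps), strictly increasing.
#' @param box length-3 numeric, box edge lengths (Angstrom).
#' @param coords numeric array `c(nframes, natoms, 3)`; atoms ordered
#'   O,H,H per molecule.
#' @return an object of class `"trajectory"` with `n_molecules = natoms/3`.
#' @export
trajectory <- function(times, box, coords) {
  times <- as.numeric(times)
  box <- as.numeric(box)
  stopifnot(length(box) == 3, all(box > 0), length(dim(coords)) == 3,
            dim(coords)[3] == 3, dim(coords)[1] == length(times))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  if (dim(coords)[2] %% 3 != 0)
    stop("atom count must be a multiple of 3 (O,H,H per molecule)", call. = FALSE)
  structure(list(times = times, box = box, coords = coords,
                 n_frames = length(times),
                 n_molecules = dim(coords)[2] %/% 3L),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames (%g..%g ps), %d water molecules, box %g x %g x %g A\n",
              x$n_frames, min(x$times), max(x$times), x$n_molecules,
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

## atom indices of molecule set
.o_idx <- function(ids) 3L * (ids - 1L) + 1L

#' Read an extended-XYZ trajectory
#'
#' Parses the common extended-XYZ dialect: per frame an atom count, a
#' comment line carrying `Lattice="ax 0 0 0 by 0 0 0 cz"` (orthorhombic
#' only) and optionally `Time=<ps>`, then `species x y z` atom lines in
#' O,H,H molecule order.
#'
#' @param path file path.
#' @param dt frame spacing in ps, used when no `Time=` fields are present
#'   (default 1).
#' @return a [trajectory()].
#' @export
read_xyz <- function(path, dt = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop("empty input: ", path, call. = FALSE)
  nat <- suppressWarnings(as.integer(lines[1L]))
  if (is.na(nat) || nat <= 0) stop("bad atom count header", call. = FALSE)
  stride <- nat + 2L
  nf <- length(lines) %/% stride
  if (nf == 0L) stop("truncated XYZ file", call. = FALSE)
  starts <- (seq_len(nf) - 1L) * stride + 1L
  comments <- lines[starts + 1L]
  lat <- regmatches(comments[1L],
                    regexpr('Lattice="[^"]*"', comments[1L]))
  if (!length(lat)) stop("no Lattice field in XYZ comment line", call. = FALSE)
  lv <- scan(text = gsub('Lattice="|"', "", lat), quiet = TRUE)
  if (length(lv) != 9) stop("Lattice must have 9 components", call. = FALSE)
  if (any(abs(lv[-c(1, 5, 9)]) > 1e-9))
    stop("only orthorhombic boxes are supported", call. = FALSE)
  box <- lv[c(1, 5, 9)]
  tm <- regmatches(comments, regexpr("Time=[-0-9.eE+]+", comments))
  times <- if (length(tm) == nf)
    as.numeric(sub("Time=", "", tm)) else (seq_len(nf) - 1L) * dt
  atom_rows <- as.vector(outer(seq_len(nat) + 1L, starts, `+`))
  fields <- utils::read.table(text = lines[atom_rows],
                              colClasses = c("character", rep("numeric", 3)))
  coords <- array(NA_real_, c(nf, nat, 3))
  for (ax in 1:3)
    coords[, , ax] <- t(matrix(fields[[ax + 1L]], nrow = nat))
  trajectory(times, box, coords)
}

#' Write an extended-XYZ trajectory
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  nat <- dim(traj$coords)[2]
  species <- rep(c("O", "H", "H"), traj$n_molecules)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    writeLines(as.character(nat), con)
    writeLines(sprintf(
      'Lattice="%.6f 0 0 0 %.6f 0 0 0 %.6f" Properties=species:S:1:pos:R:3 Time=%.6f',
      traj$box[1], traj$box[2], traj$box[3], traj$times[f]), con)
    writeLines(sprintf("%s %.8f %.8f %.8f", species,
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
  }
  invisible(path)
}

#' Unwrap periodic-boundary jumps into continuous coordinates
#'
#' Shifts each atom's coordinates by integer box multiples so that
#' consecutive-frame displacements are minimal (first frame unchanged).
#' Required before computing displacements across the periodic y and z
#' boundaries.  A per-frame jump of half a box length or more is
#' ambiguous and raises an error naming the frame and atom.
#'
#' @param traj a [trajectory()].
#' @param axes axes to unwrap (default all three).
#' @return a [trajectory()] with continuous coordinates.
#' @export
unwrap_pbc <- function(traj, axes = 1:3) {
  coords <- traj$coords
  nf <- traj$n_frames
  if (nf < 2L) return(traj)
  for (ax in axes) {
    L <- traj$box[ax]
    d <- coords[-1L, , ax, drop = FALSE] - coords[-nf, , ax, drop = FALSE]
    d <- array(d, dim(d)[1:2])
    k <- round(d / L)
    wrapped <- d - L * k
    bad <- abs(wrapped) >= L / 2 - 1e-9
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf("ambiguous jump (>= half box) on axis %d at frame %d, atom %d",
                   ax, w[1L] + 1L, w[2L]), call. = FALSE)
    }
    shift <- apply(k, 2L, cumsum)
    if (is.null(dim(shift))) shift <- matrix(shift, nrow = 1L)
    coords[-1L, , ax] <- coords[-1L, , ax] - L * shift
  }
  trajectory(traj$times, traj$box, coords)
}
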