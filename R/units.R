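#' @title Unit handling
#' @description Internal unit system: energies in kcal/mol, lengths in
#'   Angstrom, angles in radians (for torque work terms), times in
#'   picoseconds.  SI values (N, N m, m^2/s) are accepted at I/O
#'   boundaries only and converted on entry.
#' @name units
#' @keywords internal
NULL

## 1 kcal/mol per molecular entity, in joules (4184 / N_A)
.KCALMOL_J <- 6.947695e-21

## unit registry: each tag has a dimension and a factor to the internal
## base unit of that dimension
.UNIT_TABLE <- list(
  "N"            = list(dim = "force",       to_base = 1e-10 / .KCALMOL_J),
  "kcal/mol/A"   = list(dim = "force",       to_base = 1),
  "N*m"          = list(dim = "torque",      to_base = 1 / .KCALMOL_J),
  "kcal/mol/rad" = list(dim = "torque",      to_base = 1),
  "J"            = list(dim = "energy",      to_base = 1 / .KCALMOL_J),
  "kcal/mol"     = list(dim = "energy",      to_base = 1),
  "m^2/s"        = list(dim = "diffusion",   to_base = 1e8),
  "A^2/ps"       = list(dim = "diffusion",   to_base = 1),
  "K"            = list(dim = "temperature", to_base = 1)
)

.supported_units <- function() names(.UNIT_TABLE)

.unit_info <- function(tag) {
  info <- .UNIT_TABLE[[tag]]
  if (is.null(info))
    stop("unsupported unit tag '", tag, "'; supported: ",
         paste(.supported_units(), collapse = ", "), call. = FALSE)
  info
}

#' Convert a value between supported unit tags
#'
#' Exact multiplicative conversion between dimensionally compatible unit
#' tags.  The energy bridge is 1 kcal/mol = 6.947695e-21 J per entity, so
#' e.g. a force of -0.2068e-9 N converts to about -2.976 kcal/mol/A and a
#' torque of 0.3921e-18 N m to about 56.44 kcal/mol/rad.
#'
#' @param value numeric vector to convert.
#' @param from,to unit tags; see `.supported_units()` in the sources.
#'   Supported tags: `"N"`, `"kcal/mol/A"` (force); `"N*m"`,
#'   `"kcal/mol/rad"` (torque); `"J"`, `"kcal/mol"` (energy); `"m^2/s"`,
#'   `"A^2/ps"` (diffusion); `"K"` (temperature).
#' @return numeric vector in the target unit.  Round-trips are exact to
#'   better than 1e-12 relative.
#' @examples
#' convert_units(-0.2068e-9, "N", "kcal/mol/A")
#' convert_units(0.3921e-18, "N*m", "kcal/mol/rad")
#' convert_units(1, "A^2/ps", "m^2/s")
#' @export
convert_units <- function(value, from, to) {
  fi <- .unit_info(from)
  ti <- .unit_info(to)
  if (fi$dim != ti$dim)
    stop("incompatible dimensions: '", from, "' (", fi$dim, ") vs '",
         to, "' (", ti$dim, ")", call. = FALSE)
  value * (fi$to_base / ti$to_base)
}
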