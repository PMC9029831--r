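#' Construct a sampled time series of instantaneous forces/torques
#'
#' Container for the per-configuration output of a restrained simulation:
#' a strictly increasing time base (ps) plus one or more named channels
#' such as the force component `fx` and the torque component `Tz`.
#'
#' @param time numeric vector of times in picoseconds, strictly increasing.
#' @param channels named list (or data.frame) of numeric vectors, one per
#'   channel, each the same length as `time`.
#' @param units named character vector mapping channel names to unit tags
#'   (see [convert_units()]).  Channels without an entry default to
#'   `"kcal/mol/A"` for `fx`, `"kcal/mol/rad"` for `Tz`, else `"kcal/mol"`.
#' @return an object of class `"time_series"`.
#' @export
time_series <- function(time, channels, units = NULL) {
  time <- as.numeric(time)
  if (length(time) == 0L) stop("empty time series", call. = FALSE)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  channels <- lapply(as.list(channels), as.numeric)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be named", call. = FALSE)
  for (nm in names(channels))
    if (length(channels[[nm]]) != length(time))
      stop("channel '", nm, "' length differs from time", call. = FALSE)
  default_unit <- function(nm)
    switch(nm, fx = "kcal/mol/A", Tz = "kcal/mol/rad",
           T = "K", "kcal/mol")
  u <- vapply(names(channels), function(nm) {
    tag <- if (!is.null(units) && nm %in% names(units)) units[[nm]] else default_unit(nm)
    .unit_info(tag)  # validates
    tag
  }, character(1))
  structure(list(time = time, channels = channels, units = u),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("Time series: %d samples, t = %g .. %g ps\n",
              length(x$time), min(x$time), max(x$time)))
  for (nm in names(x$channels))
    cat(sprintf("  %-4s [%s]  mean %.6g\n", nm, x$units[[nm]],
                mean(x$channels[[nm]])))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$time)

#' Read a force/torque time series from a delimited text file
#'
#' Reads a headered TSV/CSV (comment lines starting with `#` are skipped)
#' and maps columns to the time base and channels by name, so column order
#' is irrelevant.  Rows containing non-numeric fields are dropped.
#'
#' @param path file path.
#' @param dialect list with entries `time` (column name of the time base,
#'   default `"t"`) and `channels` (named character vector mapping channel
#'   name -> column name, default `c(fx = "fx", Tz = "Tz")`).
#' @param units named character vector of unit tags per channel,
#'   passed to [time_series()].
#' @param sep field separator; `NULL` (default) uses `","` for `.csv`
#'   files and any whitespace otherwise.
#' @return a [time_series()] object.
#' @export
read_timeseries <- function(path, dialect = list(), units = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  time_col <- if (!is.null(dialect$time)) dialect$time else "t"
  chan_map <- if (!is.null(dialect$channels)) dialect$channels else c(fx = "fx", Tz = "Tz")
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  dat <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("empty or unreadable file: ", path, call. = FALSE))
  if (nrow(dat) == 0L) stop("empty input: ", path, call. = FALSE)
  need <- c(time_col, unname(chan_map))
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num <- lapply(dat[need], function(v) suppressWarnings(as.numeric(v)))
  keep <- !Reduce(`|`, lapply(num, is.na))
  if (!any(keep)) stop("no numeric rows in ", path, call. = FALSE)
  num <- lapply(num, `[`, keep)
  chans <- num[unname(chan_map)]
  names(chans) <- names(chan_map)
  time_series(num[[time_col]], chans, units = units)
}

#' Discard the equilibration transient of a time series
#'
#' Restrained-sampling runs need an initial relaxation period before force
#' and torque fluctuate around their stationary means; this keeps exactly
#' the samples with `time >= t_start`.
#'
#' @param ts a [time_series()].
#' @param t_start cutoff in picoseconds; must lie within the sampled range.
#' @return the trimmed `time_series`.
#' @export
trim_equilibration <- function(ts, t_start) {
  stopifnot(inherits(ts, "time_series"))
  if (t_start > max(ts$time))
    stop("t_start beyond last sample: no data left", call. = FALSE)
  keep <- ts$time >= t_start
  time_series(ts$time[keep], lapply(ts$channels, `[`, keep), units = ts$units)
}

#' Mean and block-averaged standard error of a channel
#'
#' The mean is the plain arithmetic mean of all samples.  Because
#' consecutive force/torque samples are correlated, the standard error is
#' estimated from the variance of non-overlapping block means (trailing
#' partial block discarded).  With `block_size = 1` this reduces to the
#' i.i.d. estimate sd/sqrt(n).
#'
#' @param ts a [time_series()] (trim it first; see [trim_equilibration()]).
#' @param channel channel name.
#' @param block_size samples per block (default 100).
#' @return an object of class `"mean_estimate"` with fields `mean`, `sem`,
#'   `n_samples`, `block_size`, `unit`.  When fewer than 2 complete blocks
#'   exist the mean is still reported but `sem` is `NA` with a warning.
#' @export
mean_and_sem <- function(ts, channel, block_size = 100L) {
  stopifnot(inherits(ts, "time_series"))
  if (!channel %in% names(ts$channels))
    stop("no such channel: ", channel, call. = FALSE)
  block_size <- as.integer(block_size)
  if (block_size < 1L) stop("block_size must be >= 1", call. = FALSE)
  x <- ts$channels[[channel]]
  n <- length(x)
  m <- if (block_size == 1L) mean(x) else mean(x)  # mean over all samples
  nblock <- n %/% block_size
  if (block_size == 1L) {
    sem <- stats::sd(x) / sqrt(n)
  } else if (nblock < 2L) {
    warning("fewer than 2 complete blocks: uncertainty undefined", call. = FALSE)
    sem <- NA_real_
  } else {
    bm <- colMeans(matrix(x[seq_len(nblock * block_size)], nrow = block_size))
    sem <- stats::sd(bm) / sqrt(nblock)
  }
  structure(list(mean = m, sem = sem, n_samples = n,
                 block_size = block_size, channel = channel,
                 unit = unname(ts$units[[channel]])),
            class = "mean_estimate")
}

#' @export
print.mean_estimate <- function(x, ...) {
  cat(sprintf("<%s> = %.6g +/- %.3g %s  (n = %d, block %d)\n",
              x$channel, x$mean, x$sem, x$unit, x$n_samples, x$block_size))
  invisible(x)
}
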