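#' Run the full surface-reconstruction pipeline
#'
#' Drives synth (or file input) -> coarse fit -> optional fine refinement
#' -> adsorption-state extraction, writing every stage artifact plus a
#' machine-readable run log.  Identical config and seed produce
#' byte-identical outputs.
#'
#' @param config a named list, or the path to a YAML file with the same
#'   structure.  Recognised keys (all optional):
#'   \describe{
#'     \item{input}{`field_tsv` (pre-averaged coarse field TSV) or
#'       `manifest` (per-node time-series manifest; with
#'       `equilibration_ps`, `block_size`).  When absent, the synthetic
#'       benchmark surface is sampled instead.}
#'     \item{synth}{`sigma_f`, `sigma_T`, `n_samples` for the synthetic
#'       gradient noise (defaults 1, 1, 1e4).}
#'     \item{solver}{`tol`, `max_iter`, `sweep` for [fes()].}
#'     \item{fine}{`enable` (default `TRUE` in synthetic mode): refine on
#'       the default fine grid with [refine_fes()].}
#'     \item{minima}{`neighborhood` (default 4), optional `region`.}
#'   }
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for every stochastic stage.
#' @return invisibly, a list with the fitted surfaces, the states table
#'   and the artifact paths.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("pmfrun"),
                         seed = 1L) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  get_cfg <- function(path, default) {
    v <- config
    for (k in path) { v <- v[[k]]; if (is.null(v)) return(default) }
    v
  }
  solver <- list(tol = get_cfg(c("solver", "tol"), 1e-10),
                 max_iter = get_cfg(c("solver", "max_iter"), 1e6),
                 sweep = get_cfg(c("solver", "sweep"), "random"))
  log <- list(seed = seed, config = config,
              package = as.character(utils::packageVersion("pmfsurf")))
  paths <- list()

  synthetic <- is.null(config$input)
  surface_true <- NULL
  if (synthetic) {
    surface_true <- make_surface(cnc_surface_spec())
    nz <- noise_spec(sigma_f = get_cfg(c("synth", "sigma_f"), 1),
                     sigma_T = get_cfg(c("synth", "sigma_T"), 1),
                     n_samples = get_cfg(c("synth", "n_samples"), 1e4),
                     seed = seed)
    field <- sample_gradient_field(surface_true, coarse_grid(), nz)
    paths$field <- file.path(out_dir, "field_coarse.tsv")
    write_gradient_field(field, paths$field)
  } else if (!is.null(config$input$field_tsv)) {
    field <- read_gradient_field(config$input$field_tsv, theta_periodic = TRUE)
  } else if (!is.null(config$input$manifest)) {
    field <- assemble_gradient_field(
      config$input$manifest, coarse_grid(),
      equilibration_ps = get_cfg(c("input", "equilibration_ps"), 1000),
      block_size = get_cfg(c("input", "block_size"), 100L))
  } else stop("config$input must give field_tsv or manifest", call. = FALSE)

  coarse <- fes(field, tol = solver$tol, max_iter = solver$max_iter,
                sweep = solver$sweep, seed = seed)
  paths$surface_coarse <- file.path(out_dir, "surface_coarse.tsv")
  write_fes(coarse, paths$surface_coarse)
  log$coarse <- list(residual = coarse$residual, converged = coarse$converged,
                     iterations = coarse$iterations, dFw2o = coarse$dFw2o)

  fine <- NULL
  if (get_cfg(c("fine", "enable"), synthetic) && synthetic) {
    nz <- noise_spec(sigma_f = get_cfg(c("synth", "sigma_f"), 1),
                     sigma_T = get_cfg(c("synth", "sigma_T"), 1),
                     n_samples = get_cfg(c("synth", "n_samples"), 1e4),
                     seed = seed + 1L)
    fine_field <- sample_gradient_field(surface_true, fine_grid(), nz)
    fine <- refine_fes(coarse, fine_field, tol = solver$tol,
                       max_iter = solver$max_iter, sweep = solver$sweep,
                       seed = seed)
    paths$surface_fine <- file.path(out_dir, "surface_fine.tsv")
    write_fes(fine, paths$surface_fine)
    log$fine <- list(residual = fine$residual, converged = fine$converged,
                     iterations = fine$iterations)
  }

  states <- find_local_minima(
    if (!is.null(fine)) fine else coarse,
    neighborhood = get_cfg(c("minima", "neighborhood"), 4),
    region = get_cfg(c("minima", "region"), NULL))
  paths$states <- file.path(out_dir, "states.tsv")
  .write_tsv(as.data.frame(states), paths$states)
  log$states <- nrow(states)

  paths$log <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(list(coarse = coarse, fine = fine, states = states,
                 paths = paths, log = log))
}
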