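# Run configuration: solver tolerances and the thresholds that govern
# growth calls, gapfilling and expression fitting, with YAML overrides and
# a provenance record for reproducibility.

#' Build a run configuration
#'
#' @param lp_tol LP feasibility/optimality tolerance (default 1e-9).
#' @param epsilon gapfill / flux-fit biomass target (default 0.01).
#' @param delta flux-activity classification threshold (default 1e-3).
#' @param interaction_tol minimum reported transfer flux (default 1e-6).
#' @param growth_threshold growth-call objective cutoff (default 1e-6).
#' @param percentile expression threshold percentile (default 10).
#' @param seed random seed for fixture generation.
#' @param outdir output directory for CLI runs.
#' @param verbose print progress messages.
#' @return a validated named list of class "RunConfig".
#' @export
runConfig <- function(lp_tol = 1e-9, epsilon = GAPFILL_EPSILON,
                      delta = FLUX_ACTIVITY_DELTA,
                      interaction_tol = INTERACTION_TOL,
                      growth_threshold = GROWTH_THRESHOLD,
                      percentile = 10, seed = 1L, outdir = ".",
                      verbose = FALSE) {
  cfg <- list(lp_tol = lp_tol, epsilon = epsilon, delta = delta,
              interaction_tol = interaction_tol,
              growth_threshold = growth_threshold, percentile = percentile,
              seed = as.integer(seed), outdir = outdir, verbose = verbose)
  for (f in c("lp_tol", "delta", "interaction_tol", "growth_threshold"))
    if (cfg[[f]] <= 0) stop("config field '", f, "' must be > 0")
  if (cfg$percentile <= 0 || cfg$percentile >= 100)
    stop("percentile must lie in (0, 100)")
  structure(cfg, class = "RunConfig")
}

#' Load a run configuration from YAML, with overrides
#'
#' Values in the YAML file override the defaults; `...` (e.g. parsed CLI
#' flags) override the file.
#'
#' @param path optional YAML file path.
#' @param ... named overrides applied last.
#' @return a "RunConfig" list.
#' @export
readRunConfig <- function(path = NULL, ...) {
  base <- list()
  if (!is.null(path)) {
    base <- yaml::read_yaml(path)
    known <- names(formals(runConfig))
    unknown <- setdiff(names(base), known)
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  over <- list(...)
  do.call(runConfig, modifyList(base, over[!vapply(over, is.null, TRUE)]))
}

#' Write a provenance record for a run
#'
#' Records the package version, configuration, input file hashes and seed
#' as JSON next to the outputs, so any gapfilling or FBA result can be
#' reproduced.
#'
#' @param config a "RunConfig" list.
#' @param inputs character vector of input file paths (hashed).
#' @param path output JSON path.
#' @export
writeProvenance <- function(config, inputs, path) {
  hashes <- vapply(inputs, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  }, character(1))
  rec <- list(
    tool = "CommFBA",
    version = as.character(utils::packageVersion("CommFBA")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    inputs = as.list(setNames(hashes, inputs))
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
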