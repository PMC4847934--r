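PIPELINE_KEYS <- list(
  sim = c("tr_s", "n_volumes", "voxel_mm", "grid_dims", "order_id",
          "baseline", "beta_enc", "a_voc", "rho", "noise_sd", "ar1_phi",
          "drift_slope", "n_subjects", "p_distractor", "p_immediate",
          "p_vocab"),
  localizer = c("fwhm_mm", "alpha_fwe", "k_min"),
  mvpa = c("lag_exclude_s", "cost_C", "encoding_scope", "threshold"),
  inference = c("alpha", "proximity_mode"),
  io = c("out_dir"))

#' Load a pipeline configuration from YAML or JSON
#'
#' The file may contain the sections `sim`, `localizer`, `mvpa`,
#' `inference`, `io` and a top-level `seed`; unknown sections or keys are
#' rejected. Missing keys fall back to the package defaults ([sim_config()]
#' and the [run_experiment()] arguments).
#'
#' @param path Path to a `.yaml`/`.yml` (or JSON, which YAML subsumes)
#'   configuration file.
#' @return An object of class `pipeline_config`: list with `sim` (a
#'   `sim_config`), `localizer`, `mvpa`, `inference`, `io`, `seed`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path))
  raw <- yaml::read_yaml(path)
  pipeline_config_from_list(raw)
}

#' Build a pipeline configuration from a nested list
#'
#' @param raw Nested list with the sections described in [read_config()].
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_list <- function(raw) {
  known_sections <- c(names(PIPELINE_KEYS), "seed")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown))
    stop(sprintf("unknown configuration section(s): %s",
                 paste(unknown, collapse = ", ")))
  for (sec in names(PIPELINE_KEYS)) {
    bad <- setdiff(names(raw[[sec]]), PIPELINE_KEYS[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  s <- raw$sim
  acq_args <- s[intersect(names(s), c("tr_s", "n_volumes", "voxel_mm",
                                      "grid_dims"))]
  acq <- do.call(acq_params, acq_args)
  sim_args <- s[setdiff(names(s), names(acq_args))]
  sim_args$acquisition <- acq
  sim_args$seed <- seed
  sim <- do.call(sim_config, sim_args)
  structure(list(sim = sim,
                 localizer = utils::modifyList(
                   list(fwhm_mm = 8, alpha_fwe = 0.05, k_min = 20L),
                   raw$localizer %||% list()),
                 mvpa = utils::modifyList(
                   list(lag_exclude_s = 10, cost_C = 1,
                        encoding_scope = "all", threshold = "baseline"),
                   raw$mvpa %||% list()),
                 inference = utils::modifyList(
                   list(alpha = 0.05, proximity_mode = "pooled"),
                   raw$inference %||% list()),
                 io = raw$io %||% list(out_dir = "."),
                 seed = seed),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the pipeline described by a configuration file
#'
#' Reads the configuration, runs [run_experiment()] and writes the report
#' files to the configured output directory.
#'
#' @param config A `pipeline_config` (or a path to one).
#' @param out_dir Overrides the configured output directory when given.
#' @return The `group_report`, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  report <- run_experiment(
    config$sim,
    fwhm_mm = config$localizer$fwhm_mm,
    alpha_fwe = config$localizer$alpha_fwe,
    k_min = config$localizer$k_min,
    lag_exclude_s = config$mvpa$lag_exclude_s,
    cost_C = config$mvpa$cost_C,
    encoding_scope = config$mvpa$encoding_scope,
    threshold = config$mvpa$threshold,
    alpha = config$inference$alpha)
  dest <- out_dir %||% config$io$out_dir
  if (!is.null(dest)) write_report(report, dest)
  invisible(report)
}
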