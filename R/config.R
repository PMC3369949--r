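## Configuration parsing and output writing for script / command-line use.

config_schema <- c("N", "U", "R", "s", "sbar", "generations", "seed",
                   "fitness_noise_var", "burn_in", "record_trajectories",
                   "traj_stride", "marker_position", "paint_generation")

#' Parse and validate a simulation configuration
#'
#' Reads a YAML or JSON file (by extension), or takes a named list, with
#' keys mirroring the [sim_params()] arguments.  Unknown keys are rejected
#' with their paths; values are validated by [sim_params()] itself, whose
#' errors name the offending field.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @return A validated [sim_params()] object.
#' @export
parse_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config), class = "sweeprate_io_error")
    }
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      yaml = , yml = yaml::read_yaml(config),
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      abort(sprintf("unsupported config format '.%s' (use YAML or JSON)", ext),
            class = "sweeprate_io_error"))
  }
  if (!is.list(config)) abort("config must be a file path or a named list",
                              class = "sweeprate_param_error")
  unknown <- setdiff(names(config), config_schema)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "sweeprate_param_error")
  }
  do.call(sim_params, config)
}

#' Emit a configuration that round-trips through [parse_config()]
#'
#' @param params A [sim_params()] object.
#' @param path Output path ending in `.yaml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  keep <- params[intersect(config_schema, names(params))]
  keep <- keep[!vapply(keep, is.null, TRUE)]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(keep, path),
    json = jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    abort(sprintf("unsupported config format '.%s'", ext), class = "sweeprate_io_error"))
  invisible(path)
}

#' Write simulation results to a directory
#'
#' Writes tab-delimited tables (`fixations.tsv`, `genstats.tsv`, optionally
#' `trajectories.tsv`, `heterozygosity.tsv`), a `summary.json` with the
#' [glance.sweep_sim()] quantities, and a `run_meta.json` recording the full
#' parameters and seed so the run can be reproduced exactly.
#'
#' @param results A `sweep_sim` object (or a list of them, written to
#'   subdirectories by name).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_outputs <- function(results, out_dir) {
  if (!inherits(results, "sweep_sim") && is.list(results)) {
    files <- unlist(purrr::imap(results, function(res, nm) {
      write_outputs(res, file.path(out_dir, nm))
    }))
    return(invisible(files))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create output directory: %s", out_dir), class = "sweeprate_io_error")
  }
  written <- character(0)
  wtsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    written <<- c(written, path)
  }
  wtsv(results$fixations, "fixations.tsv")
  wtsv(results$genstats, "genstats.tsv")
  if (!is.null(results$trajectories)) wtsv(results$trajectories, "trajectories.tsv")
  if (!is.null(results$heterozygosity)) wtsv(results$heterozygosity, "heterozygosity.tsv")
  sj <- file.path(out_dir, "summary.json")
  jsonlite::write_json(as.list(glance(results)), sj, auto_unbox = TRUE, digits = NA)
  written <- c(written, sj)
  meta <- results$meta
  meta$params <- unclass(meta$params)[!vapply(unclass(meta$params), is.null, TRUE)]
  mj <- file.path(out_dir, "run_meta.json")
  jsonlite::write_json(meta, mj, auto_unbox = TRUE, digits = NA)
  invisible(c(written, mj))
}
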