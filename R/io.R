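ARCHIVE_SCHEMA_VERSION <- 1L

#' Read a run configuration
#'
#' YAML configuration with required keys `model` (arguments to
#' [model_params()]), `environment` (arguments to [environment_spec()]),
#' and `seed`; optional keys `n_events`, `n_replicates`, `out`. A missing
#' required key is an error naming the key.
#'
#' @param path YAML file.
#' @return list with `params` (`model_params`), `spec`
#'   (`environment_spec`), `seed`, plus any optional entries.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (key in c("model", "environment", "seed"))
    if (is.null(raw[[key]]))
      stop("config is missing required key: '", key, "'")
  # YAML 1.1 resolves a bare `N` key to a boolean; map it back
  names(raw$model)[names(raw$model) %in% c("FALSE", "n")] <- "N"
  params <- do.call(model_params, raw$model)
  spec <- do.call(environment_spec, raw$environment)
  c(list(params = params, spec = spec, seed = raw$seed),
    raw[setdiff(names(raw), c("model", "environment", "seed"))])
}

#' Write a run configuration
#' @param config list as returned by [read_config()] (or raw model /
#'   environment lists).
#' @param path output YAML file.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  out <- config
  if (inherits(config$params, "model_params")) {
    out$model <- unclass(config$params)
    out$params <- NULL
  }
  if (inherits(config$spec, "environment_spec")) {
    sp <- unclass(config$spec)
    sp$units <- NULL
    out$environment <- sp
    out$spec <- NULL
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a simulation record to a snapshot archive
#'
#' An archive is a directory holding a JSON manifest (schema version,
#' params, environment, seed, snapshot inventory) plus the snapshot and
#' final populations in R's native serialization. Round trips are
#' bit-for-bit.
#'
#' @param record a `sim_record`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_archive <- function(record, dir) {
  stopifnot(inherits(record, "sim_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- unclass(record$spec); sp$units <- NULL
  manifest <- list(
    schema_version = ARCHIVE_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("fluctG")),
    replicate_id = record$replicate_id, seed = record$seed,
    n_events = record$n_events, params = unclass(record$params),
    environment = sp,
    snapshot_generations = vapply(record$snapshots, `[[`, 0, "generation"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(record$snapshots, file.path(dir, "snapshots.rds"))
  saveRDS(record$final, file.path(dir, "final_population.rds"))
  saveRDS(record$mean_fitness, file.path(dir, "mean_fitness.rds"))
  invisible(dir)
}

#' Read a simulation record back from an archive
#' @param dir archive directory written by [write_archive()].
#' @return a `sim_record`.
#' @export
read_archive <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath))
    stop("not an archive: missing manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (is.null(manifest$schema_version) ||
      manifest$schema_version != ARCHIVE_SCHEMA_VERSION)
    stop("archive schema version ", manifest$schema_version %||% "<absent>",
         " does not match supported version ", ARCHIVE_SCHEMA_VERSION)
  for (f in c("snapshots.rds", "final_population.rds", "mean_fitness.rds"))
    if (!file.exists(file.path(dir, f)))
      stop("corrupted archive: missing dataset ", f)
  params <- do.call(model_params, manifest$params)
  env <- manifest$environment
  blocks <- env$blocks
  if (is.matrix(blocks)) # JSON simplification of equal-sized blocks
    blocks <- lapply(seq_len(nrow(blocks)), function(i) blocks[i, ])
  spec <- environment_spec(env$pattern, n_traits = env$n_traits,
                           blocks = blocks, step_size = env$step_size,
                           period_generations = env$period_generations,
                           bounded = env$bounded, bounds = env$bounds)
  structure(list(replicate_id = manifest$replicate_id, seed = manifest$seed,
                 params = params, spec = spec, n_events = manifest$n_events,
                 snapshots = readRDS(file.path(dir, "snapshots.rds")),
                 final = readRDS(file.path(dir, "final_population.rds")),
                 final_optimum = NULL,
                 mean_fitness = readRDS(file.path(dir, "mean_fitness.rds"))),
            class = "sim_record")
}
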