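#' Write a simulation configuration to YAML
#'
#' @param cfg a [sim_config()].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Fields mirror the [sim_config()] arguments; missing fields take the
#' defaults, and the result is validated. `write_config()` followed by
#' `read_config()` round-trips losslessly.
#'
#' @param path YAML file path.
#' @return A validated [sim_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}

#' Write simulation results to disk
#'
#' Writes tidy, text-only artifacts into `dir`:
#' * `records.csv` — long format, one row per (replicate, generation, deme,
#'   statistic) with columns `replicate`, `generation`, `deme`, `statistic`,
#'   `value`;
#' * `metadata.json` — full config echo, seeds, package version, status and
#'   (for experiments) the attempt/extinction log;
#' * for experiments additionally `cells.csv` (per-cell aggregates) and
#'   `replicates.csv` (per-replicate equilibrium statistics, one row per
#'   (cell, replicate, statistic)).
#'
#' @param result a `"replicate_result"` or `"experiment_result"`.
#' @param dir destination directory (created if absent).
#' @return `dir`, invisibly.
#' @export
emit_results <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (inherits(result, "replicate_result")) {
    records <- records_to_long(result$records, replicate = 1L)
    utils::write.csv(records, file.path(dir, "records.csv"),
                     row.names = FALSE)
    meta <- list(
      kind = "replicate",
      package_version = as.character(utils::packageVersion("hedgesim")),
      config = unclass(result$config),
      seed = result$seed,
      status = result$status
    )
  } else if (inherits(result, "experiment_result")) {
    utils::write.csv(result$cells, file.path(dir, "cells.csv"),
                     row.names = FALSE)
    if (!is.null(result$replicates)) {
      long <- stats::reshape(
        result$replicates,
        direction = "long",
        varying = setdiff(names(result$replicates),
                          c("cell", "replicate", "seed")),
        v.names = "value", timevar = "statistic",
        times = setdiff(names(result$replicates),
                        c("cell", "replicate", "seed"))
      )
      long <- long[order(long$cell, long$replicate, long$statistic),
                   c("cell", "replicate", "seed", "statistic", "value")]
      rownames(long) <- NULL
      utils::write.csv(long, file.path(dir, "replicates.csv"),
                       row.names = FALSE)
    }
    meta <- list(
      kind = "experiment",
      package_version = as.character(utils::packageVersion("hedgesim")),
      config = unclass(result$base_config),
      grid = result$grid,
      attempts = result$attempts
    )
  } else {
    stop("emit_results handles replicate_result or experiment_result objects")
  }
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}

records_to_long <- function(records, replicate = 1L) {
  stats_cols <- c("mean_instability", "mean_phenotype", "mean_fitness",
                  "deme_size", "local_adaptation")
  out <- do.call(rbind, lapply(stats_cols, function(st) {
    data.frame(replicate = replicate,
               generation = records$generation,
               deme = records$deme,
               statistic = st,
               value = as.numeric(records[[st]]),
               stringsAsFactors = FALSE)
  }))
  out[order(out$generation, out$statistic), ]
}

#' Read back emitted replicate records
#'
#' Reads the long-format `records.csv` written by [emit_results()] and pivots
#' it to the wide per-generation schema used by [run_replicate()].
#'
#' @param dir directory previously passed to [emit_results()].
#' @return List with `records` (wide data.frame) and `metadata`.
#' @export
read_results <- function(dir) {
  long <- utils::read.csv(file.path(dir, "records.csv"),
                          stringsAsFactors = FALSE)
  wide <- stats::reshape(long, direction = "wide",
                         idvar = c("replicate", "generation", "deme"),
                         timevar = "statistic")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[order(wide$generation),
               c("generation", "deme", "mean_instability", "mean_phenotype",
                 "mean_fitness", "deme_size", "local_adaptation")]
  wide$deme_size <- as.integer(wide$deme_size)
  rownames(wide) <- NULL
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  list(records = wide, metadata = meta)
}
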