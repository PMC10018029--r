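# Result serialization: CSV exports for parameters, traces, results tables,
# tornado tables, PSA scatter and CEAC points, plus run manifests.  All
# writers go through write-then-rename so a failure never leaves a partial
# file behind.

# run `writer(tmp)` against a temporary sibling, then rename into place
write_atomically <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

write_csv_atomically <- function(df, path) {
  write_atomically(path, function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE)
  })
}

#' Export a resolved parameter set as CSV for audit
#'
#' One row per scalar parameter with its base value and, where present, the
#' one-way range, SD and distribution family.
#'
#' @param params A [parameter_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_parameter_csv <- function(params, path) {
  scalars <- setdiff(names(params), "uncertainty")
  df <- data.frame(parameter = scalars,
                   base = unlist(params[scalars], use.names = FALSE))
  u <- params$uncertainty
  if (!is.null(u)) df <- merge(df, u, by = "parameter", all.x = TRUE,
                               sort = FALSE)
  write_csv_atomically(df[match(scalars, df$parameter), ], path)
  invisible(path)
}

#' Export a cohort trace as CSV
#'
#' One row per cycle with the occupancy of every expanded state, the
#' new-hospitalization inflow, and the occupancy (mid-cycle) and event
#' (start-of-cycle) discount factors.
#'
#' @param cohort A [run_cohort()] result.
#' @param params The [parameter_set()] used to run it.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trace_csv <- function(cohort, params, path) {
  stopifnot(inherits(cohort, "cohort_trace"))
  H <- cohort$horizon
  r <- params$discount_annual
  cyc <- 0:H
  df <- data.frame(cycle = cyc, age = cohort$start_age + cyc %/% 12,
                   cohort$trace, inflow = cohort$inflow,
                   discount_occupancy = (1 + r)^(-(cyc + 0.5) / 12),
                   discount_event = (1 + r)^(-cyc / 12),
                   check.names = FALSE)
  write_csv_atomically(df, path)
  invisible(path)
}

#' Export a base-case results table as CSV
#'
#' @param table A [results_table()] data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_results_csv <- function(table, path) {
  write_csv_atomically(table, path)
  invisible(path)
}

#' Export a tornado table as CSV
#'
#' @param entries A [tornado()] data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_tornado_csv <- function(entries, path) {
  write_csv_atomically(entries, path)
  invisible(path)
}

#' Export PSA scatter samples and CEAC points as CSV
#'
#' @param psa A [run_psa()] result.
#' @param scatter_path CSV path for the per-iteration incremental outcomes.
#' @param ceac_path Optional CSV path for CEAC points.
#' @param wtp_grid WTP grid used when `ceac_path` is given.
#' @return Invisibly, the paths written.
#' @export
export_psa_csv <- function(psa, scatter_path, ceac_path = NULL,
                           wtp_grid = seq(0, 50000, by = 100)) {
  stopifnot(inherits(psa, "psa_result"))
  scatter <- cbind(iteration = seq_len(nrow(psa$samples)), psa$samples)
  write_csv_atomically(scatter, scatter_path)
  paths <- scatter_path
  if (!is.null(ceac_path)) {
    write_csv_atomically(ceac(psa, wtp_grid), ceac_path)
    paths <- c(paths, ceac_path)
  }
  invisible(paths)
}

#' Run manifest for reproducibility
#'
#' Records the configuration-file digest, seed, iteration count, horizon and
#' package version: identical manifests under the same code version imply
#' identical outputs.
#'
#' @param config_path Path to the configuration file the run used.
#' @param seed Integer seed (`NA` for deterministic analyses).
#' @param n_iterations Monte Carlo iteration count (`NA` if none).
#' @param horizon Model horizon in cycles.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config_path, seed = NA_integer_,
                         n_iterations = NA_integer_, horizon = NA_integer_) {
  if (!file.exists(config_path)) {
    stop("configuration file not found: ", config_path)
  }
  structure(
    list(
      config_file = basename(config_path),
      config_md5 = unname(tools::md5sum(config_path)),
      seed = seed, n_iterations = n_iterations, horizon = horizon,
      package_version = as.character(utils::packageVersion("svcea")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "run_manifest"
  )
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  write_atomically(path, function(tmp) {
    jsonlite::write_json(unclass(manifest), tmp, auto_unbox = TRUE,
                         pretty = TRUE)
  })
  invisible(path)
}
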