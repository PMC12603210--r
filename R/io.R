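#' Parse and validate a run configuration
#'
#' Reads a YAML or JSON run configuration, fills documented defaults and
#' rejects unknown keys by name. JSON and YAML encodings of the same
#' content yield identical configurations.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `ps_run_config` list with fields `tolerance`, `damping`,
#'   `max_iter`, `coverage`, `fallback_pct`, `cap`, `shock_level`, `seed`.
#' @export
parse_run_config <- function(path) {
  if (!file.exists(path)) stop_bad_input("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw <- raw %||% list()
  defaults <- list(tolerance = 1e-6, damping = 0.5, max_iter = 500L,
                   coverage = 0.95, fallback_pct = 0.5, cap = 0.999,
                   shock_level = "mean", seed = 1L)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop_bad_input("unknown config key(s): %s",
                   paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, raw)
  cfg$max_iter <- as.integer(cfg$max_iter)
  cfg$seed <- as.integer(cfg$seed)
  if (!cfg$shock_level %in% c("mean", "low", "high")) {
    stop_bad_input("shock_level must be one of mean/low/high")
  }
  solver_control(cfg$tolerance, cfg$damping, cfg$max_iter) # validates
  if (cfg$coverage < 0 || cfg$coverage >= 1) {
    stop_bad_input("coverage must lie in [0, 1)")
  }
  structure(cfg, class = "ps_run_config")
}

#' Read and write a baseline dataset directory
#'
#' A baseline dataset is a directory of six CSVs (`regions.csv`,
#' `commodities.csv`, `market.csv`, `trade.csv`, `wedges.csv`,
#' `elasticities.csv`) in the schemas of [ps_baseline()]. Numeric columns
#' are serialised at full precision; write-then-read round-trips.
#'
#' @param dir Directory path.
#' @return `read_baseline()` returns a validated `ps_baseline`;
#'   `write_baseline()` returns the directory invisibly.
#' @export
read_baseline <- function(dir) {
  need <- c("regions", "commodities", "market", "trade", "wedges",
            "elasticities")
  paths <- file.path(dir, paste0(need, ".csv"))
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0) {
    stop_bad_input("baseline directory is missing: %s",
                   paste(missing, collapse = ", "))
  }
  tabs <- lapply(paths, readr::read_csv, show_col_types = FALSE)
  names(tabs) <- need
  ps_baseline(tabs$regions, tabs$commodities, tabs$market, tabs$trade,
              tabs$wedges, tabs$elasticities)
}

#' @rdname read_baseline
#' @param baseline A `ps_baseline`.
#' @export
write_baseline <- function(baseline, dir) {
  stopifnot(inherits(baseline, "ps_baseline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("regions", "commodities", "market", "trade", "wedges",
               "elasticities")) {
    readr::write_csv(baseline[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Write a result set atomically with a run manifest
#'
#' Serialises data frames to RFC-4180 CSVs (full numeric precision) and
#' lists to JSON in a staging directory, then renames it into place, so a
#' partial failure leaves no half-written result set. A `manifest.json`
#' with file digests, timestamps, package version and the seed/config is
#' written alongside; identical inputs yield identical digests.
#'
#' @param outputs Named list of data frames and/or lists.
#' @param out_dir Destination directory (replaced if it exists).
#' @param config Optional configuration (stored in the manifest).
#' @param seed Optional seed (stored in the manifest).
#' @return The manifest, invisibly.
#' @export
write_results <- function(outputs, out_dir, config = NULL, seed = NULL) {
  if (is.null(names(outputs)) || any(names(outputs) == "")) {
    stop_bad_input("outputs must be a fully named list")
  }
  parent <- dirname(out_dir)
  if (!dir.exists(parent)) stop_bad_input("unwritable directory: %s", parent)
  staging <- tempfile("pollishock_results_", tmpdir = parent)
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  files <- character(0)
  for (nm in names(outputs)) {
    x <- outputs[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(staging, paste0(nm, ".csv"))
      readr::write_csv(as_tibble(x), f)
    } else {
      f <- file.path(staging, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    files <- c(files, f)
  }
  manifest <- list(
    package = "pollishock",
    version = as.character(utils::packageVersion("pollishock")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    files = lapply(setNames(files, basename(files)), function(f) {
      list(md5 = unname(tools::md5sum(f)), bytes = file.size(f))
    }))
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  ok <- file.rename(staging, out_dir)
  if (!ok) {
    # cross-device fallback: copy then remove staging
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.copy(list.files(staging, full.names = TRUE), out_dir)
  }
  on.exit(NULL, add = FALSE)
  unlink(staging, recursive = TRUE)
  invisible(manifest)
}
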