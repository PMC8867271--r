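# Run configuration (YAML or JSON) and provenance records.

.config_schema <- function() list(
  space = c("names", "mins", "maxs", "units"),
  emulator = names(formals(emulator_config)),
  surrogate = c("n_snapshots", "energy", "folds", "restarts"),
  uq = c("n_samples", "reps", "days", "restenosis_threshold"),
  sensitivity = c("n_base", "reps"),
  seeds = c("master"),
  output_dir = NULL,
  n_train = NULL
)

#' Read and validate a pipeline run configuration
#'
#' Accepts YAML or JSON.  Top-level blocks: `space`, `emulator`,
#' `surrogate`, `uq`, `sensitivity`, `seeds`, `n_train`, `output_dir`;
#' unknown keys (at either level) are rejected, and the parameter-space
#' block must describe a valid box.  Every omitted value falls back to the
#' package default; the shipped default configuration is at
#' `system.file("extdata", "default_config.yaml", package = "isruq")`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path) {
  check_that(file.exists(path), "config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  schema <- .config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  check_that(length(unknown) == 0L, "unknown config keys: %s", paste(unknown, collapse = ", "))
  for (blk in intersect(names(cfg), names(schema))) {
    allowed <- schema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[blk]]), allowed)
    check_that(length(bad) == 0L, "unknown keys in '%s' block: %s", blk,
               paste(bad, collapse = ", "))
  }
  space <- if (!is.null(cfg$space)) {
    # YAML sequences mixing integers and doubles arrive as lists; flatten
    parameter_space(as.character(unlist(cfg$space$names)),
                    as.numeric(unlist(cfg$space$mins)),
                    as.numeric(unlist(cfg$space$maxs)),
                    if (!is.null(cfg$space$units)) as.character(unlist(cfg$space$units)))
  } else isr_parameter_space()
  emu <- do.call(emulator_config, cfg$emulator %||% list())
  defaults <- list(surrogate = list(n_snapshots = 100L, energy = 0.999,
                                    folds = 4L, restarts = 10L),
                   uq = list(n_samples = 1e4, reps = 10L, days = c(5, 10, 15, 20, 30),
                             restenosis_threshold = 0.5),
                   sensitivity = list(n_base = 4096L, reps = 10L),
                   seeds = list(master = 1L))
  merged <- lapply(names(defaults), function(blk) {
    utils::modifyList(defaults[[blk]], as.list(cfg[[blk]] %||% list()))
  })
  names(merged) <- names(defaults)
  structure(c(list(space = space, emulator = emu,
                   n_train = as.integer(cfg$n_train %||% 512L),
                   output_dir = cfg$output_dir %||% "isruq-output"),
              merged),
            class = "run_config")
}

#' Write a provenance record for a pipeline run
#'
#' Captures the full configuration, every derived seed and the package
#' version: together with the config file this suffices to reproduce any
#' artifact of the run bitwise.
#'
#' @param dir output directory.
#' @param config a `run_config`.
#' @param extra optional named list of additional fields (hashes, stage
#'   seeds).
#' @return path of the written JSON file, invisibly.
#' @export
write_provenance <- function(dir, config, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  rec <- c(list(package_version = as.character(utils::packageVersion("isruq")),
                r_version = R.version.string,
                timestamp = format(Sys.time(), tz = "UTC"),
                config = strip(config)),
           extra)
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
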