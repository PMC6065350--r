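#' Write an interaction matrix (or topology) as headered CSV
#'
#' Species ids `S1..Sn` form the header row and first column. For a
#' `feasnet_matrix` or `feasnet_topology`, structure metadata (label,
#' partition, seed, realized strength moments) is written to a JSON sidecar
#' `<path>.json`.
#'
#' @param x a `feasnet_matrix`, `feasnet_topology`, or plain numeric matrix.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_interaction_matrix <- function(x, path) {
  meta <- NULL
  if (inherits(x, "feasnet_matrix")) {
    meta <- list(
      structure_label = x$structure_label, realized = x$realized,
      seed = x$strength_spec$seed
    )
    m <- x$A
  } else if (inherits(x, "feasnet_topology")) {
    meta <- list(
      structure_label = x$structure_label,
      module_partition = x$module_partition,
      seed = x$spec$seed, n_links = x$n_links
    )
    m <- x$adjacency
  } else {
    m <- check_square_numeric(x)
  }
  ids <- paste0("S", seq_len(nrow(m)))
  df <- data.frame(species = ids, m)
  names(df) <- c("species", ids)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an interaction matrix from headered CSV
#'
#' Expects the layout written by [write_interaction_matrix()]: a `species`
#' id column plus one numeric column per species, with matching and unique
#' ids. Violations raise a format error naming the offending row or column.
#'
#' @param path CSV path.
#' @return a numeric matrix with species ids as dimnames.
#' @export
read_interaction_matrix <- function(path) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_config("expected a species id column plus matrix columns")
  ids <- as.character(df[[1]])
  cols <- names(df)[-1]
  if (length(cols) != length(ids)) {
    stop_config(
      "non-square table: ", length(ids), " rows vs ", length(cols), " columns"
    )
  }
  if (anyDuplicated(ids)) {
    stop_config("duplicated species id in rows: ", ids[duplicated(ids)][1])
  }
  if (!identical(cols, ids)) {
    bad <- which(cols != ids)[1]
    stop_config(
      "row/column id mismatch at position ", bad, ": row '", ids[bad],
      "' vs column '", cols[bad], "'"
    )
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    badcol <- cols[which(!vapply(df[-1], is.numeric, TRUE))[1]]
    stop_config("non-numeric entries in column '", badcol, "'")
  }
  dimnames(m) <- list(ids, ids)
  m
}

# recognized experiment-config keys (all optional; defaults mirror
# experiment_config()).
config_keys <- c(
  "n", "n_modules", "connectance", "within_between_ratio",
  "strength_mean", "strength_sd", "diag_value", "meanlog", "sdlog",
  "magnitude", "n_reps", "structures", "seed", "condition_bound",
  "max_retries"
)

#' Load an experiment configuration from YAML or JSON
#'
#' Missing keys take the package defaults (21 species, 5000 replicates, the
#' six canonical scenarios); unknown keys are rejected with their key path.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`); an empty file yields
#'   the full default configuration.
#' @return an [experiment_config()].
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  vals <- vals %||% list()
  unknown <- setdiff(names(vals), config_keys)
  if (length(unknown)) {
    stop_config("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(experiment_config, vals)
}

#' Write a result object to disk
#'
#' Persistence tables go to CSV (stable column order); gamma estimates to
#' JSON with keys `gamma`, `se`, `n_samples`, `seed`.
#'
#' @param x a `feasnet_persistence` table or `feasnet_gamma` estimate.
#' @param path output path.
#' @return a manifest entry: list with `path`, `md5`, and `written_at`.
#' @export
write_results <- function(x, path) {
  if (inherits(x, "feasnet_persistence")) {
    df <- as.data.frame(x)[, c(
      "structure", "scenario", "persisted", "n_reps", "degenerate", "seed"
    )]
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (inherits(x, "feasnet_gamma")) {
    jsonlite::write_json(
      list(gamma = x$gamma, se = x$se, n_samples = x$n_samples, seed = x$seed),
      path,
      auto_unbox = TRUE, digits = NA
    )
  } else {
    stop_config("write_results handles persistence tables and gamma estimates")
  }
  list(
    path = path,
    md5 = unname(tools::md5sum(path)),
    written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Assemble a run manifest
#'
#' Records the configuration hash, master seed, package version, and the
#' artifacts written, sufficient for a bit-identical re-run.
#'
#' @param config an [experiment_config()].
#' @param entries list of manifest entries from [write_results()].
#' @param path optional path; when given the manifest is written as JSON.
#' @return the manifest list, invisibly when written.
#' @export
run_manifest <- function(config, entries = list(), path = NULL) {
  cfg_plain <- unclass(config)
  cfg_plain$scenarios <- lapply(config$scenarios, unclass)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg_plain, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(
    config = cfg_plain,
    config_md5 = unname(tools::md5sum(tmp)),
    master_seed = config$seed,
    package_version = as.character(utils::packageVersion("feasnet")),
    artifacts = entries
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(manifest))
  }
  manifest
}
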