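#' Read an experiment configuration file
#'
#' The configuration is a YAML file whose keys mirror [network_params()]
#' one-to-one under `network:`, plus optional `experiment:` (name and
#' experiment-specific arguments), `seed:` and `output_dir:`. Unknown keys
#' are rejected with the offending key named.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `network` (a `network_params`),
#'   `experiment`, `experiment_args`, `seed` and `output_dir`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  top_allowed <- c("network", "experiment", "experiment_args", "seed", "output_dir")
  bad <- setdiff(names(raw), top_allowed)
  if (length(bad) > 0) {
    abort(paste0("Unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  net <- raw$network %||% list()
  bad <- setdiff(names(net), names(formals(network_params)))
  if (length(bad) > 0) {
    abort(paste0("Unknown network key(s): ", paste(bad, collapse = ", ")))
  }
  list(
    network = do.call(network_params, net),
    experiment = raw$experiment %||% "simulate",
    experiment_args = raw$experiment_args %||% list(),
    seed = raw$seed %||% 1L,
    output_dir = raw$output_dir %||% "."
  )
}

#' Write an experiment configuration file
#'
#' @param config A list as returned by [read_config()], or with a plain list
#'   under `network`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config$network <- unclass(config$network)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a report (or tables) to an output directory
#'
#' Writes the per-iteration CSV, an aggregate JSON (including the seed, the
#' package version and the fully resolved parameters), and a manifest CSV
#' listing every written file with its MD5 checksum. Numeric CSV output uses
#' 10 significant digits so byte-identical reruns are a meaningful
#' determinism check.
#'
#' @param x A `stereotypy_report`, `drive_difference`, `sweep_result`,
#'   `cr_grid`, `hill_fit`, or a plain data frame.
#' @param output_dir Directory to write into (created if needed).
#' @param name Basename stem for the files (defaults to the object's
#'   experiment name or class).
#' @return A tibble manifest (`file`, `md5`), invisibly written as
#'   `manifest.csv` too.
#' @export
write_results <- function(x, output_dir, name = NULL) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) abort(paste0("Cannot create directory ", output_dir))
  files <- character(0)
  fmt <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.numeric(col)) signif(col, 10) else col
    })
    df
  }
  wcsv <- function(df, fname) {
    path <- file.path(output_dir, fname)
    utils::write.table(fmt(as.data.frame(df)), path,
      sep = ",",
      row.names = FALSE, quote = FALSE
    )
    files <<- c(files, path)
  }
  wjson <- function(obj, fname) {
    path <- file.path(output_dir, fname)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, path)
  }

  if (inherits(x, "stereotypy_report")) {
    name <- name %||% x$experiment
    wcsv(x$per_iteration, paste0(name, "_per_iteration.csv"))
    wcsv(x$aux, paste0(name, "_aux.csv"))
    wjson(
      list(
        experiment = x$experiment,
        seed = x$seed,
        n_iterations = x$n_iterations,
        package_version = as.character(utils::packageVersion("mbstereo")),
        params = unclass(x$params),
        aggregates = x$aggregates,
        pooled_kc = x$pooled_kc
      ),
      paste0(name, "_aggregates.json")
    )
  } else if (inherits(x, "drive_difference")) {
    name <- name %||% "drive_difference"
    wcsv(x$per_iteration, paste0(name, "_per_iteration.csv"))
    wjson(
      list(
        r_input = x$r_input, r_response = x$r_response,
        drive_constant = x$drive_constant,
        seed = x$report$seed,
        package_version = as.character(utils::packageVersion("mbstereo")),
        params = unclass(x$report$params)
      ),
      paste0(name, "_summary.json")
    )
  } else if (inherits(x, "hill_fit")) {
    name <- name %||% "hill_fit"
    wjson(glance(x), paste0(name, ".json"))
  } else if (is.data.frame(x)) {
    name <- name %||% class(x)[1]
    wcsv(x, paste0(name, ".csv"))
  } else {
    abort("write_results() does not know how to write this object.")
  }

  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  utils::write.table(as.data.frame(manifest),
    file.path(output_dir, "manifest.csv"),
    sep = ",", row.names = FALSE, quote = FALSE
  )
  invisible(manifest)
}
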