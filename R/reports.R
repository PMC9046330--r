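## Output plumbing for the analysis drivers: RFC-4180 CSVs, JSON summaries
## and a plain-text run manifest recording provenance of every output file.

#' Write a tibble as CSV
#'
#' Thin wrapper around [utils::write.csv()] used by the analysis scripts so
#' every output is written identically (no row names, no quoting surprises).
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a PSA summary as JSON
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psa_summary <- function(psa, path) {
  stopifnot(inherits(psa, "psa_result"))
  jsonlite::write_json(list(
    n_iterations = psa$n_iterations,
    seed = psa$seed,
    n_rejected = psa$n_rejected,
    wtp = psa$wtp,
    mean_nmb_intervention = psa$mean_nmb_intervention,
    ci_nmb_intervention = psa$ci_nmb_intervention,
    mean_inmb = psa$mean_inmb,
    sd_inmb = psa$sd_inmb,
    prob_cost_effective = psa$prob_cost_effective
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Plain-text provenance record for one analysis run: package version,
#' timestamp, seed, the MD5 of the configuration actually loaded, and the
#' list of files the run produced.
#'
#' @param path Manifest output path.
#' @param outputs Character vector of output file paths (must exist).
#' @param seed Seed used, or `NA` for deterministic runs.
#' @param config_path Path of the loaded configuration; `NULL` for the
#'   packaged defaults.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, outputs, seed = NA,
                           config_path = NULL) {
  if (is.null(config_path))
    config_path <- system.file("extdata", "parameters.yaml",
                               package = "adtfalls", mustWork = TRUE)
  missing <- outputs[!file.exists(outputs)]
  if (length(missing) > 0)
    stop("manifest lists outputs that do not exist: ",
         paste(missing, collapse = ", "))
  lines <- c(
    sprintf("package: adtfalls %s",
            as.character(utils::packageVersion("adtfalls"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed: %s", seed),
    sprintf("config: %s", config_path),
    sprintf("config_md5: %s", unname(tools::md5sum(config_path))),
    "outputs:",
    sprintf("  - %s (md5 %s)", outputs, unname(tools::md5sum(outputs)))
  )
  writeLines(lines, path)
  invisible(path)
}
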