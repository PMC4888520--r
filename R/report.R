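# Report rendering: deterministic text/CSV/JSON artifacts for every result
# type, plus a run manifest. Renderers never re-round — every number shown
# is taken from the result objects as computed.

#' Render results as text tables and tidy data frames
#'
#' Accepts any of the package's result objects — [analytic_validity()],
#' [run_mc()], [project_cancers()], [scenario_report()], [simulate_cohort()]
#' — or a list of them, and returns the rendered text lines together with
#' tidy data.frame views ready for CSV export. Output is byte-stable for
#' identical inputs (no timestamps, locale-independent formatting).
#'
#' @param results a result object or list of result objects.
#' @return a list with `text` (character vector of report lines) and
#'   `tables` (named list of data.frames).
#' @export
render_tables <- function(results) {
  if (!is.list(results) || !is.null(attr(results, "class"))) {
    results <- list(results)
  }
  text <- character(0)
  tables <- list()
  add_text <- function(x) {
    text <<- c(text, utils::capture.output(print(x)), "")
  }
  for (res in results) {
    if (inherits(res, "analytic_validity")) {
      add_text(res)
      tables$confusion <- rbind(tables$confusion,
                                do.call(rbind, lapply(res, function(g) as.data.frame(g$counts))))
      tables$metrics <- rbind(tables$metrics,
                              do.call(rbind, lapply(res, function(g) as.data.frame(g$metrics))))
    } else if (inherits(res, "mc_summary")) {
      add_text(res)
      tables$mc_summary <- rbind(tables$mc_summary, res$summary)
      if (!is.null(res$replicates)) {
        tables$mc_replicates <- rbind(tables$mc_replicates, res$replicates)
      }
    } else if (inherits(res, "clinical_outcome")) {
      add_text(res)
      df <- res
      class(df) <- "data.frame"
      tables$clinical <- rbind(tables$clinical, df)
    } else if (inherits(res, "scenario_report")) {
      add_text(res)
      df <- res
      class(df) <- "data.frame"
      tables$scenarios <- rbind(tables$scenarios, df)
    } else if (inherits(res, "cohort_sim")) {
      add_text(res)
      tables$cohort_counts <- rbind(tables$cohort_counts,
                                    do.call(rbind, lapply(res$counts, as.data.frame)))
      tables$cohort_cancers <- rbind(tables$cohort_cancers, res$cancers)
    } else {
      stop(sprintf("render_tables: unsupported result class '%s'",
                   paste(class(res), collapse = "/")))
    }
  }
  list(text = text, tables = tables)
}

#' Write rendered reports to disk
#'
#' Writes `<out_prefix>.txt` (the text report), one
#' `<out_prefix>_<table>.csv` per tidy table, `<out_prefix>.json` (every
#' table as JSON, raw proportions included), and
#' `<out_prefix>_manifest.json` describing the run. Empty results still
#' produce the text and JSON files (header-only) so pipelines always find
#' their outputs.
#'
#' @param results a result object or list of them (see [render_tables()]).
#' @param out_prefix output path prefix; its directory must exist.
#' @param config optional [screen_config()] to record a configuration hash
#'   in the manifest.
#' @param seed optional seed to record in the manifest.
#' @param subcommand label recorded in the manifest (default `"report"`).
#' @return the manifest, invisibly.
#' @export
write_report <- function(results, out_prefix, config = NULL, seed = NULL,
                         subcommand = "report") {
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) {
    stop(sprintf("output directory does not exist: %s", dir))
  }
  rendered <- render_tables(results)
  outputs <- character(0)

  txt_path <- paste0(out_prefix, ".txt")
  writeLines(rendered$text, txt_path)
  outputs <- c(outputs, txt_path)

  for (nm in names(rendered$tables)) {
    csv_path <- paste0(out_prefix, "_", nm, ".csv")
    utils::write.csv(rendered$tables[[nm]], csv_path, row.names = FALSE)
    outputs <- c(outputs, csv_path)
  }

  json_path <- paste0(out_prefix, ".json")
  jsonlite::write_json(rendered$tables, json_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs <- c(outputs, json_path)

  manifest <- run_manifest(subcommand = subcommand, outputs = outputs,
                           config = config, seed = seed)
  manifest_path <- paste0(out_prefix, "_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Describe a run for provenance
#'
#' @param subcommand what was run.
#' @param outputs character vector of files the run wrote.
#' @param config optional [screen_config()]; hashed so identical
#'   configurations yield identical hashes.
#' @param seed optional RNG seed used.
#' @return a list with package version, timestamp, subcommand, seed,
#'   configuration hash and output paths.
#' @export
run_manifest <- function(subcommand, outputs = character(0), config = NULL,
                         seed = NULL) {
  list(
    package = "screenval",
    version = as.character(utils::packageVersion("screenval")),
    subcommand = subcommand,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = if (!is.null(config)) config_hash(config),
    outputs = outputs
  )
}
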