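#' Analyse a curated collection end to end
#'
#' Wires the full derivation: optional title harmonisation, validation
#' (refusing to proceed on findings), network build, and computation of all
#' node and network statistics.
#'
#' @param x an [aop_collection()].
#' @param hmap optional [harmonisation_map()] applied before validation.
#' @param drop_titles,nonadjacent_policy passed to [build_network()].
#' @param orientation,max_paths passed to [summarise_network()].
#' @return a list of class `aop_analysis`: `collection` (post-harmonisation),
#'   `network`, `result` (an `aop_summary`), `validation` (empty tibble).
#' @export
analyze_collection <- function(x, hmap = NULL,
                               drop_titles = "Unknown, MIE",
                               nonadjacent_policy = "reconcile",
                               orientation = "incoming",
                               max_paths = 1e6) {
  stopifnot(inherits(x, "aop_collection"))
  unused <- NULL
  if (!is.null(hmap)) {
    # unused-key findings only make sense against the raw titles
    pre <- validate_collection(x, hmap = hmap)
    unused <- pre[pre$finding == "unused harmonisation key", ]
    x <- apply_harmonisation(x, hmap)
  }
  report <- bind_rows(validate_collection(x), unused)
  if (nrow(report) > 0) {
    abort(paste0(
      "Collection failed validation:\n",
      paste(sprintf("  [%s] AOP %s: %s", report$finding,
                    ifelse(is.na(report$aop_id), "-", report$aop_id),
                    report$detail), collapse = "\n")
    ))
  }
  net <- build_network(x, drop_titles = drop_titles,
                       nonadjacent_policy = nonadjacent_policy,
                       validate = FALSE)
  res <- summarise_network(net, orientation = orientation, max_paths = max_paths)
  structure(
    list(collection = x, network = net, result = res, validation = report),
    class = "aop_analysis"
  )
}

#' Run the full analysis from files to report artifacts
#'
#' Reads a curated relationship table, applies an optional harmonisation map,
#' derives the network, computes all statistics, and writes the requested
#' artifacts into `output_dir`: node metrics (TSV + JSON), summary JSON,
#' convergent/divergent Markdown lists, GraphML/SIF/JSON graph exports, a
#' structured curation log (one line per applied rule, so the derived network
#' is auditable against the input row by row), and a run manifest listing
#' every file written.
#'
#' @param input path to the curated table.
#' @param output_dir directory for artifacts (created if needed).
#' @param dialect,col_map passed to [read_aop_tables()].
#' @param hmap_path optional path to a two-column harmonisation CSV.
#' @param formats subset of `c("tsv", "json", "graphml", "sif", "markdown")`.
#' @param drop_titles,nonadjacent_policy,orientation,max_paths analysis
#'   settings, see [analyze_collection()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `analysis` (the [analyze_collection()]
#'   result) and `files` (named character vector of artifact paths).
#' @export
run_aop_analysis <- function(input, output_dir,
                             dialect = "csv", col_map = aop_col_map(),
                             hmap_path = NULL,
                             formats = c("tsv", "json", "graphml", "sif", "markdown"),
                             drop_titles = "Unknown, MIE",
                             nonadjacent_policy = "reconcile",
                             orientation = "incoming",
                             max_paths = 1e6,
                             quiet = FALSE) {
  formats <- match.arg(formats, several.ok = TRUE)
  if (length(formats) == 0) abort("At least one export format is required")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  x <- read_aop_tables(input, dialect = dialect, col_map = col_map)
  say("read %d KER rows across %d AOPs from %s",
      nrow(x$kers), length(unique(x$kers$aop_id)), input)
  hmap <- if (!is.null(hmap_path)) read_harmonisation_map(hmap_path) else NULL

  analysis <- analyze_collection(
    x, hmap = hmap, drop_titles = drop_titles,
    nonadjacent_policy = nonadjacent_policy,
    orientation = orientation, max_paths = max_paths
  )
  net <- analysis$network
  say("derived network: %d nodes, %d edges, %d MIE->AO simple paths",
      nrow(net$nodes), nrow(net$edges), analysis$result$summary$n_paths)

  out <- function(name) file.path(output_dir, name)
  files <- c(curation_log = out("curation_log.txt"))
  writeLines(
    c(sprintf("input: %s", input),
      sprintf("settings: drop_titles=[%s]; nonadjacent_policy=%s; orientation=%s",
              paste(drop_titles, collapse = ", "), nonadjacent_policy, orientation),
      net$build_log),
    files[["curation_log"]]
  )
  if ("tsv" %in% formats) {
    files[["metrics_tsv"]] <- out("node_metrics.tsv")
    write_metrics(analysis$result$metrics, files[["metrics_tsv"]])
  }
  if ("json" %in% formats) {
    files[["metrics_json"]] <- out("node_metrics.json")
    write_metrics(analysis$result$metrics, files[["metrics_json"]])
    files[["summary_json"]] <- out("network_summary.json")
    write_summary_json(analysis$result$summary, files[["summary_json"]])
    files[["network_json"]] <- out("network.json")
    write_network_json(net, files[["network_json"]])
  }
  if ("graphml" %in% formats) {
    files[["graphml"]] <- out("network.graphml")
    write_graphml(net, files[["graphml"]])
  }
  if ("sif" %in% formats) {
    files[["sif"]] <- out("network.sif")
    write_sif(net, files[["sif"]])
  }
  if ("markdown" %in% formats) {
    files[["convergence_md"]] <- out("convergence_tables.md")
    write_convergence_md(analysis$result$metrics, files[["convergence_md"]])
  }
  files[["manifest"]] <- out("run_manifest.json")
  jsonlite::write_json(
    list(input = input, artifacts = as.list(files)),
    files[["manifest"]], auto_unbox = TRUE, pretty = TRUE
  )
  say("wrote %d artifact(s) to %s", length(files), output_dir)
  invisible(list(analysis = analysis, files = files))
}

#' Generate a synthetic collection and write it in the canonical CSV schema
#'
#' Byte-identical output for identical configurations (including the seed).
#'
#' @param config a [generator_config()].
#' @param path output CSV path.
#' @return invisibly, the generated [aop_collection()].
#' @export
run_aop_simulation <- function(config, path) {
  x <- generate_collection(config)
  write_collection_csv(x, path)
  invisible(x)
}
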