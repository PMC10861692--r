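#' Canonical column mapping for curated AOP tables
#'
#' The canonical schema stores one key event relationship per row with columns
#' `aop_id`, `upstream_title`, `upstream_type`, `downstream_title`,
#' `downstream_type`, `adjacency`, `woe` and (optionally) `aop_title`. Curated
#' workbooks exported from the AOP-Wiki use varying column headers; a column
#' map translates them on read.
#'
#' @param ... named arguments `canonical_name = "column name in the file"`.
#'   Unspecified columns default to their canonical names.
#' @return a named character vector usable as the `col_map` of
#'   [read_aop_tables()].
#' @export
aop_col_map <- function(...) {
  defaults <- c(
    aop_id = "aop_id",
    aop_title = "aop_title",
    upstream_title = "upstream_title",
    upstream_type = "upstream_type",
    downstream_title = "downstream_title",
    downstream_type = "downstream_type",
    adjacency = "adjacency",
    woe = "woe"
  )
  override <- c(...)
  if (length(override) > 0) {
    unknown <- setdiff(names(override), names(defaults))
    if (length(unknown) > 0) {
      abort(sprintf(
        "Unknown canonical column(s) in mapping: %s",
        paste(unknown, collapse = ", ")
      ))
    }
    defaults[names(override)] <- override
  }
  defaults
}

#' Read a curated AOP relationship table
#'
#' Reads an AOP-Wiki-style curated table (one key event relationship per row)
#' from CSV or XLSX into an [aop_collection()]. Blank weight-of-evidence cells
#' become `"unspecified"`; H/M/L letters and high/medium/low words are both
#' accepted; titles are NFC-normalised and whitespace-trimmed. Row order
#' within an AOP is preserved.
#'
#' Rows that restate the same relationship within one AOP are tolerated when
#' they agree; the same pair recorded with contradictory adjacency in a single
#' AOP is a curation error and is rejected.
#'
#' @param path path to the table.
#' @param dialect `"csv"` (UTF-8, comma, header row; the canonical dialect) or
#'   `"xlsx"` (requires the readxl package).
#' @param col_map column mapping from [aop_col_map()].
#' @param sheet worksheet to read for the xlsx dialect (default first).
#' @return an [aop_collection()].
#' @export
read_aop_tables <- function(path, dialect = c("csv", "xlsx"),
                            col_map = aop_col_map(), sheet = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- switch(dialect,
    csv = readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        abort("Reading xlsx requires the readxl package; use the csv dialect otherwise")
      }
      readxl::read_excel(path, sheet = sheet, col_types = "text")
    }
  )
  mandatory <- setdiff(names(col_map), "aop_title")
  missing_cols <- col_map[mandatory][!col_map[mandatory] %in% names(raw)]
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Input table is missing mandatory column(s): %s",
      paste(dQuote(missing_cols, FALSE), collapse = ", ")
    ))
  }
  kers <- tibble(
    aop_id = raw[[col_map[["aop_id"]]]],
    aop_title = if (col_map[["aop_title"]] %in% names(raw)) {
      raw[[col_map[["aop_title"]]]]
    } else {
      NA_character_
    },
    upstream_title = raw[[col_map[["upstream_title"]]]],
    upstream_type = raw[[col_map[["upstream_type"]]]],
    downstream_title = raw[[col_map[["downstream_title"]]]],
    downstream_type = raw[[col_map[["downstream_type"]]]],
    adjacency = raw[[col_map[["adjacency"]]]],
    woe = raw[[col_map[["woe"]]]]
  )
  x <- aop_collection(kers)
  contradictions <- contradictory_rows(x)
  if (nrow(contradictions) > 0) {
    abort(paste0(
      "Contradictory duplicate KER rows (same AOP, same pair, different adjacency):\n",
      paste(sprintf(
        "  rows %s: AOP %d, %s -> %s",
        contradictions$rows, contradictions$aop_id,
        contradictions$upstream_title, contradictions$downstream_title
      ), collapse = "\n")
    ))
  }
  x
}

# Same (AOP, ordered pair) recorded with more than one adjacency value.
contradictory_rows <- function(x) {
  k <- x$kers
  if (nrow(k) == 0) {
    return(tibble(
      aop_id = integer(0), upstream_title = character(0),
      downstream_title = character(0), rows = character(0)
    ))
  }
  k$.row <- seq_len(nrow(k))
  k |>
    group_by(.data$aop_id, .data$upstream_title, .data$downstream_title) |>
    summarise(
      n_adj = length(unique(.data$adjacency)),
      rows = paste(.data$.row, collapse = ", "),
      .groups = "drop"
    ) |>
    filter(.data$n_adj > 1) |>
    select(-"n_adj")
}

#' Write a collection in the canonical CSV schema
#'
#' Round-trips with [read_aop_tables()]: reading the written file back yields
#' an identical collection. Byte output is deterministic for a given
#' collection.
#'
#' @param x an [aop_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collection_csv <- function(x, path) {
  stopifnot(inherits(x, "aop_collection"))
  readr::write_csv(x$kers, path, progress = FALSE)
  invisible(path)
}
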