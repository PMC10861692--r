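#' Validate a curated AOP collection
#'
#' Reports everything that would make the collection unsafe to merge into a
#' network: AOPs without an annotated MIE or AO, contradictory duplicate KERs
#' (same AOP and pair, different adjacency), self-loop relationships, and —
#' when a harmonisation map is supplied — map keys that match no raw title.
#' An empty report means the collection is build-ready.
#'
#' This is a reporting operation: it never throws on findings.
#'
#' @param x an [aop_collection()].
#' @param hmap optional [harmonisation_map()] to check for unused keys.
#' @return a tibble with columns `finding`, `aop_id`, `detail`; zero rows iff
#'   the collection is build-ready.
#' @export
validate_collection <- function(x, hmap = NULL) {
  stopifnot(inherits(x, "aop_collection"))
  findings <- list()
  add <- function(finding, aop_id, detail) {
    findings[[length(findings) + 1]] <<- tibble(
      finding = finding, aop_id = as.integer(aop_id), detail = detail
    )
  }

  if (nrow(x$kers) == 0) {
    add("empty collection", NA, "collection contains no KER rows")
  } else {
    recs <- aop_records(x)
    for (i in seq_len(nrow(recs))) {
      if (length(recs$mies[[i]]) == 0) {
        add("AOP without MIE", recs$aop_id[[i]],
            "no key event annotated as MIE")
      }
      if (length(recs$aos[[i]]) == 0) {
        add("AOP without AO", recs$aop_id[[i]],
            "no key event annotated as AO")
      }
    }

    contradictions <- contradictory_rows(x)
    for (i in seq_len(nrow(contradictions))) {
      add("contradictory duplicate KER", contradictions$aop_id[[i]],
          sprintf("%s -> %s recorded with differing adjacency (rows %s)",
                  contradictions$upstream_title[[i]],
                  contradictions$downstream_title[[i]],
                  contradictions$rows[[i]]))
    }

    loops <- which(x$kers$upstream_title == x$kers$downstream_title)
    for (i in loops) {
      add("self-loop KER", x$kers$aop_id[[i]],
          sprintf("row %d: %s -> itself", i, x$kers$upstream_title[[i]]))
    }

    # Conflicting role annotation for the same event within one AOP is legal
    # on the wiki (an event can be both KE and AO of one pathway); no finding.
  }

  if (!is.null(hmap)) {
    titles_raw <- unique(c(x$kers$upstream_title, x$kers$downstream_title))
    known <- unique(c(titles_raw, hmap$entries$canonical))
    unused <- setdiff(hmap$entries$raw[
      hmap$entries$raw != hmap$entries$canonical
    ], known)
    for (t in unused) {
      add("unused harmonisation key", NA,
          sprintf("raw title %s matches no key event", dQuote(t, FALSE)))
    }
  }

  if (length(findings) == 0) {
    tibble(finding = character(0), aop_id = integer(0), detail = character(0))
  } else {
    bind_rows(findings)
  }
}

#' Write a validation report as text or JSON
#'
#' @param report a tibble from [validate_collection()].
#' @param path output path; format chosen by extension (`.json` or text).
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(report, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    lines <- if (nrow(report) == 0) {
      "collection is build-ready: no findings"
    } else {
      sprintf("[%s] AOP %s: %s", report$finding,
              ifelse(is.na(report$aop_id), "-", report$aop_id), report$detail)
    }
    writeLines(lines, path)
  }
  invisible(path)
}
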