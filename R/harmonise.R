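#' Key-event title harmonisation maps
#'
#' Distinct AOP-Wiki entries frequently describe the same biological event
#' under different titles (e.g. "Dysfunction, Mitochondria" and "Increase,
#' Mitochondrial Dysfunction" both denote mitochondrial dysfunction). A
#' harmonisation map pools such synonyms under one canonical title. Pooling is
#' always explicit: the map is curated by the analyst, never inferred.
#'
#' The map must be idempotent — applying it twice equals applying it once — so
#' a canonical title may never itself be remapped (no `a -> b`, `b -> c`
#' chains), and each raw title maps to exactly one canonical title.
#'
#' @param raw character vector of raw titles (map keys).
#' @param canonical character vector of canonical titles, same length.
#' @return an object of class `harmonisation_map`.
#' @export
harmonisation_map <- function(raw, canonical) {
  raw <- normalise_title(raw)
  canonical <- normalise_title(canonical)
  if (length(raw) != length(canonical)) {
    abort("raw and canonical must have the same length")
  }
  entries <- tibble(raw = raw, canonical = canonical)
  dup <- entries |>
    group_by(.data$raw) |>
    summarise(n = n_distinct(.data$canonical), .groups = "drop") |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "Raw title(s) mapped to more than one canonical title: %s",
      paste(dQuote(dup$raw, FALSE), collapse = ", ")
    ))
  }
  entries <- distinct(entries)
  chained <- entries$raw[
    entries$raw %in% entries$canonical & entries$raw != entries$canonical
  ]
  # A canonical title appearing as a non-identity key would make the map
  # non-idempotent (a -> b -> c chain).
  if (length(chained) > 0) {
    abort(sprintf(
      "Harmonisation map contains chain(s): canonical title(s) %s are remapped",
      paste(dQuote(chained, FALSE), collapse = ", ")
    ))
  }
  structure(list(entries = entries), class = "harmonisation_map")
}

#' Read a harmonisation map from a two-column CSV
#'
#' @param path CSV with columns `raw_title`, `canonical_title` (header row).
#' @return a [harmonisation_map()].
#' @export
read_harmonisation_map <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  need <- c("raw_title", "canonical_title")
  if (!all(need %in% names(raw))) {
    abort("Harmonisation map CSV needs columns raw_title and canonical_title")
  }
  harmonisation_map(raw$raw_title, raw$canonical_title)
}

hmap_lookup <- function(hmap, titles) {
  if (is.null(hmap)) return(titles)
  idx <- match(titles, hmap$entries$raw)
  out <- ifelse(is.na(idx), titles, hmap$entries$canonical[idx])
  out
}

# canonical title -> raw titles pooled into it (non-identity entries only)
harmonisation_aliases <- function(hmap) {
  if (is.null(hmap)) return(list())
  e <- hmap$entries[hmap$entries$raw != hmap$entries$canonical, ]
  split(e$raw, e$canonical)
}

#' Apply a harmonisation map to a collection
#'
#' Rewrites every key-event title to its canonical form and records the pooled
#' raw titles as aliases. Roles and AOP memberships of pooled events are
#' unioned in the derived views. The operation is idempotent and preserves the
#' multiset of (AOP, upstream, downstream) relationships up to title
#' rewriting: no KER is created or lost.
#'
#' A map that sends both endpoints of a single KER to the same canonical title
#' would manufacture a self-loop; this is rejected with the offending AOP and
#' relationship named.
#'
#' @param x an [aop_collection()].
#' @param hmap a [harmonisation_map()].
#' @return a new [aop_collection()] with canonical titles.
#' @export
apply_harmonisation <- function(x, hmap) {
  stopifnot(inherits(x, "aop_collection"), inherits(hmap, "harmonisation_map"))
  k <- x$kers
  up <- hmap_lookup(hmap, k$upstream_title)
  dn <- hmap_lookup(hmap, k$downstream_title)
  collapsed <- which(up == dn & k$upstream_title != k$downstream_title)
  if (length(collapsed) > 0) {
    i <- collapsed[[1]]
    abort(sprintf(
      "Harmonisation collapses both endpoints of a KER into %s (AOP %d, %s -> %s)",
      dQuote(up[[i]], FALSE), k$aop_id[[i]],
      dQuote(k$upstream_title[[i]], FALSE), dQuote(k$downstream_title[[i]], FALSE)
    ))
  }
  k$upstream_title <- up
  k$downstream_title <- dn
  prior <- if (is.null(x$harmonisation)) {
    tibble(raw = character(0), canonical = character(0))
  } else {
    x$harmonisation$entries
  }
  merged <- distinct(bind_rows(prior, hmap$entries))
  aop_collection(k, harmonisation = harmonisation_map(merged$raw, merged$canonical))
}
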