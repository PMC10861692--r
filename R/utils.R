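#' @importFrom rlang %||% abort warn
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Levels are ordered weakest -> strongest so match() gives a usable rank.
WOE_LEVELS <- c("unspecified", "low", "medium", "high")
ADJACENCY_LEVELS <- c("adjacent", "nonadjacent")
KE_ROLES <- c("MIE", "KE", "AO")

#' Normalise a key-event title
#'
#' Titles are the sole node identity in a collection, so matching must be
#' deterministic: Unicode NFC normalisation, then trimming and collapsing of
#' internal whitespace. No fuzzy matching is ever applied; pooling synonymous
#' titles is the job of an explicit [harmonisation_map()].
#'
#' @param x character vector of raw titles.
#' @return character vector of normalised titles.
#' @export
normalise_title <- function(x) {
  x <- stringi::stri_trans_nfc(as.character(x))
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

# Parse weight-of-evidence annotations. Both the one-letter labels used on
# network figures (H/M/L) and the written-out words are accepted; blank or
# missing cells mean the developers left the field empty.
parse_woe <- function(x) {
  x <- tolower(stringi::stri_trim_both(as.character(x)))
  x[is.na(x) | x == "" | x == "na"] <- "unspecified"
  map <- c(
    h = "high", high = "high",
    m = "medium", medium = "medium", moderate = "medium",
    l = "low", low = "low",
    unspecified = "unspecified"
  )
  out <- unname(map[x])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort(sprintf(
      "Unrecognised weight-of-evidence value(s): %s (expected high/medium/low, H/M/L, or blank)",
      paste(dQuote(bad, FALSE), collapse = ", ")
    ))
  }
  out
}

parse_adjacency <- function(x) {
  x <- tolower(stringi::stri_trim_both(as.character(x)))
  map <- c(
    adjacent = "adjacent", direct = "adjacent",
    nonadjacent = "nonadjacent", `non-adjacent` = "nonadjacent",
    indirect = "nonadjacent"
  )
  out <- unname(map[x])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort(sprintf(
      "Unrecognised adjacency value(s): %s (expected adjacent/nonadjacent)",
      paste(dQuote(bad, FALSE), collapse = ", ")
    ))
  }
  out
}

parse_role <- function(x) {
  x <- toupper(stringi::stri_trim_both(as.character(x)))
  if (!all(x %in% KE_ROLES)) {
    bad <- unique(x[!x %in% KE_ROLES])
    abort(sprintf(
      "Unrecognised key-event type(s): %s (expected MIE, KE or AO)",
      paste(dQuote(bad, FALSE), collapse = ", ")
    ))
  }
  x
}

woe_rank <- function(x) match(x, WOE_LEVELS)

# Highest evidence level among contributors (high > medium > low > unspecified).
merge_woe <- function(x) WOE_LEVELS[max(woe_rank(x))]

#' Round half away from zero
#'
#' Integer-percent rounding used throughout the summaries, so that the shares
#' of a 45-node network render consistently (26/45 -> 58%, 11/45 -> 24%,
#' 27/45 -> 60%, 7/45 -> 16%). Base `round()` rounds half to even, which is the
#' wrong convention for these reports.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Locale-independent sort: node and edge orderings must be identical on every
# platform for the serialised outputs to be reproducible.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")
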