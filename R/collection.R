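#' Curated AOP collections
#'
#' An `aop_collection` holds a set of curated linear adverse outcome pathways
#' in the canonical one-row-per-KER form: each row records one key event
#' relationship (KER) of one AOP, with the upstream and downstream key-event
#' titles, the role each plays in that AOP (MIE, KE or AO), the adjacency flag
#' and the qualitative weight of evidence. Row order within an AOP is
#' preserved, mirroring the upstream-to-downstream order of the source tables.
#'
#' The relationship table is the single source of truth; the key-event and
#' per-AOP views ([key_events()], [aop_records()]) are derived from it.
#'
#' @param kers a data frame with columns `aop_id`, `upstream_title`,
#'   `upstream_type`, `downstream_title`, `downstream_type`, `adjacency`,
#'   `woe`, and optionally `aop_title`.
#' @param harmonisation an optional harmonisation map already applied to the
#'   titles (recorded so alias sets can be reported).
#' @return an object of class `aop_collection`.
#' @export
aop_collection <- function(kers, harmonisation = NULL) {
  kers <- as_tibble(kers)
  required <- c(
    "aop_id", "upstream_title", "upstream_type",
    "downstream_title", "downstream_type", "adjacency", "woe"
  )
  missing_cols <- setdiff(required, names(kers))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Collection is missing mandatory column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"aop_title" %in% names(kers)) kers$aop_title <- NA_character_
  kers <- kers[, c(
    "aop_id", "aop_title", "upstream_title", "upstream_type",
    "downstream_title", "downstream_type", "adjacency", "woe"
  )]
  kers$aop_id <- as.integer(kers$aop_id)
  if (anyNA(kers$aop_id)) abort("aop_id must be an integer for every row")
  kers$upstream_title <- normalise_title(kers$upstream_title)
  kers$downstream_title <- normalise_title(kers$downstream_title)
  if (nrow(kers) > 0) {
    if (any(!nzchar(kers$upstream_title)) || any(!nzchar(kers$downstream_title))) {
      abort("Key-event titles must be non-empty")
    }
    kers$upstream_type <- parse_role(kers$upstream_type)
    kers$downstream_type <- parse_role(kers$downstream_type)
    kers$adjacency <- parse_adjacency(kers$adjacency)
    kers$woe <- parse_woe(kers$woe)
  } else {
    kers$upstream_type <- character(0)
    kers$downstream_type <- character(0)
    kers$adjacency <- character(0)
    kers$woe <- character(0)
  }
  structure(
    list(kers = kers, harmonisation = harmonisation),
    class = "aop_collection"
  )
}

#' @export
print.aop_collection <- function(x, ...) {
  ids <- unique(x$kers$aop_id)
  cat(sprintf(
    "<aop_collection> %d AOP(s), %d KER row(s), %d distinct key event(s)\n",
    length(ids), nrow(x$kers), length(collection_titles(x))
  ))
  invisible(x)
}

collection_titles <- function(x) {
  sort_c(unique(c(x$kers$upstream_title, x$kers$downstream_title)))
}

# Long view of key-event roles: one row per (title, AOP, role).
ke_roles <- function(x) {
  k <- x$kers
  long <- bind_rows(
    tibble(
      canonical_title = k$upstream_title, aop_id = k$aop_id,
      role = k$upstream_type
    ),
    tibble(
      canonical_title = k$downstream_title, aop_id = k$aop_id,
      role = k$downstream_type
    )
  )
  distinct(long) |> arrange(.data$canonical_title, .data$aop_id, .data$role)
}

#' Key-event view of a collection
#'
#' One row per harmonised key event: its canonical title, the AOPs it appears
#' in, its role in each of those AOPs (a key event may be an MIE in one AOP
#' and an ordinary KE in another), and any raw titles pooled into it by a
#' harmonisation map.
#'
#' @param x an [aop_collection()].
#' @return a tibble with columns `canonical_title`, `aop_ids` (list of integer
#'   vectors), `n_aops`, `roles` (list of per-AOP role vectors named by AOP
#'   id), and `aliases` (list of raw-title character vectors).
#' @export
key_events <- function(x) {
  stopifnot(inherits(x, "aop_collection"))
  roles <- ke_roles(x)
  ke <- roles |>
    group_by(.data$canonical_title) |>
    summarise(
      aop_ids = list(sort(unique(.data$aop_id))),
      n_aops = length(unique(.data$aop_id)),
      roles = list({
        per_aop <- split(.data$role, .data$aop_id)
        vapply(per_aop, function(r) paste(
          KE_ROLES[KE_ROLES %in% r],
          collapse = "/"
        ), character(1))
      }),
      .groups = "drop"
    )
  aliases <- harmonisation_aliases(x$harmonisation)
  ke$aliases <- lapply(ke$canonical_title, function(t) {
    als <- aliases[[t]] %||% character(0)
    sort_c(unique(c(als, t)))
  })
  ke[order_c(ke$canonical_title), ]
}

#' Per-AOP view of a collection
#'
#' @param x an [aop_collection()].
#' @return a tibble with one row per AOP: `aop_id`, `title`, `n_kers`, and
#'   list-columns `mies` and `aos` holding the canonical titles annotated as
#'   molecular initiating events and adverse outcomes in that AOP.
#' @export
aop_records <- function(x) {
  stopifnot(inherits(x, "aop_collection"))
  roles <- ke_roles(x)
  k <- x$kers
  ids <- unique(k$aop_id)
  out <- lapply(ids, function(id) {
    r <- roles[roles$aop_id == id, ]
    tibble(
      aop_id = id,
      title = {
        t <- k$aop_title[k$aop_id == id]
        t <- t[!is.na(t)]
        if (length(t) > 0) t[[1]] else NA_character_
      },
      n_kers = sum(k$aop_id == id),
      mies = list(sort_c(r$canonical_title[r$role == "MIE"])),
      aos = list(sort_c(r$canonical_title[r$role == "AO"]))
    )
  })
  bind_rows(out) |> arrange(.data$aop_id)
}
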