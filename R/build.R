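#' Merge curated AOPs into a single directed network
#'
#' Pools the relationship rows of all AOPs into one directed graph of key
#' events, applying the standard derivation rules:
#'
#' * **Edge collapse** — the same ordered pair reported by several AOPs
#'   becomes one edge; the contributing AOP ids are unioned into the edge's
#'   provenance. The collapsed edge's weight of evidence is the highest level
#'   among contributors (high > medium > low > unspecified); the per-AOP
#'   levels are retained in `woe_by_aop`.
#' * **Nonadjacency reconciliation** (`nonadjacent_policy = "reconcile"`,
#'   the default) — a relationship flagged nonadjacent in one AOP but adjacent
#'   in another is stored as adjacent; pairs nonadjacent in every contributor
#'   keep the flag. `"keep_flagged"` marks a collapsed edge nonadjacent if any
#'   contributor did; `"exclude"` removes nonadjacent rows before collapsing.
#' * **Node drops** — placeholder events (by default the `"Unknown, MIE"`
#'   stub used when an AOP's initiating event is not characterised) are
#'   removed together with their incident edges and recorded in
#'   `dropped_nodes`.
#'
#' Nodes left isolated by the rules are retained (they still appear in
#' sharing statistics, with degree 0) and logged. Every applied rule is
#' appended to `build_log` so the derivation is auditable row by row. The
#' build is deterministic: nodes and edges are stored in a fixed,
#' locale-independent order.
#'
#' @param x a validated [aop_collection()].
#' @param drop_titles canonical titles to remove after merging.
#' @param nonadjacent_policy `"reconcile"`, `"keep_flagged"` or `"exclude"`.
#' @param validate run [validate_collection()] first and refuse to build on
#'   findings (default). Disable only for ad-hoc graphs built in code.
#' @return an object of class `aop_network` with fields `nodes`, `edges`,
#'   `dropped_nodes`, `build_log`, `aop_ids`, `aop_titles`.
#' @export
build_network <- function(x, drop_titles = "Unknown, MIE",
                          nonadjacent_policy = c("reconcile", "keep_flagged", "exclude"),
                          validate = TRUE) {
  stopifnot(inherits(x, "aop_collection"))
  nonadjacent_policy <- match.arg(nonadjacent_policy)
  if (nrow(x$kers) == 0) abort("Cannot build a network from an empty collection")

  loops <- which(x$kers$upstream_title == x$kers$downstream_title)
  if (length(loops) > 0) {
    abort(sprintf(
      "Self-loop relationship at node %s (AOP %d); harmonisation must not collapse a KER's endpoints",
      dQuote(x$kers$upstream_title[[loops[1]]], FALSE),
      x$kers$aop_id[[loops[1]]]
    ))
  }
  if (validate) {
    report <- validate_collection(x)
    if (nrow(report) > 0) {
      abort(paste0(
        "Collection is not build-ready; validate_collection() reports:\n",
        paste(sprintf("  [%s] AOP %s: %s", report$finding,
                      ifelse(is.na(report$aop_id), "-", report$aop_id),
                      report$detail), collapse = "\n")
      ))
    }
  }

  log <- character(0)
  note <- function(msg) log <<- c(log, msg)
  drop_titles <- normalise_title(drop_titles)

  k <- x$kers
  if (nonadjacent_policy == "exclude") {
    n_drop <- sum(k$adjacency == "nonadjacent")
    if (n_drop > 0) {
      note(sprintf("excluded %d nonadjacent KER row(s) before collapsing", n_drop))
    }
    k <- k[k$adjacency == "adjacent", , drop = FALSE]
  }

  edges <- k |>
    group_by(upstream = .data$upstream_title, downstream = .data$downstream_title) |>
    summarise(
      aop_ids = list(sort(unique(.data$aop_id))),
      # per-AOP evidence first: the collapsed `woe` column would mask the raw
      # one inside later summarise() expressions
      woe_by_aop = list(
        vapply(split(.data$woe, .data$aop_id), merge_woe, character(1))
      ),
      woe = merge_woe(.data$woe),
      n_adjacent = sum(.data$adjacency == "adjacent"),
      n_nonadjacent = sum(.data$adjacency == "nonadjacent"),
      adj_aops = list(sort(unique(.data$aop_id[.data$adjacency == "adjacent"]))),
      nonadj_aops = list(sort(unique(.data$aop_id[.data$adjacency == "nonadjacent"]))),
      .groups = "drop"
    )

  edges$adjacency <- vapply(seq_len(nrow(edges)), function(i) {
    has_adj <- edges$n_adjacent[[i]] > 0
    has_non <- edges$n_nonadjacent[[i]] > 0
    switch(nonadjacent_policy,
      reconcile = if (has_adj) "adjacent" else "nonadjacent",
      keep_flagged = if (has_non) "nonadjacent" else "adjacent",
      exclude = "adjacent"
    )
  }, character(1))
  reconciled <- which(edges$n_adjacent > 0 & edges$n_nonadjacent > 0)
  if (nonadjacent_policy == "reconcile") {
    for (i in reconciled) {
      note(sprintf(
        "reconciled %s -> %s as adjacent (nonadjacent in AOP %s; adjacent in AOP %s)",
        edges$upstream[[i]], edges$downstream[[i]],
        paste(edges$nonadj_aops[[i]], collapse = ","),
        paste(edges$adj_aops[[i]], collapse = ",")
      ))
    }
  }
  multi <- which(lengths(edges$aop_ids) > 1)
  for (i in multi) {
    note(sprintf(
      "collapsed %s -> %s across AOP %s (merged WoE: %s)",
      edges$upstream[[i]], edges$downstream[[i]],
      paste(edges$aop_ids[[i]], collapse = ","), edges$woe[[i]]
    ))
  }
  edges <- edges[, c("upstream", "downstream", "adjacency", "woe",
                     "aop_ids", "woe_by_aop")]

  ke <- key_events(x)
  nodes <- tibble(
    canonical_title = ke$canonical_title,
    roles = ke$roles,
    aliases = ke$aliases,
    aop_ids = ke$aop_ids,
    aop_count = ke$n_aops
  )
  nodes$is_mie <- vapply(nodes$roles, function(r) any(grepl("MIE", r)), logical(1))
  nodes$is_ao <- vapply(nodes$roles, function(r) any(grepl("AO", r)), logical(1))

  dropped <- intersect(drop_titles, nodes$canonical_title)
  if (length(dropped) > 0) {
    n_inc <- sum(edges$upstream %in% dropped | edges$downstream %in% dropped)
    note(sprintf(
      "dropped node(s) %s with %d incident edge(s)",
      paste(dQuote(dropped, FALSE), collapse = ", "), n_inc
    ))
    nodes <- nodes[!nodes$canonical_title %in% dropped, , drop = FALSE]
    edges <- edges[!(edges$upstream %in% dropped | edges$downstream %in% dropped), ,
                   drop = FALSE]
  }

  isolated <- setdiff(nodes$canonical_title, c(edges$upstream, edges$downstream))
  for (t in isolated) {
    note(sprintf("retained isolated node %s (no remaining edges)", dQuote(t, FALSE)))
  }

  nodes <- nodes[order_c(nodes$canonical_title), ]
  edges <- edges[order_c(edges$upstream, edges$downstream), ]

  recs <- aop_records(x)
  structure(
    list(
      nodes = nodes,
      edges = edges,
      dropped_nodes = sort_c(dropped),
      build_log = log,
      aop_ids = sort(unique(x$kers$aop_id)),
      aop_titles = stats::setNames(recs$title, recs$aop_id)
    ),
    class = "aop_network"
  )
}

#' @export
print.aop_network <- function(x, ...) {
  cat(sprintf(
    "<aop_network> %d node(s), %d edge(s), merged from %d AOP(s)%s\n",
    nrow(x$nodes), nrow(x$edges), length(x$aop_ids),
    if (length(x$dropped_nodes) > 0) {
      sprintf(" [dropped: %s]", paste(x$dropped_nodes, collapse = ", "))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Convert an AOP network to an igraph graph
#'
#' Vertex attributes: `name` (canonical title), `roles` (per-AOP roles
#' collapsed to a string), `aop_count`, `aop_ids`. Edge attributes: `woe`,
#' `adjacency`, `aop_ids` (comma-joined).
#'
#' @param net an [build_network()] result.
#' @return an igraph directed graph.
#' @export
as_igraph_network <- function(net) {
  stopifnot(inherits(net, "aop_network"))
  vertices <- data.frame(
    name = net$nodes$canonical_title,
    roles = vapply(seq_len(nrow(net$nodes)), function(i) {
      r <- net$nodes$roles[[i]]
      paste(sprintf("%s:%s", names(r), r), collapse = ";")
    }, character(1)),
    aop_count = net$nodes$aop_count,
    aop_ids = vapply(net$nodes$aop_ids, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    from = net$edges$upstream,
    to = net$edges$downstream,
    woe = net$edges$woe,
    adjacency = net$edges$adjacency,
    aop_ids = vapply(net$edges$aop_ids, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' Extract the subnetwork contributed by one AOP
#'
#' Induces the subgraph of edges whose provenance contains `aop_id` (and the
#' nodes belonging to that AOP). For a linear source AOP the result is its
#' original chain. The union of all per-AOP subnetworks reconstructs the full
#' edge set.
#'
#' @param net an [build_network()] result.
#' @param aop_id an AOP id present in the network's provenance.
#' @return an `aop_network`.
#' @export
subnetwork_for_aop <- function(net, aop_id) {
  stopifnot(inherits(net, "aop_network"))
  aop_id <- as.integer(aop_id)
  if (!aop_id %in% net$aop_ids) {
    abort(sprintf("AOP id %d is not present in this network", aop_id))
  }
  keep_edge <- vapply(net$edges$aop_ids, function(ids) aop_id %in% ids, logical(1))
  keep_node <- vapply(net$nodes$aop_ids, function(ids) aop_id %in% ids, logical(1))
  out <- net
  out$edges <- net$edges[keep_edge, , drop = FALSE]
  out$nodes <- net$nodes[keep_node, , drop = FALSE]
  out$aop_ids <- aop_id
  out$aop_titles <- net$aop_titles[as.character(aop_id)]
  out$build_log <- c(net$build_log, sprintf("induced subnetwork for AOP %d", aop_id))
  out
}

#' Annotation-driven MIE and AO sets of a network
#'
#' Returns the molecular-initiating-event and adverse-outcome node sets used
#' as path-enumeration endpoints. Membership is taken from the curated role
#' annotations, never inferred from degree: an event recorded as the MIE of
#' one AOP keeps that status even when other AOPs give it upstream causes
#' (cytotoxicity is the canonical example), and an AO may have outgoing edges
#' when another AOP treats it as an intermediate event.
#'
#' @param net an [build_network()] result.
#' @return a list with character vectors `mie_set` and `ao_set`.
#' @export
sources_and_sinks <- function(net) {
  stopifnot(inherits(net, "aop_network"))
  mie_set <- net$nodes$canonical_title[net$nodes$is_mie]
  ao_set <- net$nodes$canonical_title[net$nodes$is_ao]
  if (length(mie_set) == 0) abort("Network has no node annotated as MIE; cannot enumerate paths")
  if (length(ao_set) == 0) abort("Network has no node annotated as AO; cannot enumerate paths")
  list(mie_set = sort_c(mie_set), ao_set = sort_c(ao_set))
}
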