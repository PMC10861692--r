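#' GraphML export / import
#'
#' Writes the network for use in Cytoscape or any GraphML consumer. Node
#' attributes: canonical title (`name`), per-AOP roles collapsed to a string,
#' `aop_count`, contributing `aop_ids` (comma-joined). Edge attributes:
#' `woe`, `adjacency`, `aop_ids`. Re-importing with [read_graphml_network()]
#' reconstructs an identical network (alias sets and the per-AOP WoE
#' provenance are carried only by the JSON export, and the build log only
#' describes the original derivation).
#'
#' @param net an [build_network()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph_network(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

parse_id_csv <- function(x) lapply(strsplit(x, ","), function(v) as.integer(v[nzchar(v)]))

#' @rdname write_graphml
#' @export
read_graphml_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  roles <- lapply(igraph::V(g)$roles, function(r) {
    parts <- strsplit(strsplit(r, ";")[[1]], ":", fixed = TRUE)
    stats::setNames(
      vapply(parts, `[[`, character(1), 2),
      vapply(parts, `[[`, character(1), 1)
    )
  })
  nodes <- tibble(
    canonical_title = igraph::V(g)$name,
    roles = roles,
    aliases = lapply(igraph::V(g)$name, identity),
    aop_ids = parse_id_csv(igraph::V(g)$aop_ids),
    aop_count = as.integer(igraph::V(g)$aop_count)
  )
  nodes$is_mie <- vapply(nodes$roles, function(r) any(grepl("MIE", r)), logical(1))
  nodes$is_ao <- vapply(nodes$roles, function(r) any(grepl("AO", r)), logical(1))
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble(
    upstream = el$from, downstream = el$to,
    adjacency = el$adjacency, woe = el$woe,
    aop_ids = parse_id_csv(el$aop_ids),
    woe_by_aop = lapply(seq_len(nrow(el)), function(i) character(0))
  )
  nodes <- nodes[order_c(nodes$canonical_title), ]
  edges <- edges[order_c(edges$upstream, edges$downstream), ]
  structure(
    list(
      nodes = nodes, edges = edges,
      dropped_nodes = character(0),
      build_log = sprintf("imported from GraphML: %s", basename(path)),
      aop_ids = sort(unique(unlist(nodes$aop_ids))),
      aop_titles = character(0)
    ),
    class = "aop_network"
  )
}

#' SIF export (Cytoscape simple interaction format)
#'
#' Three tab-separated columns: upstream title, the literal interaction type
#' `KER`, downstream title.
#'
#' @param net an [build_network()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "aop_network"))
  lines <- sprintf("%s\tKER\t%s", net$edges$upstream, net$edges$downstream)
  writeLines(lines, path)
  invisible(path)
}

#' Full-fidelity JSON export / import of a network
#'
#' Mirrors the complete network object: nodes with roles, aliases and AOP
#' memberships, collapsed edges with per-AOP WoE provenance, dropped nodes,
#' the build log and the AOP inventory. `read_network_json()` reconstructs an
#' equal network.
#'
#' @param net an [build_network()] result.
#' @param path output path.
#' @return `path` (write) or an `aop_network` (read).
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "aop_network"))
  doc <- list(
    nodes = lapply(seq_len(nrow(net$nodes)), function(i) list(
      canonical_title = net$nodes$canonical_title[[i]],
      roles = as.list(net$nodes$roles[[i]]),
      aliases = net$nodes$aliases[[i]],
      aop_ids = net$nodes$aop_ids[[i]],
      aop_count = net$nodes$aop_count[[i]]
    )),
    edges = lapply(seq_len(nrow(net$edges)), function(i) list(
      upstream = net$edges$upstream[[i]],
      downstream = net$edges$downstream[[i]],
      adjacency = net$edges$adjacency[[i]],
      woe = net$edges$woe[[i]],
      aop_ids = net$edges$aop_ids[[i]],
      woe_by_aop = as.list(net$edges$woe_by_aop[[i]])
    )),
    dropped_nodes = net$dropped_nodes,
    build_log = net$build_log,
    aop_ids = net$aop_ids,
    aop_titles = as.list(net$aop_titles)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "list",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_chr <- function(x) {
    out <- as.character(unlist(x))
    names(out) <- names(x)
    out
  }
  nodes <- tibble(
    canonical_title = vapply(doc$nodes, `[[`, character(1), "canonical_title"),
    roles = lapply(doc$nodes, function(n) {
      stats::setNames(as_chr(n$roles), names(n$roles))
    }),
    aliases = lapply(doc$nodes, function(n) as_chr(n$aliases)),
    aop_ids = lapply(doc$nodes, function(n) as.integer(unlist(n$aop_ids))),
    aop_count = vapply(doc$nodes, function(n) as.integer(n$aop_count), integer(1))
  )
  nodes$is_mie <- vapply(nodes$roles, function(r) any(grepl("MIE", r)), logical(1))
  nodes$is_ao <- vapply(nodes$roles, function(r) any(grepl("AO", r)), logical(1))
  edges <- tibble(
    upstream = vapply(doc$edges, `[[`, character(1), "upstream"),
    downstream = vapply(doc$edges, `[[`, character(1), "downstream"),
    adjacency = vapply(doc$edges, `[[`, character(1), "adjacency"),
    woe = vapply(doc$edges, `[[`, character(1), "woe"),
    aop_ids = lapply(doc$edges, function(e) as.integer(unlist(e$aop_ids))),
    woe_by_aop = lapply(doc$edges, function(e) {
      stats::setNames(as_chr(e$woe_by_aop), names(e$woe_by_aop))
    })
  )
  structure(
    list(
      nodes = nodes[order_c(nodes$canonical_title), ],
      edges = edges[order_c(edges$upstream, edges$downstream), ],
      dropped_nodes = as.character(unlist(doc$dropped_nodes)),
      build_log = as.character(unlist(doc$build_log)),
      aop_ids = as.integer(unlist(doc$aop_ids)),
      aop_titles = stats::setNames(as_chr(doc$aop_titles), names(doc$aop_titles))
    ),
    class = "aop_network"
  )
}

#' Write the node-metrics table
#'
#' TSV for reports (occurrence and betweenness rounded to 3 decimals, the
#' precision at which these scores are conventionally reported) or JSON at
#' full precision.
#'
#' @param metrics the `metrics` tibble of [summarise_network()].
#' @param path output path; format chosen by extension (`.json` or TSV).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(metrics, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    out <- metrics
    out$betweenness <- round_half_away(out$betweenness, 3)
    out$path_occurrence <- round_half_away(out$path_occurrence, 3)
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Write the network summary as JSON
#'
#' @param summary the `summary` list of [summarise_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  summary$woe_distribution <- as.data.frame(summary$woe_distribution)
  jsonlite::write_json(summary, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write the convergent/divergent key-event lists as Markdown
#'
#' @param metrics the `metrics` tibble of [summarise_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_convergence_md <- function(metrics, path) {
  fmt <- function(class) {
    rows <- metrics[metrics$convergence_class == class, ]
    rows <- rows[order_c(-rows$degree, rows$node), ]
    if (nrow(rows) == 0) return("(none)")
    sprintf("| %s | %d | %d |", rows$node, rows$in_degree, rows$out_degree)
  }
  lines <- c(
    sprintf("## Convergent key events (%d)",
            sum(metrics$convergence_class == "convergent")),
    "", "| Key event | In-degree | Out-degree |", "| --- | --- | --- |",
    fmt("convergent"), "",
    sprintf("## Divergent key events (%d)",
            sum(metrics$convergence_class == "divergent")),
    "", "| Key event | In-degree | Out-degree |", "| --- | --- | --- |",
    fmt("divergent"), ""
  )
  writeLines(lines, path)
  invisible(path)
}
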