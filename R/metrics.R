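#' Node degrees over the collapsed directed edge set
#'
#' @param net an [build_network()] result.
#' @return a tibble with columns `node`, `in_degree`, `out_degree`, `degree`,
#'   one row per node (isolated nodes included with zeros), ordered by title.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "aop_network"))
  titles <- net$nodes$canonical_title
  indeg <- table(factor(net$edges$downstream, levels = titles))
  outdeg <- table(factor(net$edges$upstream, levels = titles))
  tibble(
    node = titles,
    in_degree = as.integer(indeg),
    out_degree = as.integer(outdeg),
    degree = as.integer(indeg) + as.integer(outdeg)
  )
}

#' Classify nodes as convergent, divergent or balanced
#'
#' Convergent key events have more incoming than outgoing relationships
#' (pathways meet there); divergent key events have more outgoing than
#' incoming (fork points); nodes with equal counts — including isolated
#' nodes — are balanced and belong to neither list.
#'
#' @param degrees output of [node_degrees()].
#' @return the input tibble with an added `convergence_class` column.
#' @export
classify_convergence <- function(degrees) {
  degrees$convergence_class <- dplyr::case_when(
    degrees$in_degree > degrees$out_degree ~ "convergent",
    degrees$out_degree > degrees$in_degree ~ "divergent",
    TRUE ~ "balanced"
  )
  degrees
}

#' Directed eccentricity
#'
#' For the default `orientation = "incoming"`, the eccentricity of a node `v`
#' is the longest shortest directed path (in hops) from any node that can
#' reach `v`; nodes with no ancestors score 0. Low values therefore mark net
#' upstream positions (initiating events) and high values net downstream
#' positions (outcomes). Unreachable pairs are ignored — the maximum is taken
#' over finite distances only, so disconnected components never produce
#' infinities. `orientation = "outgoing"` measures instead how far a node can
#' reach, for sensitivity analysis.
#'
#' @param net an [build_network()] result.
#' @param orientation `"incoming"` (default) or `"outgoing"`.
#' @return a named integer vector of eccentricities, ordered by title.
#' @export
directed_eccentricity <- function(net, orientation = c("incoming", "outgoing")) {
  orientation <- match.arg(orientation)
  g <- as_igraph_network(net)
  mode <- if (orientation == "incoming") "in" else "out"
  # distances(mode = "in")[v, u] = length of shortest directed path u -> v
  d <- igraph::distances(g, mode = mode)
  diag(d) <- Inf
  ecc <- apply(d, 1, function(row) {
    finite <- row[is.finite(row)]
    if (length(finite) == 0) 0L else as.integer(max(finite))
  })
  ecc[order_c(names(ecc))]
}

#' Band eccentricities into upstream / middle / downstream
#'
#' Nodes with eccentricity below 3 occupy net upstream positions, above 6 net
#' downstream positions; the rest (3–6) are too interconnected to classify.
#'
#' @param ecc named vector from [directed_eccentricity()].
#' @return a named character vector with values `"upstream"`, `"middle"`,
#'   `"downstream"`.
#' @export
band_eccentricity <- function(ecc) {
  out <- ifelse(ecc < 3, "upstream", ifelse(ecc > 6, "downstream", "middle"))
  stats::setNames(out, names(ecc))
}

#' Normalised directed betweenness centrality
#'
#' Standard shortest-path betweenness on the collapsed directed graph,
#' normalised by `(n-1)(n-2)` so scores lie in \[0, 1\]; path endpoints are
#' not counted as interior. Computed with igraph.
#'
#' @param net an [build_network()] result.
#' @return a named numeric vector, ordered by title.
#' @export
node_betweenness <- function(net) {
  stopifnot(inherits(net, "aop_network"))
  g <- as_igraph_network(net)
  n <- igraph::vcount(g)
  if (n < 3) {
    b <- stats::setNames(rep(0, n), igraph::V(g)$name)
  } else {
    b <- igraph::betweenness(g, directed = TRUE, normalized = TRUE)
  }
  b[order_c(names(b))]
}

#' AOP-sharing count per key event
#'
#' How many of the source AOPs report each key event; the histogram over
#' counts summarises the interconnectivity of the collection (a tall bar at 1
#' means most events belong to a single pathway).
#'
#' @param net an [build_network()] result.
#' @return a list with `counts` (tibble `node`, `aop_share_count`) and
#'   `share_histogram` (named integer vector over observed counts
#'   `1..max`).
#' @export
ke_sharing <- function(net) {
  stopifnot(inherits(net, "aop_network"))
  counts <- tibble(
    node = net$nodes$canonical_title,
    aop_share_count = net$nodes$aop_count
  )
  breaks <- seq_len(max(c(counts$aop_share_count, 1)))
  hist <- table(factor(counts$aop_share_count, levels = breaks))
  list(
    counts = counts,
    share_histogram = stats::setNames(as.integer(hist), breaks)
  )
}

#' Weight-of-evidence distribution over collapsed edges
#'
#' Percentage of network edges at each qualitative evidence level, using the
#' merged (highest-contributor) level per collapsed edge. Percentages are
#' rounded half away from zero to integers; because of rounding they may not
#' sum to exactly 100, which is flagged, and the raw fractions are returned
#' alongside.
#'
#' @param net an [build_network()] result.
#' @return a tibble with columns `woe`, `n_edges`, `fraction`, `pct` and an
#'   attribute `sums_to_100` (logical).
#' @export
woe_distribution <- function(net) {
  stopifnot(inherits(net, "aop_network"))
  n <- nrow(net$edges)
  if (n == 0) abort("Network has no edges; WoE distribution is undefined")
  counts <- table(factor(net$edges$woe, levels = WOE_LEVELS))
  out <- tibble(
    woe = WOE_LEVELS,
    n_edges = as.integer(counts),
    fraction = as.integer(counts) / n
  )
  out$pct <- round_half_away(100 * out$fraction)
  attr(out, "sums_to_100") <- sum(out$pct) == 100
  out
}
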