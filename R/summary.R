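#' Full node-metrics table and network summary
#'
#' Computes every node-level statistic in one call — degree triple with
#' convergence class, directed eccentricity with upstream/middle/downstream
#' band, normalised betweenness, normalised MIE-to-AO simple-path occurrence,
#' and AOP-sharing count — plus the network-level summary: convergence
#' counts, sharing histogram, eccentricity-band percentages, in/out-degree
#' histograms (with percentages over both all nodes and nodes of nonzero
#' respective degree, since either denominator is defensible), and the
#' weight-of-evidence distribution.
#'
#' The metrics table is ranked by path occurrence (descending), then degree
#' (descending), then title — a deterministic order for reports.
#'
#' @param net an [build_network()] result.
#' @param orientation eccentricity orientation, see [directed_eccentricity()].
#' @param max_paths guard for [enumerate_mie_ao_paths()].
#' @return a list of class `aop_summary` with elements `metrics` (tibble, one
#'   row per node) and `summary` (named list).
#' @export
summarise_network <- function(net, orientation = "incoming", max_paths = 1e6) {
  stopifnot(inherits(net, "aop_network"))
  deg <- classify_convergence(node_degrees(net))
  ecc <- directed_eccentricity(net, orientation = orientation)
  bands <- band_eccentricity(ecc)
  btw <- node_betweenness(net)
  paths <- enumerate_mie_ao_paths(net, max_paths = max_paths)
  occ <- path_occurrence(paths, net$nodes$canonical_title)
  sharing <- ke_sharing(net)
  woe <- woe_distribution(net)

  metrics <- deg |>
    mutate(
      eccentricity = unname(ecc[.data$node]),
      eccentricity_band = unname(bands[.data$node]),
      betweenness = unname(btw[.data$node]),
      path_occurrence = unname(occ[.data$node]),
      aop_share_count = sharing$counts$aop_share_count[
        match(.data$node, sharing$counts$node)
      ]
    ) |>
    select(
      "node", "degree", "in_degree", "out_degree", "eccentricity",
      "eccentricity_band", "betweenness", "path_occurrence",
      "convergence_class", "aop_share_count"
    )
  metrics <- metrics[order_c(-metrics$path_occurrence, -metrics$degree,
                             metrics$node), ]

  n_nodes <- nrow(net$nodes)
  band_counts <- table(factor(bands, levels = c("upstream", "middle", "downstream")))
  deg_hist <- function(d) {
    lv <- 0:max(c(d, 0))
    stats::setNames(as.integer(table(factor(d, levels = lv))), lv)
  }
  in_hist <- deg_hist(metrics$in_degree)
  out_hist <- deg_hist(metrics$out_degree)
  pct_over <- function(hist, denom) {
    if (denom == 0) return(stats::setNames(numeric(length(hist)), names(hist)))
    stats::setNames(round_half_away(100 * hist / denom), names(hist))
  }

  summary <- list(
    n_nodes = n_nodes,
    n_edges = nrow(net$edges),
    n_aops = length(net$aop_ids),
    n_paths = length(paths),
    n_convergent = sum(metrics$convergence_class == "convergent"),
    n_divergent = sum(metrics$convergence_class == "divergent"),
    n_balanced = sum(metrics$convergence_class == "balanced"),
    max_degree = max(c(metrics$degree, 0)),
    share_histogram = sharing$share_histogram,
    pct_single_aop = round_half_away(
      100 * sum(metrics$aop_share_count == 1) / n_nodes
    ),
    ecc_band_counts = stats::setNames(as.integer(band_counts), names(band_counts)),
    ecc_band_fractions = stats::setNames(
      round_half_away(100 * as.integer(band_counts) / n_nodes),
      names(band_counts)
    ),
    indegree_histogram = in_hist,
    outdegree_histogram = out_hist,
    indegree_pct_all = pct_over(in_hist, n_nodes),
    indegree_pct_nonzero = pct_over(
      in_hist[names(in_hist) != "0"], sum(metrics$in_degree > 0)
    ),
    outdegree_pct_all = pct_over(out_hist, n_nodes),
    outdegree_pct_nonzero = pct_over(
      out_hist[names(out_hist) != "0"], sum(metrics$out_degree > 0)
    ),
    woe_distribution = woe,
    dropped_nodes = net$dropped_nodes
  )
  structure(
    list(metrics = metrics, summary = summary, paths = paths),
    class = "aop_summary"
  )
}

#' @export
print.aop_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<aop_summary> %d nodes, %d edges, %d MIE->AO simple paths\n",
      "  convergent %d | divergent %d | balanced %d; max degree %d\n",
      "  single-AOP KEs: %d%%; eccentricity bands (up/mid/down): %d%%/%d%%/%d%%\n"
    ),
    s$n_nodes, s$n_edges, s$n_paths,
    s$n_convergent, s$n_divergent, s$n_balanced, s$max_degree,
    s$pct_single_aop,
    s$ecc_band_fractions[["upstream"]], s$ecc_band_fractions[["middle"]],
    s$ecc_band_fractions[["downstream"]]
  ))
  invisible(x)
}
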