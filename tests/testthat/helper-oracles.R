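# Independent brute-force oracles, kept deliberately separate from the
# package's implementations.

path_key <- function(p) paste(p, collapse = "\r")

# All simple directed paths with >= 1 edge from any source to any sink,
# via igraph's own enumerator.
oracle_simple_paths <- function(net, sources, sinks) {
  g <- as_igraph_network(net)
  out <- character(0)
  for (s in intersect(sources, igraph::V(g)$name)) {
    ps <- igraph::all_simple_paths(g, from = s, to = igraph::V(g), mode = "out")
    for (p in ps) {
      nm <- names(p)
      if (length(nm) >= 2 && nm[length(nm)] %in% sinks) {
        out <- c(out, path_key(nm))
      }
    }
  }
  sort(out)
}

# Normalised directed betweenness from first principles: BFS distances,
# shortest-path counts, then the pair-dependency formula
#   B(v) = sum_{s!=v!=t} sigma_sv * sigma_vt / sigma_st  [d(s,v)+d(v,t)=d(s,t)]
oracle_betweenness <- function(net) {
  nodes <- net$nodes$canonical_title
  from <- net$edges$upstream
  to <- net$edges$downstream
  n <- length(nodes)
  adj_out <- lapply(stats::setNames(nm = nodes), function(v) to[from == v])
  adj_in <- lapply(stats::setNames(nm = nodes), function(v) from[to == v])
  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (s in nodes) {
    dist[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(adj_out[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(dist[s, nxt])]
      if (length(nxt) > 0) dist[s, nxt] <- d
      frontier <- nxt
    }
  }
  sigma <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (s in nodes) {
    sigma[s, s] <- 1
    for (t in nodes[order(dist[s, nodes])]) {
      if (t == s || is.infinite(dist[s, t])) next
      preds <- adj_in[[t]]
      preds <- preds[dist[s, preds] == dist[s, t] - 1]
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  b <- stats::setNames(numeric(n), nodes)
  for (s in nodes) {
    for (t in nodes) {
      if (s == t || is.infinite(dist[s, t])) next
      for (v in nodes) {
        if (v == s || v == t) next
        if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
            dist[s, v] + dist[v, t] == dist[s, t]) {
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  if (n > 2) b / ((n - 1) * (n - 2)) else b * 0
}

# Edge sets of every labelled digraph on n nodes (no self-loops), as a list
# of from/to pairs indexed by a bitmask over the n*(n-1) ordered pairs.
digraph_pairs <- function(n) {
  nodes <- LETTERS[seq_len(n)]
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs[pairs$from != pairs$to, ]
}

digraph_from_mask <- function(pairs, mask_bits) {
  pairs[mask_bits, , drop = FALSE]
}

# Random digraph edge set (at least one edge).
random_digraph <- function(n, p) {
  pairs <- digraph_pairs(n)
  repeat {
    keep <- stats::runif(nrow(pairs)) < p
    if (any(keep)) return(pairs[keep, , drop = FALSE])
  }
}
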