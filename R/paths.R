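#' Enumerate all simple MIE-to-AO paths
#'
#' Depth-first enumeration of every simple directed path (no node revisited)
#' from any annotated molecular initiating event to any annotated adverse
#' outcome. Because revisits are forbidden, enumeration terminates on graphs
#' with feedback loops. A path is emitted whenever an AO is reached, so
#' routes extending beyond an AO with outgoing edges yield both the shorter
#' and the longer path. Single-node "paths" (a node annotated as both MIE and
#' AO) are not emitted: a zero-length path carries no relationship.
#'
#' Emission order is deterministic and lexicographic in the node sequence
#' (start nodes and neighbours are explored in locale-independent sorted
#' order).
#'
#' Simple-path counts are worst-case exponential in the number of nodes; the
#' `max_paths` guard aborts enumeration with a resource error rather than
#' exhausting memory on pathological graphs.
#'
#' @param net an [build_network()] result.
#' @param mie_set,ao_set character vectors of endpoint titles; default to the
#'   annotation-driven sets from [sources_and_sinks()].
#' @param max_paths guard on the number of emitted paths (default 1e6).
#' @return a list of character vectors (node sequences), with attributes
#'   `mie_set` and `ao_set`.
#' @export
enumerate_mie_ao_paths <- function(net, mie_set = NULL, ao_set = NULL,
                                   max_paths = 1e6) {
  stopifnot(inherits(net, "aop_network"))
  if (is.null(mie_set) || is.null(ao_set)) {
    ss <- sources_and_sinks(net)
    mie_set <- mie_set %||% ss$mie_set
    ao_set <- ao_set %||% ss$ao_set
  }
  titles <- net$nodes$canonical_title
  mie_set <- sort_c(intersect(normalise_title(mie_set), titles))
  ao_set <- sort_c(intersect(normalise_title(ao_set), titles))
  if (length(mie_set) == 0) abort("mie_set contains no node of the network")
  if (length(ao_set) == 0) abort("ao_set contains no node of the network")

  adj <- lapply(
    stats::setNames(nm = titles),
    function(v) sort_c(net$edges$downstream[net$edges$upstream == v])
  )
  is_ao <- stats::setNames(titles %in% ao_set, titles)

  paths <- vector("list", 256)
  n_paths <- 0L
  emit <- function(path) {
    n_paths <<- n_paths + 1L
    if (n_paths > max_paths) {
      abort(
        sprintf(
          "More than %g simple MIE->AO paths; raise max_paths if enumeration of this graph is really intended",
          max_paths
        ),
        class = "aopnet_path_guard"
      )
    }
    if (n_paths > length(paths)) length(paths) <<- 2L * n_paths
    paths[[n_paths]] <<- path
  }
  visit <- function(v, path, on_path) {
    path <- c(path, v)
    on_path[[v]] <- TRUE
    if (is_ao[[v]] && length(path) >= 2) emit(path)
    for (w in adj[[v]]) {
      if (!on_path[[w]]) visit(w, path, on_path)
    }
  }
  blank <- stats::setNames(rep(FALSE, length(titles)), titles)
  for (s in mie_set) visit(s, character(0), blank)

  out <- paths[seq_len(n_paths)]
  attr(out, "mie_set") <- mie_set
  attr(out, "ao_set") <- ao_set
  out
}

#' Normalised simple-path occurrence
#'
#' The fraction of all enumerated MIE-to-AO simple paths that pass through
#' each node — an adaptation of betweenness centrality restricted to the
#' toxicologically meaningful routes from initiating events to outcomes. A
#' node lying on every path scores exactly 1; nodes on no path (including
#' isolated nodes) score 0. Path endpoints count as contained.
#'
#' @param paths the list returned by [enumerate_mie_ao_paths()].
#' @param nodes character vector of node titles to score (typically the
#'   network's node set).
#' @return a named numeric vector in \[0, 1\], ordered by title.
#' @export
path_occurrence <- function(paths, nodes) {
  if (length(paths) == 0) {
    abort("No MIE->AO paths were enumerated; occurrence is undefined (empty normalisation)")
  }
  nodes <- sort_c(unique(nodes))
  counts <- table(factor(unlist(paths), levels = nodes))
  stats::setNames(as.numeric(counts) / length(paths), nodes)
}
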