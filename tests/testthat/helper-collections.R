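# Small collections built in code.

mk_coll <- function(aop_id, up, dn, utype = "KE", dtype = "KE",
                    adjacency = "adjacent", woe = "unspecified") {
  aop_collection(tibble::tibble(
    aop_id = aop_id,
    upstream_title = up, upstream_type = utype,
    downstream_title = dn, downstream_type = dtype,
    adjacency = adjacency, woe = woe
  ))
}

# A linear pathway MIE -> KE* -> AO over the given titles.
chain_coll <- function(titles, aop_id = 1L, adjacency = "adjacent",
                       woe = "unspecified") {
  n <- length(titles)
  stopifnot(n >= 2)
  role <- function(i) if (i == 1) "MIE" else if (i == n) "AO" else "KE"
  mk_coll(
    aop_id = rep(aop_id, n - 1),
    up = titles[-n], dn = titles[-1],
    utype = vapply(seq_len(n - 1), role, character(1)),
    dtype = vapply(2:n, role, character(1)),
    adjacency = adjacency, woe = woe
  )
}

# M -> A -> Z, M -> B -> Z as two single-AOP branches.
diamond_coll <- function() {
  aop_collection(tibble::tibble(
    aop_id = c(1L, 1L, 2L, 2L),
    upstream_title = c("M", "A", "M", "B"),
    upstream_type = c("MIE", "KE", "MIE", "KE"),
    downstream_title = c("A", "Z", "B", "Z"),
    downstream_type = c("KE", "AO", "KE", "AO"),
    adjacency = "adjacent", woe = "unspecified"
  ))
}

# Two titles with no relationship between them in either direction, so
# pooling them cannot create a self-loop.
find_nonedge_pair <- function(x) {
  titles <- unique(c(x$kers$upstream_title, x$kers$downstream_title))
  pairs <- paste(x$kers$upstream_title, x$kers$downstream_title)
  for (a in titles) {
    for (b in setdiff(titles, a)) {
      if (!any(c(paste(a, b), paste(b, a)) %in% pairs)) return(c(a, b))
    }
  }
  stop("no non-adjacent title pair found")
}

# Arbitrary digraph as a roles-free network (for metric/oracle tests).
edges_net <- function(from, to) {
  build_network(
    mk_coll(rep(1L, length(from)), from, to),
    drop_titles = character(0), validate = FALSE
  )
}
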