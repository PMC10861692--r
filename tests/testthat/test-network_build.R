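test_that("one linear AOP builds to its own chain: 3 nodes, 2 edges, no drops", {
  net <- build_network(chain_coll(c("M", "K", "A")))
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$dropped_nodes, character(0))
  ss <- sources_and_sinks(net)
  expect_equal(ss$mie_set, "M")
  expect_equal(ss$ao_set, "A")
})

test_that("a KER shared by two AOPs collapses to one edge with both ids", {
  x <- aop_collection(tibble::tibble(
    aop_id = c(1L, 1L, 2L, 2L),
    upstream_title = c("M1", "X", "M2", "X"),
    upstream_type = c("MIE", "KE", "MIE", "KE"),
    downstream_title = c("X", "Y", "X", "Y"),
    downstream_type = c("KE", "AO", "KE", "AO"),
    adjacency = "adjacent", woe = c("low", "low", "high", "medium")
  ))
  net <- build_network(x)
  xy <- net$edges[net$edges$upstream == "X", ]
  expect_equal(nrow(xy), 1)
  expect_equal(xy$aop_ids[[1]], c(1L, 2L))
  # merged WoE is the highest contributor level; per-AOP levels retained
  expect_equal(xy$woe, "medium")
  expect_equal(xy$woe_by_aop[[1]], c(`1` = "low", `2` = "medium"))
})

test_that("nonadjacent flags reconcile against adjacent reports by default", {
  x <- aop_collection(tibble::tibble(
    aop_id = c(1L, 2L),
    upstream_title = "X", upstream_type = "MIE",
    downstream_title = "Y", downstream_type = "AO",
    adjacency = c("nonadjacent", "adjacent"), woe = "unspecified"
  ))
  rec <- build_network(x)
  expect_equal(nrow(rec$edges), 1)
  expect_equal(rec$edges$adjacency, "adjacent")
  expect_equal(rec$edges$aop_ids[[1]], c(1L, 2L))
  expect_true(any(grepl("reconciled", rec$build_log)))

  kept <- build_network(x, nonadjacent_policy = "keep_flagged")
  expect_equal(kept$edges$adjacency, "nonadjacent")

  excl <- build_network(x, nonadjacent_policy = "exclude")
  expect_equal(nrow(excl$edges), 1)
  expect_equal(excl$edges$aop_ids[[1]], 2L)

  # a pair nonadjacent in every contributor keeps its flag under reconcile
  solo <- aop_collection(tibble::tibble(
    aop_id = 1L, upstream_title = c("X", "X"), upstream_type = c("MIE", "MIE"),
    downstream_title = c("Y", "Z"), downstream_type = c("KE", "AO"),
    adjacency = c("nonadjacent", "adjacent"), woe = "unspecified"
  ))
  net <- build_network(solo)
  expect_equal(net$edges$adjacency[net$edges$downstream == "Y"], "nonadjacent")
})

test_that("the Unknown, MIE placeholder is dropped with its incident edges", {
  x <- aop_collection(tibble::tibble(
    aop_id = c(186L, 186L, 186L, 2L, 2L),
    upstream_title = c("Unknown, MIE", "K1", "K2", "M", "K1"),
    upstream_type = c("MIE", "KE", "KE", "MIE", "KE"),
    downstream_title = c("K1", "K2", "Increased mortality", "K1", "Z"),
    downstream_type = c("KE", "KE", "AO", "KE", "AO"),
    adjacency = "adjacent", woe = "unspecified"
  ))
  net <- build_network(x)
  expect_equal(net$dropped_nodes, "Unknown, MIE")
  expect_false("Unknown, MIE" %in% net$nodes$canonical_title)
  expect_false(any(net$edges$upstream == "Unknown, MIE"))
  expect_true(any(grepl("dropped node", net$build_log)))
  # node count = union of titles minus dropped ones present
  all_titles <- unique(c(x$kers$upstream_title, x$kers$downstream_title))
  expect_equal(nrow(net$nodes), length(all_titles) - 1)
})

test_that("nodes isolated by a drop are retained and logged", {
  x <- aop_collection(tibble::tibble(
    aop_id = c(1L, 1L),
    upstream_title = c("M", "Hub"), upstream_type = c("MIE", "KE"),
    downstream_title = c("Hub", "A"), downstream_type = c("KE", "AO"),
    adjacency = "adjacent", woe = "unspecified"
  ))
  net <- build_network(x, drop_titles = "Hub", validate = FALSE)
  expect_setequal(net$nodes$canonical_title, c("A", "M"))
  expect_equal(nrow(net$edges), 0)
  expect_equal(sum(grepl("retained isolated node", net$build_log)), 2)
})

test_that("self-loops and empty collections are build errors", {
  loop <- mk_coll(1L, c("A", "B"), c("B", "B"),
                  utype = c("MIE", "KE"), dtype = c("KE", "AO"))
  expect_error(build_network(loop, validate = FALSE), "Self-loop")
  empty <- aop_collection(tibble::tibble(
    aop_id = integer(0), upstream_title = character(0),
    upstream_type = character(0), downstream_title = character(0),
    downstream_type = character(0), adjacency = character(0),
    woe = character(0)
  ))
  expect_error(build_network(empty), "empty")
  # findings block the build when validation is on
  no_mie <- mk_coll(1L, "A", "B", utype = "KE", dtype = "AO")
  expect_error(build_network(no_mie), "AOP without MIE")
})

test_that("per-AOP subnetworks are the source chains and union to the full edge set", {
  x <- generate_collection(generator_config(seed = 5))
  net <- build_network(x, drop_titles = character(0))

  sub_edges <- lapply(net$aop_ids, function(id) {
    sub <- subnetwork_for_aop(net, id)
    paste(sub$edges$upstream, sub$edges$downstream, sep = "\r")
  })
  expect_setequal(
    unique(unlist(sub_edges)),
    paste(net$edges$upstream, net$edges$downstream, sep = "\r")
  )
  expect_error(subnetwork_for_aop(net, 999L), "not present")

  # a pure chain AOP round-trips to a linear subgraph
  chain <- build_network(chain_coll(c("M", "K1", "K2", "A"), aop_id = 4L))
  sub <- subnetwork_for_aop(chain, 4L)
  expect_equal(sub$edges[, c("upstream", "downstream")],
               chain$edges[, c("upstream", "downstream")])

  # single-AOP collection: its subnetwork is the whole network
  one <- build_network(diamond_coll())
  sub1 <- subnetwork_for_aop(one, 1L)
  expect_equal(sub1$edges$upstream, c("A", "M"))
})

test_that("MIE/AO endpoint sets are annotation-driven, not degree-driven", {
  # cytotoxicity-style node: MIE of AOP 2 yet fed by AOP 1; kidney-failure-style
  # node: AO of AOP 1 with outgoing edges in AOP 3
  x <- aop_collection(tibble::tibble(
    aop_id = c(1L, 1L, 2L, 3L, 3L),
    upstream_title = c("M1", "Cyto", "Cyto", "Fail", "K"),
    upstream_type = c("MIE", "KE", "MIE", "KE", "KE"),
    downstream_title = c("Cyto", "Fail", "Fail", "K", "Z"),
    downstream_type = c("KE", "AO", "AO", "KE", "AO"),
    adjacency = "adjacent", woe = "unspecified"
  ))
  net <- build_network(x, validate = FALSE)
  ss <- sources_and_sinks(net)
  deg <- node_degrees(net)
  expect_true("Cyto" %in% ss$mie_set)
  expect_gt(deg$in_degree[deg$node == "Cyto"], 0)
  expect_true("Fail" %in% ss$ao_set)
  expect_gt(deg$out_degree[deg$node == "Fail"], 0)

  no_ao <- build_network(mk_coll(1L, "A", "B", utype = "MIE", dtype = "KE"),
                         validate = FALSE)
  expect_error(sources_and_sinks(no_ao), "AO")
})

test_that("the build is deterministic and invariant to input row order", {
  x <- generate_collection(generator_config(seed = 13))
  net1 <- build_network(x)
  set.seed(99)
  shuffled <- aop_collection(x$kers[sample(nrow(x$kers)), ])
  net2 <- build_network(shuffled)
  expect_equal(net2$nodes, net1$nodes)
  expect_equal(net2$edges, net1$edges)
  # edge provenance is non-empty and within the input AOP ids
  expect_true(all(lengths(net1$edges$aop_ids) > 0))
  expect_true(all(unlist(net1$edges$aop_ids) %in% net1$aop_ids))
  expect_gte(nrow(x$kers), nrow(net1$edges))
})
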