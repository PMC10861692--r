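test_that("degree triples on chain and diamond match hand counts", {
  chain <- build_network(chain_coll(c("M", "K", "A")))
  d <- node_degrees(chain)
  expect_equal(d[d$node == "M", -1], tibble::tibble(in_degree = 0L, out_degree = 1L, degree = 1L))
  expect_equal(d[d$node == "K", -1], tibble::tibble(in_degree = 1L, out_degree = 1L, degree = 2L))
  expect_equal(d[d$node == "A", -1], tibble::tibble(in_degree = 1L, out_degree = 0L, degree = 1L))

  dia <- node_degrees(build_network(diamond_coll()))
  expect_equal(dia$degree[dia$node %in% c("M", "Z")], c(2L, 2L))
  expect_equal(dia$in_degree[dia$node == "Z"], 2L)
  expect_equal(dia$out_degree[dia$node == "M"], 2L)
  expect_equal(dia$degree[dia$node %in% c("A", "B")], c(2L, 2L))
})

test_that("convergence classification follows the in/out comparison and partitions nodes", {
  dia <- classify_convergence(node_degrees(build_network(diamond_coll())))
  cls <- stats::setNames(dia$convergence_class, dia$node)
  expect_equal(cls[["M"]], "divergent")
  expect_equal(cls[["Z"]], "convergent")
  expect_equal(cls[["A"]], "balanced")
  expect_equal(cls[["B"]], "balanced")

  # glutathione-oxidation pattern: an MIE with one upstream and one downstream
  # link is balanced, not divergent
  x <- aop_collection(tibble::tibble(
    aop_id = c(1L, 1L, 2L),
    upstream_title = c("GSH ox", "ROS", "Thiol binding"),
    upstream_type = c("MIE", "KE", "MIE"),
    downstream_title = c("ROS", "AO1", "GSH ox"),
    downstream_type = c("KE", "AO", "KE"),
    adjacency = "adjacent", woe = "unspecified"
  ))
  net <- build_network(x, validate = FALSE)
  cc <- classify_convergence(node_degrees(net))
  expect_equal(cc$convergence_class[cc$node == "GSH ox"], "balanced")

  for (seed in c(2, 21)) {
    m <- classify_convergence(node_degrees(
      build_network(generate_collection(generator_config(seed = seed)))
    ))
    expect_equal(
      sum(m$convergence_class == "convergent") +
        sum(m$convergence_class == "divergent") +
        sum(m$convergence_class == "balanced"),
      nrow(m)
    )
  }
})

test_that("incoming eccentricity is 0 at sources and the hop depth downstream", {
  chain7 <- build_network(chain_coll(paste0("N", 1:7)))
  ecc <- directed_eccentricity(chain7)
  expect_equal(unname(ecc[paste0("N", 1:7)]), 0:6)
  out <- directed_eccentricity(chain7, orientation = "outgoing")
  expect_equal(unname(out[paste0("N", 1:7)]), 6:0)
})

test_that("eccentricity stays finite on cycles and ignores unreachable pairs", {
  # M -> A -> B -> C -> A: hand-traced shortest incoming distances
  net <- edges_net(c("M", "A", "B", "C"), c("A", "B", "C", "A"))
  ecc <- directed_eccentricity(net)
  expect_equal(ecc, c(A = 2L, B = 2L, C = 3L, M = 0L))

  # two disconnected chains: no infinities, each component banded on its own
  two <- build_network(
    aop_collection(dplyr::bind_rows(
      chain_coll(c("M1", "K1", "A1"), aop_id = 1L)$kers,
      chain_coll(c("M2", "K2", "A2"), aop_id = 2L)$kers
    ))
  )
  expect_true(all(is.finite(directed_eccentricity(two))))
})

test_that("eccentricity bands split at 3 and 6", {
  ecc <- stats::setNames(c(0L, 2L, 3L, 6L, 7L), letters[1:5])
  expect_equal(
    unname(band_eccentricity(ecc)),
    c("upstream", "upstream", "middle", "middle", "downstream")
  )
  isolated <- stats::setNames(c(0L, 0L), c("x", "y"))
  expect_true(all(band_eccentricity(isolated) == "upstream"))
})

test_that("normalised betweenness matches hand values on chain and star", {
  chain <- build_network(chain_coll(c("M", "K", "A")))
  b <- node_betweenness(chain)
  expect_equal(b[["K"]], 0.5)
  expect_equal(b[["M"]], 0)

  # in-star + out-star through a centre: centre strictly maximal
  net <- edges_net(
    c("i1", "i2", "i3", "c", "c", "c"),
    c("c", "c", "c", "o1", "o2", "o3")
  )
  b2 <- node_betweenness(net)
  expect_true(all(b2[["c"]] > b2[names(b2) != "c"]))
})

test_that("path enumeration matches hand enumeration and halts on feedback loops", {
  dia <- build_network(diamond_coll())
  p <- enumerate_mie_ao_paths(dia)
  expect_equal(length(p), 2)
  expect_equal(p[[1]], c("M", "A", "Z"))
  expect_equal(p[[2]], c("M", "B", "Z"))

  # feedback loop A <-> B: the revisit ban leaves exactly one path
  fb <- edges_net(c("M", "A", "B", "B"), c("A", "B", "A", "Z"))
  pf <- enumerate_mie_ao_paths(fb, mie_set = "M", ao_set = "Z")
  expect_equal(length(pf), 1)
  expect_equal(pf[[1]], c("M", "A", "B", "Z"))

  # emission order is lexicographic in the node sequence
  lex <- edges_net(c("M", "M", "A", "B", "A"), c("A", "B", "Z", "Z", "B"))
  pl <- enumerate_mie_ao_paths(lex, mie_set = "M", ao_set = "Z")
  expect_equal(
    vapply(pl, paste, character(1), collapse = ","),
    c("M,A,B,Z", "M,A,Z", "M,B,Z")
  )

  # guard trips with a resource error
  expect_error(
    enumerate_mie_ao_paths(lex, mie_set = "M", ao_set = "Z", max_paths = 2),
    class = "aopnet_path_guard"
  )
})

test_that("a node annotated as both MIE and AO yields no single-node path", {
  x <- aop_collection(tibble::tibble(
    aop_id = c(1L, 2L),
    upstream_title = c("Dual", "M2"), upstream_type = c("MIE", "MIE"),
    downstream_title = c("Z", "Dual"), downstream_type = c("AO", "AO"),
    adjacency = "adjacent", woe = "unspecified"
  ))
  net <- build_network(x, validate = FALSE)
  p <- enumerate_mie_ao_paths(net)
  expect_true(all(lengths(p) >= 2))
  # Dual still acts as endpoint in both directions
  keys <- vapply(p, paste, character(1), collapse = ",")
  expect_true("Dual,Z" %in% keys)
  expect_true("M2,Dual" %in% keys)
})

test_that("path occurrence is the fraction of MIE->AO paths through each node", {
  dia <- build_network(diamond_coll())
  p <- enumerate_mie_ao_paths(dia)
  occ <- path_occurrence(p, dia$nodes$canonical_title)
  expect_equal(occ, c(A = 0.5, B = 0.5, M = 1, Z = 1))

  chain <- build_network(chain_coll(c("M", "K", "A")))
  occ2 <- path_occurrence(
    enumerate_mie_ao_paths(chain), chain$nodes$canonical_title
  )
  expect_true(all(occ2 == 1))

  expect_error(path_occurrence(list(), "A"), "undefined")
})

test_that("deleting a node that lies on no MIE->AO path leaves occurrences unchanged", {
  # Off-path appendix: Z -> W (W on no MIE->AO path)
  x <- aop_collection(tibble::tibble(
    aop_id = rep(1L, 5),
    upstream_title = c("M", "A", "M", "B", "Z"),
    upstream_type = c("MIE", "KE", "MIE", "KE", "AO"),
    downstream_title = c("A", "Z", "B", "Z", "W"),
    downstream_type = c("KE", "AO", "KE", "AO", "KE"),
    adjacency = "adjacent", woe = "unspecified"
  ))
  full <- build_network(x, validate = FALSE)
  occ_full <- path_occurrence(enumerate_mie_ao_paths(full),
                              full$nodes$canonical_title)
  expect_equal(occ_full[["W"]], 0)
  pruned <- build_network(x, drop_titles = "W", validate = FALSE)
  occ_pruned <- path_occurrence(enumerate_mie_ao_paths(pruned),
                                pruned$nodes$canonical_title)
  common <- setdiff(names(occ_full), "W")
  expect_equal(occ_full[common], occ_pruned[common])
})

test_that("AOP sharing counts and histogram reflect the provenance", {
  one <- build_network(diamond_coll())
  sh <- ke_sharing(one)
  expect_equal(sh$counts$aop_share_count[sh$counts$node == "M"], 2L)
  expect_equal(sh$counts$aop_share_count[sh$counts$node == "A"], 1L)
  expect_equal(sum(sh$share_histogram), nrow(one$nodes))

  solo <- build_network(chain_coll(c("M", "K", "A")))
  expect_true(all(ke_sharing(solo)$counts$aop_share_count == 1))
})

test_that("WoE distribution percentages use half-away rounding and flag non-100 sums", {
  x <- mk_coll(rep(1L, 3), c("A", "B", "C"), c("B", "C", "D"),
               utype = c("MIE", "KE", "KE"), dtype = c("KE", "KE", "AO"),
               woe = c("high", "medium", "low"))
  w <- woe_distribution(build_network(x))
  expect_equal(w$pct[w$woe %in% c("high", "medium", "low")], c(33, 33, 33))
  expect_false(attr(w, "sums_to_100"))

  allu <- woe_distribution(build_network(chain_coll(c("M", "K", "A"))))
  expect_equal(allu$pct[allu$woe == "unspecified"], 100)
  expect_true(attr(allu, "sums_to_100"))
})

test_that("summarise_network assembles consistent metrics in rank order", {
  x <- generate_collection(generator_config(seed = 17))
  res <- summarise_network(build_network(x))
  m <- res$metrics
  expect_equal(
    names(m),
    c("node", "degree", "in_degree", "out_degree", "eccentricity",
      "eccentricity_band", "betweenness", "path_occurrence",
      "convergence_class", "aop_share_count")
  )
  expect_equal(m$degree, m$in_degree + m$out_degree)
  expect_equal(sum(m$in_degree), nrow(res$metrics) * 0 + sum(m$out_degree))
  expect_equal(sum(m$in_degree), res$summary$n_edges)
  expect_true(all(m$path_occurrence >= 0 & m$path_occurrence <= 1))
  expect_true(all(diff(m$path_occurrence) <= 1e-12))
  s <- res$summary
  expect_equal(s$n_convergent + s$n_divergent + s$n_balanced, s$n_nodes)
  expect_equal(sum(s$share_histogram), s$n_nodes)
  expect_equal(sum(s$ecc_band_counts), s$n_nodes)
  expect_equal(sum(s$indegree_histogram), s$n_nodes)
})

test_that("metrics are invariant to input row order", {
  x <- generate_collection(generator_config(seed = 23))
  res1 <- summarise_network(build_network(x))
  set.seed(4)
  res2 <- summarise_network(build_network(
    aop_collection(x$kers[sample(nrow(x$kers)), ])
  ))
  expect_equal(res2$metrics, res1$metrics)
  expect_equal(res2$summary, res1$summary)
})

test_that("adding a disjoint linear AOP never lowers incoming eccentricities", {
  x <- generate_collection(generator_config(n_aops = 3, seed = 31))
  net <- build_network(x, drop_titles = character(0))
  ecc <- directed_eccentricity(net)
  extra <- chain_coll(paste0("disjoint-", 1:5), aop_id = 99L)
  both <- build_network(
    aop_collection(dplyr::bind_rows(x$kers, extra$kers)),
    drop_titles = character(0)
  )
  ecc2 <- directed_eccentricity(both)
  expect_true(all(ecc2[names(ecc)] >= ecc))
})
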