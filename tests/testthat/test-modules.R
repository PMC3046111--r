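triangle_net <- function() {
  build_network(unit_edges(clique_edges(c("A", "B", "C"))), 0.5)
}

test_that("cohesiveness follows the penalized internal-weight formula", {
  tri <- triangle_net()
  expect_equal(cohesiveness(tri, c("A", "B", "C"), penalty = 0), 1)
  expect_equal(cohesiveness(tri, c("A", "B", "C"), penalty = 2), 3 / 9)
  # single node with one external unit edge
  pair <- build_network(unit_edges(list(c("A", "B"))), 0.5)
  expect_equal(cohesiveness(pair, "A", penalty = 0), 0)
  expect_equal(cohesiveness(pair, c("A", "B"), penalty = 2), 1 / 5)
  expect_error(cohesiveness(tri, character(0)), class = "mirkey_parameter_error")
})

test_that("cohesiveness agrees with brute-force recomputation on random graphs", {
  for (seed in 1:6) {
    net <- build_network(random_edges(30, p = 0.2, seed = seed))
    nodes <- network_nodes(net)
    set.seed(seed + 50)
    for (rep in 1:5) {
      members <- sample(nodes, sample(2:8, 1))
      expect_equal(cohesiveness(net, members),
                   brute_cohesiveness(net, members), tolerance = 1e-12)
    }
  }
})

test_that("greedy growth recovers closed cliques and respects weak bridges", {
  # a 4-clique grows to completion from any seed
  cl4 <- build_network(unit_edges(clique_edges(c("A", "B", "C", "D"))), 0.5)
  expect_equal(grow_cluster(cl4, "C"), c("A", "B", "C", "D"))

  # an isolated seed has no admissible move
  pair <- build_network(unit_edges(list(c("A", "B"), c("C", "D"))), 0.5)
  iso <- induced_subnetwork(pair, c("A", "C"))
  expect_equal(grow_cluster(iso, "A"), "A")

  # two 5-cliques joined by one bridge: growth stays on the seed's side
  c1 <- paste0("P", 1:5); c2 <- paste0("Q", 1:5)
  bridged <- build_network(unit_edges(c(
    clique_edges(c1), clique_edges(c2), list(c("P1", "Q1"))
  )), 0.5)
  expect_equal(grow_cluster(bridged, "P3"), sort(c1))
  expect_equal(grow_cluster(bridged, "Q2"), sort(c2))
})

test_that("every growth step strictly improves on the seed singleton", {
  for (seed in 1:5) {
    net <- build_network(random_edges(25, p = 0.25, seed = seed))
    nodes <- network_nodes(net)
    set.seed(seed)
    for (s in sample(nodes, 5)) {
      grown <- grow_cluster(net, s)
      expect_gte(cohesiveness(net, grown), cohesiveness(net, s))
    }
  }
})

test_that("module discovery finds disjoint cliques and drops isolated nodes", {
  c1 <- paste0("P", 1:5); c2 <- paste0("Q", 1:5)
  edges <- unit_edges(c(clique_edges(c1), clique_edges(c2),
                        list(c("I1", "I2"), c("I3", "I4"), c("I5", "I6"))))
  net <- build_network(edges, 0.5)
  # carve out: two 5-cliques and 3 isolated nodes on a 13-node graph
  net <- induced_subnetwork(net, c(c1, c2, "I1", "I3", "I5"))
  mods <- cluster_one(net)
  expect_equal(nrow(mods), 2L)
  expect_setequal(mods$members[[1]], c1)
  expect_setequal(mods$members[[2]], c2)
  expect_true(all(mods$density == 1))

  # pairwise overlap between returned modules is below the merge threshold
  if (nrow(mods) > 1) {
    for (i in 1:(nrow(mods) - 1)) {
      for (j in (i + 1):nrow(mods)) {
        expect_lt(overlap_score(mods$members[[i]], mods$members[[j]]), 0.8)
      }
    }
  }

  # isolated-only graph yields no module at the default minimum size
  iso_only <- induced_subnetwork(net, c("I1", "I3"))
  expect_equal(nrow(cluster_one(iso_only)), 0L)
})

test_that("module discovery is deterministic under edge-list shuffling", {
  edges <- random_edges(40, p = 0.2, seed = 3)
  net <- build_network(edges)
  ref <- cluster_one(net)
  for (seed in 1:3) {
    set.seed(seed)
    net2 <- build_network(edges[sample(nrow(edges)), ])
    expect_identical(cluster_one(net2), ref)
  }
})

test_that("overlap score and largest-module tie-breaking behave as documented", {
  expect_equal(overlap_score(c("a", "b"), c("a", "b")), 1)
  expect_equal(overlap_score(c("a", "b", "c"), c("b", "c", "d")), 4 / 9)

  mods <- tibble::tibble(
    module_id = c("M1", "M2", "M3"),
    members = list(c("a", "b", "c", "d"), c("e", "f", "g", "h"), c("x", "y", "z")),
    size = c(4L, 4L, 3L),
    cohesiveness = c(0.5, 0.7, 0.9),
    density = c(1, 1, 1)
  )
  expect_equal(largest_module(mods)$module_id, "M2")
  expect_equal(largest_module(mods[3, ])$module_id, "M3")
  expect_error(largest_module(mods[0, ]), class = "mirkey_not_found_error")
})

test_that("hypergeometric enrichment matches exact enumeration and BH is monotone", {
  universe <- letters[1:10]
  sets <- list(hit = letters[1:5])
  res <- enrich_module(letters[1:3], sets, universe)
  expect_equal(res$p_value, choose(5, 3) / choose(10, 3))  # = 1/12
  expect_equal(res$overlap, 3L)

  # certain event: the set covers the whole universe
  res2 <- enrich_module(letters[1:3], list(all = universe), universe)
  expect_equal(res2$p_value, 1)

  # zero overlap keeps p in (0, 1]
  res3 <- enrich_module(c("h", "i", "j"), list(miss = letters[1:4]), universe)
  expect_lte(res3$p_value, 1)
  expect_gt(res3$p_value, 0)

  # BH preserves the p-value ordering across many random sets
  set.seed(1)
  sets_many <- lapply(1:8, function(i) sample(universe, sample(2:6, 1)))
  names(sets_many) <- paste0("s", 1:8)
  res4 <- enrich_module(letters[1:4], sets_many, universe)
  expect_false(is.unsorted(res4$adjusted_p[order(res4$p_value)]))
  expect_true(all(res4$p_value > 0 & res4$p_value <= 1))
  expect_error(enrich_module("a", sets, character(0)), class = "mirkey_parameter_error")
  expect_error(enrich_module("zz", sets, universe), class = "mirkey_input_error")
})

test_that("planted dense modules are recovered from target-induced subnetworks", {
  # the module stage runs on the subgraph induced by a miRNA's targets:
  # there the planted module (within-module edge probability 0.9) sits in a
  # background of pairwise density ~0.05 and must be recovered cleanly
  jacs <- c()
  for (seed in 1:5) {
    st <- simulate_mi_study(seed = seed)
    for (key in st$truth$planted_key_mirnas) {
      targets <- st$target_map$gene_id[st$target_map$mirna_id == key]
      sub <- induced_subnetwork(st$network, targets)
      n <- length(network_nodes(sub))
      bg_density <- (nrow(network_edges(sub)) - choose(8, 2) * 0.9) / choose(n, 2)
      expect_lt(bg_density, 0.15)
      mods <- cluster_one(sub)
      expect_gte(nrow(mods), 1L)
      top <- largest_module(mods)
      jacs <- c(jacs, best_jaccard(top$members[[1]], st$truth$planted_modules))
    }
  }
  # a background node with several in-module edges is occasionally a locally
  # optimal member of the cohesive cluster; recovery must still be sharp
  expect_gte(mean(jacs >= 0.9), 0.9)
  expect_true(all(jacs >= 0.8))
})

test_that("per-miRNA module discovery reports the largest target-subnetwork module", {
  st <- simulate_mi_study(n_nodes = 150, attachment = 2, seed = 4)
  key <- st$truth$planted_key_mirnas
  out <- mirna_modules(st$network, st$target_map, st$gene_sets, mirnas = key)
  expect_setequal(out$modules$mirna_id, key)
  for (i in seq_len(nrow(out$modules))) {
    expect_gte(best_jaccard(out$modules$members[[i]], st$truth$planted_modules), 0.8)
  }
  dis <- out$enrichment[out$enrichment$set_id == "disease_ischemia", ]
  dec <- out$enrichment[grepl("^decoy", out$enrichment$set_id), ]
  expect_lt(max(dis$p_value), min(dec$p_value))
})
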