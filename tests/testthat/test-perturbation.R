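path_network <- function() {
  build_network(unit_edges(list(c("A", "B"), c("B", "C"))),
                confidence_threshold = 0.5)
}

with_totals <- function(net, totals) {
  set_abundance(net, setNames(totals, network_nodes(net)))
}

test_that("binding-free limits: no edges or K = 0 leave free = total", {
  pair <- build_network(unit_edges(list(c("A", "B"), c("C", "D"))),
                        confidence_threshold = 0.5)
  edgeless <- induced_subnetwork(pair, c("A", "C"))
  edgeless <- with_totals(edgeless, c(2, 5))
  eq <- equilibrate(edgeless)
  expect_equal(unname(eq$free), c(2, 5))
  expect_equal(nrow(eq$complex), 0L)

  bound <- with_totals(path_network(), c(1, 2, 3))
  eq0 <- equilibrate(bound, K = 0)
  expect_equal(unname(eq0$free[c("A", "B", "C")]), c(1, 2, 3))
})

test_that("two-node equilibrium matches the closed-form quadratic root", {
  net <- with_totals(build_network(unit_edges(list(c("A", "B"))), 0.5), c(1, 1))
  eq <- equilibrate(net, K = 1)
  expect_equal(unname(eq$free["A"]), (sqrt(5) - 1) / 2, tolerance = 1e-9)
  expect_equal(eq$complex$complex, (3 - sqrt(5)) / 2, tolerance = 1e-9)
})

test_that("equilibria conserve mass and are order- and damping-invariant", {
  for (seed in 1:4) {
    net <- build_network(random_edges(30, p = 0.2, seed = seed))
    set.seed(seed)
    totals <- setNames(rlnorm(length(network_nodes(net)), log(5), 1),
                       network_nodes(net))
    net <- set_abundance(net, totals)
    eq <- equilibrate(net)
    # mass balance: free + bound pairs = total at every node
    bound_per_node <- tapply(
      c(eq$complex$complex, eq$complex$complex),
      c(eq$complex$protein_a, eq$complex$protein_b), sum
    )
    recon <- eq$free
    recon[names(bound_per_node)] <- recon[names(bound_per_node)] + bound_per_node
    expect_equal(unname(recon), unname(eq$totals), tolerance = 1e-8)
    expect_lt(eq$residual, 1e-10)
    expect_true(all(eq$free >= 0))

    # damping choice must not change the fixed point
    eq2 <- equilibrate(net, damping = 0.8)
    expect_equal(eq$free, eq2$free, tolerance = 1e-8)

    # node relabeling/input order must not change the fixed point
    el <- network_edges(net)
    shuffled <- el[sample(nrow(el)), ]
    net_s <- set_abundance(build_network(shuffled), totals)
    eq3 <- equilibrate(net_s)
    expect_equal(eq3$free[names(eq$free)], eq$free, tolerance = 1e-8)
  }
})

test_that("three-node chain perturbation matches an independent Newton oracle", {
  net <- with_totals(path_network(), c(1, 1, 1))
  base <- equilibrate(net, tol = 1e-12)
  oracle_base <- newton_equilibrium(net, base$totals, K = 1)
  expect_equal(base$free, oracle_base, tolerance = 1e-9)

  res <- perturb(net, base, "A", fold = 0.5, tol = 1e-12)
  totals2 <- base$totals; totals2["A"] <- 0.5
  oracle_pert <- newton_equilibrium(net, totals2, K = 1)
  expect_equal(res$equilibrium$free, oracle_pert, tolerance = 1e-9)
  expected_resp <- pmax(oracle_pert / oracle_base, oracle_base / oracle_pert)[c("B", "C")]
  got <- setNames(res$response$response, res$response$node)[c("B", "C")]
  expect_equal(got, expected_resp, tolerance = 1e-9)
})

test_that("identity and no-path perturbations leave responses at unity", {
  net <- with_totals(path_network(), c(1, 2, 3))
  base <- equilibrate(net)
  same <- perturb(net, base, "A", fold = 1)
  expect_equal(same$response$response, rep(1, 2), tolerance = 1e-8)
  expect_equal(perturbed_subgroup_size(same, 1.2), 0L)

  # isolated source: no propagation path to the other node
  pair <- build_network(unit_edges(list(c("A", "B"), c("C", "D"))), 0.5)
  iso <- with_totals(induced_subnetwork(pair, c("A", "C")), c(2, 5))
  base_iso <- equilibrate(iso)
  res <- perturb(iso, base_iso, "A", fold = 0.5)
  expect_equal(res$response$response, 1)
  expect_error(perturb(net, base, character(0)), class = "mirkey_parameter_error")
  expect_error(perturb(net, base, "A", fold = 0), class = "mirkey_parameter_error")
})

test_that("subgroup sizes count thresholded responses and bound the score", {
  fake <- structure(
    list(sources = "S",
         response = tibble::tibble(node = c("a", "b", "c"),
                                   response = c(1.0, 1.3, 2.5))),
    class = "perturbation_result"
  )
  expect_equal(perturbed_subgroup_size(fake, 1.2), 2L)
  expect_equal(perturbed_subgroup_size(fake, 2.0), 1L)
  expect_equal(dynamic_score(fake), 0.5)
  expect_error(perturbed_subgroup_size(fake, 0.9), class = "mirkey_parameter_error")

  flat <- fake; flat$response$response <- rep(1, 3)
  expect_equal(perturbed_subgroup_size(flat, 1.0 + 1e-9), 0L)
  expect_equal(dynamic_score(flat), 0)

  all_high <- fake; all_high$response$response <- c(2.5, 3, 4)
  expect_equal(dynamic_score(all_high), 1)
})

test_that("random perturbations keep the dynamic score in [0,1] with monotone subgroups", {
  net <- build_network(random_edges(35, p = 0.15, seed = 9))
  set.seed(9)
  nodes <- network_nodes(net)
  net <- set_abundance(net, setNames(rlnorm(length(nodes), log(10), 1), nodes))
  base <- equilibrate(net)
  for (rep in 1:25) {
    src <- sample(nodes, sample(1:5, 1))
    res <- perturb(net, base, src, fold = sample(c(0.25, 0.5, 2, 4), 1))
    sizes <- vapply(c(1, 1.2, 1.5, 2, 3), function(th) {
      perturbed_subgroup_size(res, th)
    }, numeric(1))
    expect_true(all(diff(sizes) <= 0))
    ds <- dynamic_score(res)
    expect_gte(ds, 0); expect_lte(ds, 1)
  }
})

test_that("per-miRNA dynamic scoring is deterministic and handles edge cases", {
  st <- simulate_mi_study(n_nodes = 80, attachment = 2, module_size = 5,
                          n_targets = 10, seed = 5)
  tm <- st$target_map
  # two miRNAs with identical target sets score identically
  first <- tm$mirna_id[1]
  clone <- tm[tm$mirna_id == first, ]
  clone$mirna_id <- "miR-clone"
  dyn <- score_mirna_dynamics(st$network, rbind(tm[tm$mirna_id == first, ], clone))
  expect_equal(dyn$dynamic_score[1], dyn$dynamic_score[2])
  expect_equal(dyn$mean_log2_abundance[1], dyn$mean_log2_abundance[2])

  # miRNA with no in-network target gets the undefined marker
  ghost <- tibble::tibble(mirna_id = "miR-ghost", gene_id = c("nope1", "nope2"))
  dyn2 <- score_mirna_dynamics(st$network, ghost)
  expect_true(is.na(dyn2$dynamic_score))
  expect_equal(dyn2$n_targets_in_network, 0L)

  # miRNA targeting only isolated nodes cannot perturb anything
  pair <- build_network(unit_edges(list(c("A", "B"), c("C", "E"))), 0.5)
  iso_net <- induced_subnetwork(pair, c("A", "B", "C"))
  iso_net <- set_abundance(iso_net, c(A = 1, B = 1, C = 5))
  only_iso <- tibble::tibble(mirna_id = "m", gene_id = "C")
  expect_equal(score_mirna_dynamics(iso_net, only_iso)$dynamic_score, 0)
})

test_that("abundant low-load targets out-propagate scarce ones (planted contrast)", {
  # Under mass-action binding, a perturbed node moves its partners in
  # proportion to its own free concentration, so high-abundance targets with
  # few competing partners are the efficient regulators.
  for (seed in 1:3) {
    net <- simulate_ppi_network(300, 3, seed = seed)
    deg <- node_degree(net)
    ab <- setNames(igraph::V(net$graph)$abundance, network_nodes(net))
    low_deg <- names(deg)[deg <= stats::median(deg)]
    efficient <- low_deg[order(-ab[low_deg])][1:10]
    inefficient <- names(ab)[order(ab)][1:10]
    tm <- tibble::tibble(
      mirna_id = rep(c("miR-eff", "miR-ineff"), each = 10),
      gene_id = c(efficient, inefficient)
    )
    dyn <- score_mirna_dynamics(net, tm)
    expect_gt(dyn$dynamic_score[dyn$mirna_id == "miR-eff"],
              dyn$dynamic_score[dyn$mirna_id == "miR-ineff"])
  }
})

test_that("score-covariate correlation matches the closed form and drops NAs", {
  x <- c(1, 2, 3, 5); y <- c(2, 1, 4, 6)
  expected <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  out <- correlate_scores(x, y)
  expect_equal(out$r, expected, tolerance = 1e-12)
  expect_equal(out$p_value, stats::cor.test(x, y)$p.value)
  expect_equal(correlate_scores(x, x)$r, 1)
  expect_equal(correlate_scores(x, -x)$r, -1)
  out2 <- correlate_scores(c(x, NA), c(y, 1))
  expect_equal(out2$n_dropped, 1L)
  expect_error(correlate_scores(c(1, 2, NA), c(1, 2, 3)),
               class = "mirkey_undefined_error")
})
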