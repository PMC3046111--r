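#' Simulate a scale-free PPI network with abundances
#'
#' Preferential-attachment (Barabasi-Albert) graph: starting from
#' `attachment` unconnected seed nodes, each new node attaches to
#' `attachment` distinct existing nodes chosen proportionally to degree,
#' giving exactly `(n_nodes - attachment) * attachment` edges.  Edge
#' confidences are drawn uniformly from `confidence_range` (so every edge
#' survives the default 0.7 construction threshold) and node abundances
#' from a log-normal, emulating the heavy-tailed abundance distribution of
#' tissue expression profiles.
#'
#' @param n_nodes Number of nodes (>= attachment + 1).
#' @param attachment Edges added per new node.  Default 3.
#' @param seed Integer RNG seed (the generator is a pure function of its
#'   arguments).
#' @param confidence_range Range of edge confidences.  Default \[0.7, 1\].
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance
#'   parameters.  Defaults `log(10)` and 1.
#' @return A `ppi_network` with node attribute `abundance`.
#' @export
simulate_ppi_network <- function(n_nodes = 500, attachment = 3, seed = 1,
                                 confidence_range = c(0.7, 1),
                                 abundance_meanlog = log(10),
                                 abundance_sdlog = 1) {
  if (n_nodes < attachment + 1L || attachment < 1L) {
    abort("Need `n_nodes` >= `attachment` + 1 and `attachment` >= 1.",
          class = "mirkey_parameter_error")
  }
  set.seed(seed)
  nodes <- sprintf("G%04d", seq_len(n_nodes))
  m <- attachment
  # networkx-style preferential attachment via a repeated-nodes urn
  targets <- seq_len(m)
  repeated <- integer(0)
  from <- integer(0); to <- integer(0)
  for (v in (m + 1L):n_nodes) {
    from <- c(from, rep.int(v, m))
    to <- c(to, targets)
    repeated <- c(repeated, targets, rep.int(v, m))
    # next targets: m distinct draws from the urn
    nt <- integer(0)
    while (length(nt) < m) {
      nt <- unique(c(nt, repeated[sample.int(length(repeated), m)]))
    }
    targets <- nt[seq_len(m)]
  }
  edges <- tibble(
    protein_a = nodes[from], protein_b = nodes[to],
    confidence = runif(length(from), confidence_range[1L], confidence_range[2L])
  )
  net <- build_network(edges, confidence_threshold = confidence_range[1L])
  # isolated seed-era nodes can drop out of the edge list; keep all nodes
  missing <- setdiff(nodes, network_nodes(net))
  if (length(missing) > 0L) {
    net$graph <- igraph::add_vertices(net$graph, length(missing), name = missing)
  }
  ab <- rlnorm(n_nodes, meanlog = abundance_meanlog, sdlog = abundance_sdlog)
  set_abundance(net, setNames(ab, nodes))
}

#' Plant dense modules into a network
#'
#' Chooses `n_modules` disjoint member sets at random and adds each
#' within-module edge with probability `intra_p` at a confidence drawn from
#' `confidence_range`, giving the overlapping-module stage recoverable
#' ground truth.
#'
#' @param net A `ppi_network`.
#' @param n_modules,module_size Number and size of planted modules.
#' @param intra_p Within-module edge probability.  Default 0.9.
#' @param seed Integer RNG seed.
#' @param confidence_range Confidence range for added edges.  Defaults to
#'   \[0.85, 1\]: within-complex interactions carry stronger evidence than
#'   generic background edges.
#' @param candidates Optional pool of node ids to draw members from
#'   (default: all nodes).
#' @return A list: `network` (with planted edges) and `modules` (list of
#'   member-id vectors).
#' @export
plant_modules <- function(net, n_modules = 2, module_size = 8, intra_p = 0.9,
                          seed = 1, confidence_range = c(0.85, 1),
                          candidates = NULL) {
  check_ppi(net)
  nodes <- if (is.null(candidates)) network_nodes(net) else
    intersect(as.character(candidates), network_nodes(net))
  if (n_modules * module_size > length(nodes)) {
    abort("Planted modules would need more nodes than the network has.",
          class = "mirkey_parameter_error")
  }
  if (intra_p < 0 || intra_p > 1) {
    abort("`intra_p` must lie in [0, 1].", class = "mirkey_parameter_error")
  }
  set.seed(seed)
  picked <- sample(nodes, n_modules * module_size)
  modules <- split(picked, rep(seq_len(n_modules), each = module_size))
  modules <- lapply(modules, sort)
  names(modules) <- paste0("planted_", seq_len(n_modules))

  g <- net$graph
  for (mod in modules) {
    pairs <- utils::combn(mod, 2L)
    add <- runif(ncol(pairs)) < intra_p
    for (k in which(add)) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      w <- runif(1L, confidence_range[1L], confidence_range[2L])
      eid <- igraph::get_edge_ids(g, c(a, b))
      if (eid > 0) {
        igraph::E(g)$confidence[eid] <- max(igraph::E(g)$confidence[eid], w)
      } else {
        g <- igraph::add_edges(g, c(a, b), confidence = w)
      }
    }
  }
  net$graph <- g
  list(network = net, modules = modules)
}

#' Simulate a miRNA -> target-gene map with planted key miRNAs
#'
#' Background miRNAs target network genes uniformly at random.  Key miRNAs
#' get a composite target set: planted-module members (module recovery and
#' disease enrichment), top-degree hubs (high static score), and abundant
#' low-degree "amplifier" nodes.  The amplifiers are what make the planted
#' perturbation propagate: under the mass-action model a node's influence
#' on a binding partner scales with its free concentration, which is large
#' exactly for abundant nodes with few competing partners, so halving them
#' moves their neighbourhood past the subgroup thresholds and yields a high
#' dynamic score.
#' Evidence labels and prediction p-values are drawn so that about 60% of
#' each miRNA's records are validated or credibly predicted
#' (`p < p_cutoff`).
#'
#' @param mirnas Character vector of miRNA ids.
#' @param net A `ppi_network`.
#' @param key_mirnas Subset of `mirnas` planted as key regulators.
#' @param modules Optional list of planted-module member vectors assigned
#'   round-robin to the key miRNAs.
#' @param seed Integer RNG seed.
#' @param n_targets Targets per miRNA (>= 1).  Default 25.
#' @param validated_frac Fraction of records labelled validated.
#'   Default 0.3.
#' @param credible_predicted_frac Fraction of predicted records given
#'   `p < p_cutoff`.  Default 3/7 (so overall credibility is 60%).
#' @param p_cutoff Credibility cutoff used for the p-value mixture.
#'   Default 0.01.
#' @param hub_targets Number of top-degree hub nodes in a key miRNA's
#'   target set.  Default 12.
#' @return A tibble: `mirna_id`, `gene_id`, `evidence`, `p_value`.
#' @export
simulate_target_map <- function(mirnas, net, key_mirnas = character(0),
                                modules = NULL, seed = 1, n_targets = 25,
                                validated_frac = 0.3,
                                credible_predicted_frac = 3 / 7,
                                p_cutoff = 0.01, hub_targets = 12) {
  check_ppi(net)
  if (!all(key_mirnas %in% mirnas)) {
    abort("`key_mirnas` must be a subset of `mirnas`.", class = "mirkey_parameter_error")
  }
  if (n_targets < 1L) {
    abort("Every miRNA needs at least one target (`n_targets` >= 1).",
          class = "mirkey_parameter_error")
  }
  set.seed(seed)
  nodes <- network_nodes(net)
  deg <- node_degree(net)
  ab <- setNames(igraph::V(net$graph)$abundance, nodes)
  hubs <- nodes[order(-deg, nodes)][seq_len(min(hub_targets, length(nodes)))]
  low_deg <- setdiff(nodes[deg <= stats::median(deg)], unlist(modules))
  amplifiers <- low_deg[order(-ab[low_deg], low_deg)]  # abundant, few partners

  rows <- purrr::imap_dfr(setNames(mirnas, mirnas), function(id, nm) {
    if (id %in% key_mirnas) {
      mod <- character(0)
      if (!is.null(modules) && length(modules) > 0L) {
        mod <- modules[[(match(id, key_mirnas) - 1L) %% length(modules) + 1L]]
      }
      n_amp <- max(n_targets - length(mod) - length(hubs), 1L)
      genes <- unique(c(mod, hubs, amplifiers[seq_len(min(n_amp, length(amplifiers)))]))
    } else {
      genes <- sample(nodes, min(n_targets, length(nodes)))
    }
    tibble(mirna_id = id, gene_id = genes)
  })
  n <- nrow(rows)
  validated <- runif(n) < validated_frac
  credible <- runif(n) < credible_predicted_frac
  p <- ifelse(credible, runif(n, 0, p_cutoff), runif(n, p_cutoff, 1))
  rows %>%
    mutate(evidence = ifelse(validated, "validated", "predicted"),
           p_value = ifelse(validated, NA_real_, p))
}

#' Simulate a four-group pooled expression table from a planted truth
#'
#' Control values are drawn around a typical log2 microarray intensity of
#' 8; the disease group adds each miRNA's planted signed effect, the
#' disease+drug group restores planted drug-reversed miRNAs toward control
#' by the planted reversal (and drifts non-reversed ones only slightly),
#' and i.i.d. Gaussian noise at `noise_sd` is added to every value.
#'
#' @param truth A `synthetic_truth` from [simulate_mi_study()] (or a list
#'   with an `effects` tibble holding `mirna_id`, `effect`, `reversal`,
#'   `drift`, `drug_only_shift`).
#' @param noise_sd Noise standard deviation in log2 units.  Default 0.1.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `mirna_id`, `control`, `disease`,
#'   `disease_drug`, `drug_only`.
#' @export
simulate_expression <- function(truth, noise_sd = 0.1, seed = 1) {
  if (noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "mirkey_parameter_error")
  }
  eff <- truth$effects
  set.seed(seed)
  n <- nrow(eff)
  control <- rnorm(n, mean = 8, sd = 1)
  disease <- control + eff$effect
  disease_drug <- disease - eff$reversal + eff$drift
  drug_only <- control + eff$drug_only_shift
  noise <- function(x) x + rnorm(n, 0, noise_sd)
  tibble(
    mirna_id = eff$mirna_id,
    control = noise(control),
    disease = noise(disease),
    disease_drug = noise(disease_drug),
    drug_only = noise(drug_only)
  )
}

#' Simulate disease gene sets
#'
#' One disease set equal to the planted disease genes plus `n_decoys` decoy
#' sets of matched size drawn uniformly from the network nodes.
#'
#' @param net A `ppi_network`.
#' @param disease_genes Character vector of planted disease genes (must be
#'   network nodes).
#' @param n_decoys Number of decoy sets.  Default 5.
#' @param seed Integer RNG seed.
#' @return A named list of gene-id vectors; the disease set is named
#'   `"disease_ischemia"`.
#' @export
simulate_gene_sets <- function(net, disease_genes, n_decoys = 5, seed = 1) {
  check_ppi(net)
  nodes <- network_nodes(net)
  if (!all(disease_genes %in% nodes)) {
    abort("`disease_genes` must all be network nodes.", class = "mirkey_parameter_error")
  }
  set.seed(seed)
  sets <- list(disease_ischemia = sort(unique(disease_genes)))
  size <- length(sets$disease_ischemia)
  for (k in seq_len(n_decoys)) {
    sets[[sprintf("decoy_%02d", k)]] <- sort(sample(nodes, size))
  }
  sets
}

#' Simulate a complete four-group miRNA study with planted truth
#'
#' Bundles all generators: a scale-free PPI network with planted dense
#' modules and log-normal abundances, a target map whose planted key
#' miRNAs aim at module members and low-abundance hubs, a four-group
#' expression table with planted dysregulation and drug reversal, and
#' disease/decoy gene sets.  Effects are planted at least two noise
#' standard deviations beyond every classification threshold so recovery
#' tests are sharp.
#'
#' @param n_mirnas Number of miRNAs.  Default 30.
#' @param n_dysregulated Planted dysregulated miRNAs.  Default 10.
#' @param n_prmirs Planted drug-reversed subset.  Default 6.
#' @param n_key Planted key miRNAs (subset of the PRmiRs).  Default 2.
#' @param n_nodes,attachment Network size parameters.  Defaults 500 and 3.
#' @param n_modules,module_size,intra_p Planted-module parameters.
#' @param n_targets Targets per miRNA.  Default 25.
#' @param noise_sd Expression noise (log2).  Default 0.1.
#' @param n_decoys Decoy gene sets.  Default 5.
#' @param seed Integer RNG seed driving every component.
#' @return A list of class `mi_study`: `expression`, `edges`, `network`,
#'   `target_map`, `abundance`, `gene_sets`, and `truth` (a
#'   `synthetic_truth` with the planted sets and effect table).
#' @export
simulate_mi_study <- function(n_mirnas = 30, n_dysregulated = 10, n_prmirs = 6,
                              n_key = 2, n_nodes = 500, attachment = 3,
                              n_modules = 2, module_size = 8, intra_p = 0.9,
                              n_targets = 25, noise_sd = 0.1, n_decoys = 5,
                              seed = 1) {
  if (n_prmirs > n_dysregulated || n_key > n_prmirs || n_dysregulated > n_mirnas) {
    abort("Need n_key <= n_prmirs <= n_dysregulated <= n_mirnas.",
          class = "mirkey_parameter_error")
  }
  mirnas <- sprintf("miR-%03d", seq_len(n_mirnas))

  net0 <- simulate_ppi_network(n_nodes, attachment, seed = seed)
  # plant disease modules on abundant low-degree proteins: few hub contacts
  # keeps the complexes separable in target subnetworks, and their abundance
  # makes perturbing them propagate (high dynamic scores for key miRNAs)
  deg0 <- node_degree(net0)
  ab0 <- setNames(igraph::V(net0$graph)$abundance, names(deg0))
  low_deg <- names(deg0)[deg0 <= stats::median(deg0)]
  pool <- low_deg[order(-ab0[low_deg], low_deg)]
  pool <- pool[seq_len(min(3L * n_modules * module_size, length(pool)))]
  planted <- plant_modules(net0, n_modules = n_modules, module_size = module_size,
                           intra_p = intra_p, seed = seed + 1L, candidates = pool)
  net <- planted$network

  set.seed(seed + 2L)
  dys <- sort(sample(mirnas, n_dysregulated))
  prm <- sort(sample(dys, n_prmirs))
  key <- sort(sample(prm, n_key))

  n <- length(mirnas)
  is_dys <- mirnas %in% dys
  is_prm <- mirnas %in% prm
  effect <- ifelse(is_dys,
                   sample(c(-1, 1), n, replace = TRUE) * runif(n, 1.0, 1.4),
                   runif(n, -0.15, 0.15))
  reversal <- ifelse(is_prm, sign(effect) * runif(n, 1.0, pmax(abs(effect), 1.0)), 0)
  drift <- ifelse(is_prm, 0, runif(n, -0.25, 0.25))
  drug_only_shift <- runif(n, -0.3, 0.3)

  truth <- structure(
    list(
      planted_dysregulated = dys,
      planted_prmirs = prm,
      planted_key_mirnas = key,
      planted_modules = planted$modules,
      planted_disease_genes = NULL,  # filled below
      effects = tibble(mirna_id = mirnas, effect = effect, reversal = reversal,
                       drift = drift, drug_only_shift = drug_only_shift),
      rng_seed = seed
    ),
    class = "synthetic_truth"
  )

  target_map <- simulate_target_map(mirnas, net, key_mirnas = key,
                                    modules = planted$modules, seed = seed + 3L,
                                    n_targets = n_targets)
  expression <- simulate_expression(truth, noise_sd = noise_sd, seed = seed + 4L)

  set.seed(seed + 5L)
  extra <- sample(setdiff(network_nodes(net), unlist(planted$modules)), 10L)
  disease_genes <- sort(unique(c(unlist(planted$modules), extra)))
  truth$planted_disease_genes <- disease_genes
  gene_sets <- simulate_gene_sets(net, disease_genes, n_decoys = n_decoys,
                                  seed = seed + 6L)

  nodes <- network_nodes(net)
  structure(
    list(
      expression = expression,
      edges = network_edges(net),
      network = net,
      target_map = target_map,
      abundance = tibble(gene_id = nodes,
                         abundance = igraph::V(net$graph)$abundance),
      gene_sets = gene_sets,
      truth = truth
    ),
    class = "mi_study"
  )
}

#' @exportS3Method base::print
print.mi_study <- function(x, ...) {
  cat(sprintf(
    "<mi_study> %d miRNAs, %d-node network; planted: %d dysregulated, %d reversed, %d key (seed %d)\n",
    nrow(x$expression), length(network_nodes(x$network)),
    length(x$truth$planted_dysregulated), length(x$truth$planted_prmirs),
    length(x$truth$planted_key_mirnas), x$truth$rng_seed
  ))
  invisible(x)
}
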