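# Fixture builders and independent oracles (deliberately naive: plain loops
# and dense matrices, no shared code with the package internals).

unit_edges <- function(pairs) {
  tibble::tibble(
    protein_a = vapply(pairs, `[[`, "", 1L),
    protein_b = vapply(pairs, `[[`, "", 2L),
    confidence = 1
  )
}

# hub-and-spoke star: hub H, leaves L1..Ln, unit confidences
star_network <- function(n_leaves = 4) {
  build_network(unit_edges(lapply(seq_len(n_leaves), function(i) {
    c("H", paste0("L", i))
  })), confidence_threshold = 0.5)
}

clique_edges <- function(nodes) {
  pr <- utils::combn(nodes, 2L)
  lapply(seq_len(ncol(pr)), function(k) pr[, k])
}

# Erdos-Renyi-style random weighted graph as an edge tibble
random_edges <- function(n, p = 0.3, seed = 1, conf_range = c(0.7, 1)) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pr <- utils::combn(nodes, 2L)
  keep <- runif(ncol(pr)) < p
  if (!any(keep)) keep[1L] <- TRUE
  tibble::tibble(
    protein_a = pr[1L, keep], protein_b = pr[2L, keep],
    confidence = runif(sum(keep), conf_range[1L], conf_range[2L])
  )
}

# dense adjacency (0/1) of a ppi_network, rows/cols in node order given
dense_adjacency <- function(net, nodes = network_nodes(net)) {
  el <- network_edges(net)
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(el))) {
    A[el$protein_a[k], el$protein_b[k]] <- 1
    A[el$protein_b[k], el$protein_a[k]] <- 1
  }
  A
}

# brute-force static score: explicit loops over a dense adjacency matrix
brute_static_score <- function(net, targets, offset = 3.3) {
  nodes <- network_nodes(net)
  A <- dense_adjacency(net, nodes)
  deg <- rowSums(A)
  nc <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    nb <- which(A[i, ] > 0)
    nc[i] <- if (length(nb) == 0L) 0 else mean(deg[nb])
  }
  names(nc) <- nodes
  inside <- intersect(targets, nodes)
  mean(deg[inside]) / mean(deg) + mean(nc[inside]) / mean(nc) - offset
}

# brute-force cohesiveness: loop over the edge list
brute_cohesiveness <- function(net, members, penalty = 2) {
  el <- network_edges(net)
  w_in <- 0; w_bound <- 0
  for (k in seq_len(nrow(el))) {
    ina <- el$protein_a[k] %in% members
    inb <- el$protein_b[k] %in% members
    if (ina && inb) w_in <- w_in + el$confidence[k]
    else if (ina || inb) w_bound <- w_bound + el$confidence[k]
  }
  denom <- w_in + w_bound + penalty * length(members)
  if (denom == 0) 0 else w_in / denom
}

# independent Newton solver for the same mass-action equilibrium equations
newton_equilibrium <- function(net, totals, K, tol = 1e-13) {
  nodes <- network_nodes(net)
  A <- dense_adjacency(net, nodes)
  total <- as.numeric(totals[nodes])
  f <- total
  for (iter in 1:200) {
    s <- as.numeric(A %*% f)
    Fv <- f * (1 + K * s) - total
    if (max(abs(Fv)) < tol) break
    J <- diag(1 + K * s, nrow = length(f)) + K * (f * A)
    f <- f - solve(J, Fv)
    f[f < 0] <- 1e-12
  }
  names(f) <- nodes
  f
}

# closed-form two-node equilibrium: complex c solves K(Ta-c)(Tb-c) = c
two_node_closed_form <- function(Ta, Tb, K) {
  a <- K
  b <- -(K * (Ta + Tb) + 1)
  cc <- K * Ta * Tb
  croot <- (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
  c(free_a = Ta - croot, free_b = Tb - croot, complex = croot)
}

best_jaccard <- function(members, planted_list) {
  max(vapply(planted_list, function(p) {
    length(intersect(members, p)) / length(union(members, p))
  }, numeric(1)))
}
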