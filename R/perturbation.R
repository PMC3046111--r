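#' Mass-action binding equilibrium on a PPI network
#'
#' Treats every retained edge as a reversible dimerization with a single
#' global association constant `K`: at equilibrium the bound-pair
#' concentration on edge (i, j) is `K * free_i * free_j`, and mass balance
#' requires `free_i + sum_j complex_ij = total_i` for every node, where
#' `total_i` is the node's abundance.  The fixed point of
#' `free_i = total_i / (1 + K * sum_j free_j)` is found by damped iteration.
#'
#' @param net A `ppi_network` with node abundances (see [set_abundance()]).
#' @param K Global association constant (1/concentration).  Default 1.
#' @param tol Relative convergence tolerance on the update step and the
#'   mass-balance residual.  Default 1e-10.
#' @param max_iter Maximum iterations.  Default 10000.
#' @param damping Damping factor in (0, 1\]: the fraction of the plain
#'   fixed-point update taken per iteration.  Default 0.5.
#' @param totals Optional vector overriding node abundances (named or in
#'   node order), used internally by [perturb()].
#' @param init Optional starting free-concentration vector.
#'
#' @return An `equilibrium_state`: list with `free` (named vector),
#'   `complex` (tibble per edge), `residual` (max relative mass-balance
#'   violation), `iterations`, `K`, `totals`.
#' @export
equilibrate <- function(net, K = 1, tol = 1e-10, max_iter = 10000,
                        damping = 0.5, totals = NULL, init = NULL) {
  check_ppi(net)
  if (!is.numeric(K) || length(K) != 1L || K < 0) {
    abort("`K` must be a single nonnegative number.", class = "mirkey_parameter_error")
  }
  nodes <- network_nodes(net)
  if (is.null(totals)) {
    totals <- igraph::V(net$graph)$abundance
    if (is.null(totals)) {
      abort("Network has no abundances; call set_abundance() first.",
            class = "mirkey_input_error")
    }
  } else if (!is.null(names(totals))) {
    totals <- totals[nodes]
  }
  totals <- as.numeric(totals)
  if (length(totals) != length(nodes) || any(!is.finite(totals)) || any(totals < 0)) {
    abort("Abundances must be finite and nonnegative for every node.",
          class = "mirkey_input_error")
  }

  adj <- igraph::as_adjacency_matrix(net$graph, sparse = TRUE)
  f <- if (is.null(init)) totals else as.numeric(init[nodes])
  it <- 0L
  scale <- pmax(totals, 1e-12)
  repeat {
    it <- it + 1L
    s <- as.numeric(adj %*% f)
    f_new <- totals / (1 + K * s)
    residual <- max(abs(f * (1 + K * s) - totals) / scale)
    step <- max(abs(f_new - f) / scale)
    if ((residual < tol && step < tol) || it >= max_iter) break
    f <- (1 - damping) * f + damping * f_new
  }
  if (residual >= tol) {
    abort(sprintf("Equilibrium did not converge in %d iterations (residual %.3g).",
                  it, residual),
          class = "mirkey_convergence_error")
  }
  names(f) <- nodes
  el <- igraph::as_edgelist(net$graph)
  structure(
    list(
      free = f,
      complex = tibble(protein_a = el[, 1L], protein_b = el[, 2L],
                       complex = unname(K * f[el[, 1L]] * f[el[, 2L]])),
      residual = residual,
      iterations = it,
      K = K,
      totals = setNames(totals, nodes)
    ),
    class = "equilibrium_state"
  )
}

#' @exportS3Method base::print
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("<equilibrium_state> %d nodes, residual %.2e after %d iterations\n",
              length(x$free), x$residual, x$iterations))
  invisible(x)
}

#' Perturb a miRNA's target nodes and re-equilibrate
#'
#' Multiplies the total concentration of each source node by `fold`
#' (halving emulates repression by an over-expressed miRNA, doubling
#' de-repression by an under-expressed one), recomputes the equilibrium and
#' records, for every non-source node, the fold change of its free
#' concentration: `max(free'/free, free/free')`, with the convention 1 when
#' both are 0.
#'
#' @param net A `ppi_network` with abundances.
#' @param baseline An `equilibrium_state` from [equilibrate()] on `net`.
#' @param sources Character vector of perturbed nodes (must be in the
#'   network, non-empty).
#' @param fold Multiplicative factor applied to source totals (> 0).
#'   Default 0.5.
#' @inheritParams equilibrate
#'
#' @return A `perturbation_result`: list with `sources`, `response` (tibble
#'   `node`, `response` over non-source nodes), `fold`, and the perturbed
#'   `equilibrium`.
#' @export
perturb <- function(net, baseline, sources, fold = 0.5, K = baseline$K,
                    tol = 1e-10, max_iter = 10000, damping = 0.5) {
  check_ppi(net)
  if (!inherits(baseline, "equilibrium_state")) {
    abort("`baseline` must be an equilibrium_state.", class = "mirkey_input_error")
  }
  sources <- unique(as.character(sources))
  if (length(sources) == 0L) {
    abort("`sources` must be non-empty.", class = "mirkey_parameter_error")
  }
  check_nodes(net, sources)
  if (!is.numeric(fold) || length(fold) != 1L || fold <= 0) {
    abort("`fold` must be a single positive number.", class = "mirkey_parameter_error")
  }
  totals <- baseline$totals
  totals[sources] <- totals[sources] * fold
  eq <- equilibrate(net, K = K, tol = tol, max_iter = max_iter,
                    damping = damping, totals = totals, init = baseline$free)
  others <- setdiff(names(baseline$free), sources)
  f0 <- baseline$free[others]
  f1 <- eq$free[others]
  resp <- ifelse(
    f0 == 0 & f1 == 0, 1,
    pmax(f1 / pmax(f0, .Machine$double.xmin), f0 / pmax(f1, .Machine$double.xmin))
  )
  structure(
    list(sources = sources,
         response = tibble(node = others, response = unname(resp)),
         fold = fold,
         equilibrium = eq),
    class = "perturbation_result"
  )
}

#' Perturbed subgroup size at a response threshold
#'
#' Number of non-source nodes whose free-concentration fold change reaches
#' `threshold`.
#'
#' @param result A `perturbation_result` from [perturb()].
#' @param threshold Fold-change threshold, >= 1.
#' @return An integer count.
#' @export
perturbed_subgroup_size <- function(result, threshold) {
  if (!inherits(result, "perturbation_result")) {
    abort("`result` must be a perturbation_result.", class = "mirkey_input_error")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 1) {
    abort("`threshold` must be a single number >= 1.", class = "mirkey_parameter_error")
  }
  sum(result$response$response >= threshold)
}

#' Dynamic (regulatory-efficiency) score
#'
#' Ratio of the perturbed subgroup sizes at the high and low fold-change
#' thresholds (defaults 2.0 and 1.2).  A perturbation that pushes most of
#' the nodes it reaches past the high threshold scores near 1; one whose
#' effect decays quickly scores near 0.  Defined as 0 when the low-threshold
#' subgroup is empty.
#'
#' @param result A `perturbation_result`.
#' @param thresholds Length-2 numeric vector `c(low, high)`, both >= 1.
#'   Default `c(1.2, 2)`.
#' @return A number in \[0, 1\].
#' @export
dynamic_score <- function(result, thresholds = c(1.2, 2)) {
  thresholds <- sort(as.numeric(thresholds))
  if (length(thresholds) != 2L || any(thresholds < 1)) {
    abort("`thresholds` must be two numbers >= 1.", class = "mirkey_parameter_error")
  }
  lo <- perturbed_subgroup_size(result, thresholds[1L])
  hi <- perturbed_subgroup_size(result, thresholds[2L])
  if (lo == 0L) 0 else hi / lo
}

#' Dynamic scores for every miRNA of a target map
#'
#' For each miRNA, perturbs its in-network target nodes (fold chosen by the
#' miRNA's dysregulation direction when `calls` is supplied: `fold_up` for
#' up-regulated miRNAs, `fold_down` for down-regulated) and records the
#' dynamic score together with the mean log2 abundance of those targets.
#'
#' @param net A `ppi_network` with abundances.
#' @param target_map Data frame with `mirna_id`, `gene_id`.
#' @param calls Optional output of [detect_dysregulated()]; used to pick the
#'   perturbation fold per miRNA.
#' @param fold_up,fold_down Fold applied to targets of up-/down-regulated
#'   miRNAs (an over-expressed miRNA represses its targets).  Defaults 0.5
#'   and 2.
#' @param thresholds Passed to [dynamic_score()].
#' @inheritParams equilibrate
#'
#' @return A tibble with one row per miRNA: `mirna_id`,
#'   `n_targets_in_network`, `fold`, `subgroup_low`, `subgroup_high`,
#'   `dynamic_score`, `mean_log2_abundance` (`NA` scores mark miRNAs with no
#'   in-network target).
#' @export
score_mirna_dynamics <- function(net, target_map, calls = NULL,
                                 fold_up = 0.5, fold_down = 2,
                                 thresholds = c(1.2, 2), K = 1,
                                 tol = 1e-10, max_iter = 10000, damping = 0.5) {
  check_ppi(net)
  check_target_map(target_map)
  thresholds <- sort(as.numeric(thresholds))
  baseline <- equilibrate(net, K = K, tol = tol, max_iter = max_iter, damping = damping)
  nodes <- network_nodes(net)
  abundance <- setNames(igraph::V(net$graph)$abundance, nodes)

  dir_of <- function(id) {
    if (is.null(calls)) return("up")
    d <- calls$direction[match(id, calls$mirna_id)]
    if (is.na(d)) "up" else d
  }

  by_mirna <- split(as.character(target_map$gene_id), as.character(target_map$mirna_id))
  purrr::imap_dfr(by_mirna, function(genes, id) {
    targets <- intersect(unique(genes), nodes)
    if (length(targets) == 0L) {
      return(tibble(mirna_id = id, n_targets_in_network = 0L, fold = NA_real_,
                    subgroup_low = NA_integer_, subgroup_high = NA_integer_,
                    dynamic_score = NA_real_, mean_log2_abundance = NA_real_))
    }
    fold <- if (dir_of(id) == "down") fold_down else fold_up
    res <- perturb(net, baseline, targets, fold = fold, K = K,
                   tol = tol, max_iter = max_iter, damping = damping)
    tibble(
      mirna_id = id,
      n_targets_in_network = length(targets),
      fold = fold,
      subgroup_low = perturbed_subgroup_size(res, thresholds[1L]),
      subgroup_high = perturbed_subgroup_size(res, thresholds[2L]),
      dynamic_score = dynamic_score(res, thresholds),
      mean_log2_abundance = mean(log2(abundance[targets]))
    )
  }) %>% arrange(.data$mirna_id)
}

#' Pearson correlation between per-miRNA scores and a covariate
#'
#' Standard Pearson correlation with a t-distributed two-sided p-value;
#' pairs with undefined entries are dropped and counted.
#'
#' @param scores,covariate Numeric vectors of equal length (may contain
#'   `NA`).
#' @return A one-row tibble: `r`, `p_value`, `n_pairs`, `n_dropped`.
#' @export
correlate_scores <- function(scores, covariate) {
  if (length(scores) != length(covariate)) {
    abort("`scores` and `covariate` must have equal length.",
          class = "mirkey_input_error")
  }
  ok <- is.finite(scores) & is.finite(covariate)
  if (sum(ok) < 3L) {
    abort("Correlation is undefined for fewer than 3 complete pairs.",
          class = "mirkey_undefined_error")
  }
  ct <- cor.test(scores[ok], covariate[ok], method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value,
         n_pairs = sum(ok), n_dropped = sum(!ok))
}
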