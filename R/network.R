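#' Build a confidence-filtered protein-protein interaction network
#'
#' Constructs an undirected weighted PPI network from an edge-list data
#' frame, keeping edges whose confidence score is at least
#' `confidence_threshold` (boundary inclusive).  Self-loops are dropped and
#' duplicate undirected edges are collapsed keeping the maximum confidence.
#' Scores given in the STRING 0-999 integer dialect (any score > 1) are
#' rescaled by 1/1000 before filtering.
#'
#' @param edges A data frame whose first three columns are interpreted as
#'   protein A, protein B and the confidence score (canonical names
#'   `protein_a`, `protein_b`, `confidence`; `combined_score` is accepted).
#' @param confidence_threshold Minimum retained confidence, in \[0, 1\].
#'   Default 0.7.
#'
#' @return A `ppi_network` object: an undirected [igraph][igraph::igraph]
#'   graph with edge attribute `confidence`, plus the construction threshold.
#' @export
#' @examples
#' edges <- tibble::tibble(
#'   protein_a = c("A", "B"), protein_b = c("B", "C"),
#'   confidence = c(0.9, 0.5)
#' )
#' build_network(edges)
build_network <- function(edges, confidence_threshold = 0.7) {
  if (!is.data.frame(edges) || ncol(edges) < 3L) {
    abort("`edges` must be a data frame with at least 3 columns.",
          class = "mirkey_input_error")
  }
  if (!is.numeric(confidence_threshold) || length(confidence_threshold) != 1L ||
      confidence_threshold < 0 || confidence_threshold > 1) {
    abort("`confidence_threshold` must be a single number in [0, 1].",
          class = "mirkey_parameter_error")
  }
  cols <- names(edges)
  a_col <- if ("protein_a" %in% cols) "protein_a" else cols[1L]
  b_col <- if ("protein_b" %in% cols) "protein_b" else cols[2L]
  s_col <- if ("confidence" %in% cols) "confidence" else if ("combined_score" %in% cols) "combined_score" else cols[3L]

  a <- as.character(edges[[a_col]])
  b <- as.character(edges[[b_col]])
  s <- suppressWarnings(as.numeric(edges[[s_col]]))
  bad <- which(is.na(a) | is.na(b) | a == "" | b == "" | !is.finite(s))
  if (length(bad) > 0L) {
    abort(paste0("Malformed edge record at line ", bad[1L], "."),
          class = "mirkey_input_error")
  }
  # STRING dialect: integer combined scores on a 0-999 scale
  if (any(s > 1)) {
    if (any(s < 0 | s > 999)) {
      abort("Confidence scores must lie in [0, 1] or the 0-999 STRING dialect.",
            class = "mirkey_input_error")
    }
    s <- s / 1000
  }
  if (any(s < 0)) {
    abort("Confidence scores must be nonnegative.", class = "mirkey_input_error")
  }

  keep <- a != b & s >= confidence_threshold
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  if (length(a) == 0L) {
    abort("No edges survive the confidence filter: empty network.",
          class = "mirkey_empty_network_error")
  }
  # canonical unordered orientation, then collapse duplicates keeping max
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  df <- tibble(a = lo, b = hi, confidence = s) %>%
    group_by(.data$a, .data$b) %>%
    summarise(confidence = max(.data$confidence), .groups = "drop") %>%
    arrange(.data$a, .data$b)

  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::E(g)$confidence <- df$confidence
  structure(
    list(graph = g, confidence_threshold = confidence_threshold),
    class = "ppi_network"
  )
}

#' @exportS3Method base::print
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "<ppi_network> %d nodes, %d edges (confidence >= %.3g)%s\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    x$confidence_threshold,
    if (!is.null(igraph::V(x$graph)$abundance)) ", with abundances" else ""
  ))
  invisible(x)
}

#' Nodes and edges of a PPI network
#'
#' @param net A `ppi_network`.
#' @return `network_nodes()` returns the node identifiers; `network_edges()`
#'   a tibble with `protein_a`, `protein_b`, `confidence`.
#' @export
network_nodes <- function(net) {
  check_ppi(net)
  igraph::V(net$graph)$name
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  check_ppi(net)
  el <- igraph::as_edgelist(net$graph)
  tibble(protein_a = el[, 1L], protein_b = el[, 2L],
         confidence = igraph::E(net$graph)$confidence)
}

#' Attach protein abundances to a network
#'
#' Abundances are linear-scale expression values used as a proxy for
#' protein concentration.  Non-positive or missing values are floored at
#' `floor` so every node has a positive total concentration.
#'
#' @param net A `ppi_network`.
#' @param abundance A data frame with columns `gene_id` and `abundance`
#'   (linear scale), or a named numeric vector.
#' @param floor Minimum abundance assigned to missing/non-positive entries.
#' @return The network with a node attribute `abundance`.
#' @export
set_abundance <- function(net, abundance, floor = 1e-6) {
  check_ppi(net)
  if (is.data.frame(abundance)) {
    if (!all(c("gene_id", "abundance") %in% names(abundance))) {
      abort("`abundance` needs columns `gene_id` and `abundance`.",
            class = "mirkey_input_error")
    }
    ab <- setNames(as.numeric(abundance$abundance), as.character(abundance$gene_id))
  } else {
    ab <- abundance
  }
  if (any(is.finite(ab) & ab < 0)) {
    abort("Abundances must be nonnegative.", class = "mirkey_input_error")
  }
  nodes <- network_nodes(net)
  vals <- ab[nodes]
  vals[!is.finite(vals) | vals <= 0] <- floor
  igraph::V(net$graph)$abundance <- unname(vals)
  net
}

#' Node degree and neighborhood connectivity
#'
#' Degree is the number of incident edges on the unweighted topology of the
#' filtered graph; neighborhood connectivity is the arithmetic mean of the
#' neighbors' degrees (0 for an isolated node).
#'
#' @param net A `ppi_network`.
#' @param nodes Node identifiers; default all nodes.
#' @return A named numeric vector.
#' @export
node_degree <- function(net, nodes = NULL) {
  check_ppi(net)
  deg <- igraph::degree(net$graph)
  if (is.null(nodes)) return(deg)
  check_nodes(net, nodes)
  deg[nodes]
}

#' @rdname node_degree
#' @export
neighborhood_connectivity <- function(net, nodes = NULL) {
  check_ppi(net)
  g <- net$graph
  deg <- igraph::degree(g)
  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  sums <- as.numeric(adj %*% deg)
  nc <- ifelse(deg > 0, sums / deg, 0)
  names(nc) <- igraph::V(g)$name
  if (is.null(nodes)) return(nc)
  check_nodes(net, nodes)
  nc[nodes]
}

#' Static topological score of a target set
#'
#' The regulatory-capacity score of a miRNA whose targets map to `targets`:
#' mean degree and mean neighborhood connectivity over the in-network
#' targets, each normalized by the corresponding network-wide mean, summed,
#' minus a fixed `offset`.  Targets absent from the network are ignored for
#' the mean but counted in the output.
#'
#' @param net A `ppi_network`.
#' @param targets Character vector of gene identifiers.
#' @param offset Score offset subtracted from the sum of the two normalized
#'   values.  Default 3.3.
#' @return A one-row tibble: `n_targets`, `n_targets_in_network`,
#'   `norm_mean_degree`, `norm_mean_nc`, `static_score`.  When no target is
#'   in the network the score columns are `NA` (undefined marker).
#' @export
static_score <- function(net, targets, offset = 3.3) {
  check_ppi(net)
  targets <- unique(as.character(targets))
  nodes <- network_nodes(net)
  inside <- intersect(targets, nodes)
  if (length(inside) == 0L) {
    return(tibble(
      n_targets = length(targets), n_targets_in_network = 0L,
      norm_mean_degree = NA_real_, norm_mean_nc = NA_real_,
      static_score = NA_real_
    ))
  }
  deg <- node_degree(net)
  nc <- neighborhood_connectivity(net)
  nmd <- mean(deg[inside]) / mean(deg)
  nmn <- mean(nc[inside]) / mean(nc)
  tibble(
    n_targets = length(targets), n_targets_in_network = length(inside),
    norm_mean_degree = nmd, norm_mean_nc = nmn,
    static_score = nmd + nmn - offset
  )
}

#' Static scores for every miRNA of a target map
#'
#' @param net A `ppi_network`.
#' @param target_map A data frame with columns `mirna_id`, `gene_id` (and
#'   optionally `evidence`, `p_value`).
#' @param offset Passed to [static_score()].
#' @param cutoff Scores strictly above this are flagged `enhanced`.
#'   Default 0.6.
#' @return A tibble with one row per miRNA: the [static_score()] columns
#'   plus `enhanced` (`NA` when the score is undefined).
#' @export
static_scores <- function(net, target_map, offset = 3.3, cutoff = 0.6) {
  check_target_map(target_map)
  target_map %>%
    group_by(mirna_id = as.character(.data$mirna_id)) %>%
    summarise(targets = list(unique(as.character(.data$gene_id))), .groups = "drop") %>%
    mutate(score = purrr::map(.data$targets, ~static_score(net, .x, offset = offset))) %>%
    select(-"targets") %>%
    tidyr::unnest("score") %>%
    mutate(enhanced = .data$static_score > cutoff)
}

#' Combine enhancement flags across two networks
#'
#' A miRNA shows strengthened regulation overall when its static score
#' exceeds the cutoff on both networks.  miRNAs whose score is undefined on
#' either network are flagged not evaluable.
#'
#' @param records_net1,records_net2 Outputs of [static_scores()] on the two
#'   networks.  `records_net2` may be `NULL`, in which case `enhanced_both`
#'   degrades to the single-network flag.
#' @param cutoff Enhancement cutoff (strict).  Default 0.6.
#' @return A tibble with `mirna_id`, `enhanced_net1`, `enhanced_net2`,
#'   `enhanced_both`, `evaluable`.
#' @export
classify_enhanced <- function(records_net1, records_net2 = NULL, cutoff = 0.6) {
  r1 <- records_net1 %>%
    select("mirna_id", score1 = "static_score") %>%
    mutate(enhanced_net1 = .data$score1 > cutoff)
  if (is.null(records_net2)) {
    return(r1 %>%
      mutate(enhanced_net2 = NA, enhanced_both = .data$enhanced_net1,
             evaluable = !is.na(.data$score1)) %>%
      select("mirna_id", "enhanced_net1", "enhanced_net2", "enhanced_both", "evaluable"))
  }
  r2 <- records_net2 %>%
    select("mirna_id", score2 = "static_score") %>%
    mutate(enhanced_net2 = .data$score2 > cutoff)
  dplyr::full_join(r1, r2, by = "mirna_id") %>%
    mutate(
      evaluable = !is.na(.data$score1) & !is.na(.data$score2),
      enhanced_both = ifelse(.data$evaluable,
                             .data$enhanced_net1 & .data$enhanced_net2, NA)
    ) %>%
    select("mirna_id", "enhanced_net1", "enhanced_net2", "enhanced_both", "evaluable")
}

#' Fraction of credible target records per miRNA
#'
#' The fraction of a miRNA's target records that are experimentally
#' validated or predicted with a prediction p-value below `p_cutoff`.
#'
#' @param target_map A data frame with columns `mirna_id`, `gene_id`,
#'   `evidence` (`"validated"` or `"predicted"`) and `p_value` (`NA` for
#'   validated records).
#' @param p_cutoff Prediction p-value cutoff (strict).  Default 0.01.
#' @return A tibble with `mirna_id`, `n_targets`, `credible_fraction`.
#' @export
target_confidence_summary <- function(target_map, p_cutoff = 0.01) {
  check_target_map(target_map)
  if (nrow(target_map) == 0L) {
    abort("Credible-target fraction is undefined for an empty target map.",
          class = "mirkey_undefined_error")
  }
  if (!all(c("evidence", "p_value") %in% names(target_map))) {
    abort("`target_map` needs `evidence` and `p_value` columns.",
          class = "mirkey_input_error")
  }
  target_map %>%
    group_by(mirna_id = as.character(.data$mirna_id)) %>%
    summarise(
      n_targets = dplyr::n(),
      credible_fraction = mean(
        .data$evidence == "validated" |
          (.data$evidence == "predicted" & !is.na(.data$p_value) & .data$p_value < p_cutoff)
      ),
      .groups = "drop"
    )
}

#' Subnetwork induced by a node set
#'
#' @param net A `ppi_network`.
#' @param nodes Node identifiers (unknown ones are ignored).
#' @return A `ppi_network` restricted to `nodes` and the edges among them.
#' @export
induced_subnetwork <- function(net, nodes) {
  check_ppi(net)
  keep <- intersect(unique(as.character(nodes)), network_nodes(net))
  g <- igraph::induced_subgraph(net$graph, keep)
  structure(list(graph = g, confidence_threshold = net$confidence_threshold),
            class = "ppi_network")
}

# ---- internal -------------------------------------------------------------

check_ppi <- function(net) {
  if (!inherits(net, "ppi_network")) {
    abort("Expected a `ppi_network` object.", class = "mirkey_input_error")
  }
  invisible(net)
}

check_nodes <- function(net, nodes) {
  unknown <- setdiff(nodes, igraph::V(net$graph)$name)
  if (length(unknown) > 0L) {
    abort(paste0("Unknown node(s): ", paste(head(unknown, 3L), collapse = ", "), "."),
          class = "mirkey_lookup_error")
  }
  invisible(nodes)
}

check_target_map <- function(target_map) {
  if (!is.data.frame(target_map) || !all(c("mirna_id", "gene_id") %in% names(target_map))) {
    abort("`target_map` must be a data frame with `mirna_id` and `gene_id` columns.",
          class = "mirkey_input_error")
  }
  invisible(target_map)
}
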