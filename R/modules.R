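#' Cohesiveness of a vertex set
#'
#' The overlapping-clustering objective
#' `w_in / (w_in + w_bound + penalty * |V|)`, where `w_in` is the total
#' confidence weight of edges with both endpoints in the set and `w_bound`
#' the total weight of edges with exactly one endpoint inside.  The penalty
#' term models unobserved external interactions of each member.
#'
#' @param net A `ppi_network`.
#' @param members Non-empty character vector of member nodes.
#' @param penalty Per-node penalty weight.  Default 2.
#' @return A number in \[0, 1\] (0 for a set with no internal weight).
#' @export
cohesiveness <- function(net, members, penalty = 2) {
  check_ppi(net)
  members <- unique(as.character(members))
  if (length(members) == 0L) {
    abort("`members` must be non-empty.", class = "mirkey_parameter_error")
  }
  check_nodes(net, members)
  el <- network_edges(net)
  a_in <- el$protein_a %in% members
  b_in <- el$protein_b %in% members
  w_in <- sum(el$confidence[a_in & b_in])
  w_bound <- sum(el$confidence[xor(a_in, b_in)])
  denom <- w_in + w_bound + penalty * length(members)
  if (denom == 0) 0 else w_in / denom
}

#' Greedy cohesive cluster growth from a seed node
#'
#' Starting from the singleton seed, repeatedly applies the single
#' add-a-boundary-node or remove-a-member move that most increases
#' cohesiveness, stopping when no move gives a strict increase.
#' Deterministic: ties prefer the higher new cohesiveness, then additions
#' over removals, then the lexicographically smallest node.
#'
#' @inheritParams cohesiveness
#' @param seed A node identifier.
#' @return Character vector of member nodes (sorted).
#' @export
grow_cluster <- function(net, seed, penalty = 2) {
  check_ppi(net)
  seed <- as.character(seed)
  check_nodes(net, seed)
  g <- net$graph
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  adj <- igraph::as_adjacency_matrix(g, attr = "confidence", sparse = TRUE)
  strength <- as.numeric(Matrix::rowSums(adj))
  names(strength) <- nodes

  in_set <- setNames(logical(n), nodes)
  in_set[seed] <- TRUE
  # w_to[x]: total edge weight from x to current members (excluding x itself)
  w_to <- as.numeric(adj[, seed])
  names(w_to) <- nodes
  w_in <- 0
  w_bound <- strength[seed]
  size <- 1L

  coh <- function(wi, wb, sz) {
    d <- wi + wb + penalty * sz
    if (d == 0) 0 else wi / d
  }
  current <- coh(w_in, w_bound, size)

  repeat {
    add_cand <- names(which(!in_set & w_to > 0))
    best_val <- current
    best_node <- NA_character_
    best_action <- ""
    if (length(add_cand) > 0L) {
      wi <- w_in + w_to[add_cand]
      wb <- w_bound - 2 * w_to[add_cand] + strength[add_cand]
      vals <- wi / pmax(wi + wb + penalty * (size + 1L), .Machine$double.xmin)
      o <- order(-vals, add_cand)
      if (vals[o[1L]] > best_val + 1e-12) {
        best_val <- vals[o[1L]]; best_node <- add_cand[o[1L]]; best_action <- "add"
      }
    }
    if (size > 1L) {
      rem_cand <- names(which(in_set))
      wi <- w_in - w_to[rem_cand]
      wb <- w_bound + 2 * w_to[rem_cand] - strength[rem_cand]
      vals <- wi / pmax(wi + wb + penalty * (size - 1L), .Machine$double.xmin)
      o <- order(-vals, rem_cand)
      if (vals[o[1L]] > best_val + 1e-12) {
        best_val <- vals[o[1L]]; best_node <- rem_cand[o[1L]]; best_action <- "remove"
      }
    }
    if (is.na(best_node)) break
    u_w <- as.numeric(adj[, best_node])
    if (best_action == "add") {
      w_in <- w_in + w_to[[best_node]]
      w_bound <- w_bound - 2 * w_to[[best_node]] + strength[[best_node]]
      in_set[best_node] <- TRUE
      w_to <- w_to + u_w
      size <- size + 1L
    } else {
      w_in <- w_in - w_to[[best_node]]
      w_bound <- w_bound + 2 * w_to[[best_node]] - strength[[best_node]]
      in_set[best_node] <- FALSE
      w_to <- w_to - u_w
      size <- size - 1L
    }
    current <- best_val
  }
  sort(names(which(in_set)))
}

#' Overlapping module discovery by cohesive cluster growth
#'
#' Re-implementation of cohesiveness-based overlapping clustering: clusters
#' are grown greedily (see [grow_cluster()]) from seeds taken in decreasing
#' degree order over nodes not yet covered by an earlier cluster;
#' near-duplicate clusters with overlap score
#' `omega(A, B) = |A intersect B|^2 / (|A| * |B|) >= overlap_merge` are
#' merged (union); clusters below the minimum size or internal weighted
#' density are discarded.
#'
#' @inheritParams cohesiveness
#' @param min_size Minimum module size.  Default 3.
#' @param min_density Minimum internal density: total internal edge weight
#'   divided by the number of member pairs.  Default 0.5.
#' @param overlap_merge Overlap-score merge threshold.  Default 0.8.
#' @return A tibble of modules sorted largest first: `module_id`, `members`
#'   (list column, sorted), `size`, `cohesiveness`, `density`.
#' @export
cluster_one <- function(net, penalty = 2, min_size = 3, min_density = 0.5,
                        overlap_merge = 0.8) {
  check_ppi(net)
  nodes <- network_nodes(net)
  if (length(nodes) == 0L) {
    return(empty_modules())
  }
  deg <- node_degree(net)
  seeds <- nodes[order(-deg, nodes)]
  covered <- character(0)
  clusters <- list()
  for (s in seeds) {
    if (s %in% covered) next
    cl <- grow_cluster(net, s, penalty = penalty)
    clusters[[length(clusters) + 1L]] <- cl
    covered <- union(covered, cl)
  }
  clusters <- unique(clusters)

  # iterative merge of highly overlapping clusters
  repeat {
    if (length(clusters) < 2L) break
    merged <- FALSE
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        ov <- overlap_score(clusters[[i]], clusters[[j]])
        if (ov >= overlap_merge) {
          clusters[[i]] <- sort(union(clusters[[i]], clusters[[j]]))
          clusters[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }

  rows <- purrr::map_dfr(clusters, function(cl) {
    sz <- length(cl)
    tibble(members = list(sort(cl)), size = sz,
           cohesiveness = cohesiveness(net, cl, penalty = penalty),
           density = internal_density(net, cl))
  })
  rows <- rows %>%
    filter(.data$size >= min_size, .data$density >= min_density) %>%
    arrange(desc(.data$size), desc(.data$cohesiveness),
            purrr::map_chr(.data$members, 1L)) %>%
    mutate(module_id = paste0("M", row_number()), .before = 1L)
  if (nrow(rows) == 0L) empty_modules() else rows
}

#' Overlap score between two node sets
#'
#' @param a,b Character vectors.
#' @return `|a intersect b|^2 / (|a| * |b|)`.
#' @export
overlap_score <- function(a, b) {
  length(intersect(a, b))^2 / (length(a) * length(b))
}

#' Select the largest module
#'
#' Ties are broken by higher cohesiveness, then by the lexicographically
#' smallest member.
#'
#' @param modules Output of [cluster_one()] (non-empty).
#' @return A one-row tibble.
#' @export
largest_module <- function(modules) {
  if (is.null(modules) || nrow(modules) == 0L) {
    abort("No modules to select from.", class = "mirkey_not_found_error")
  }
  modules %>%
    arrange(desc(.data$size), desc(.data$cohesiveness),
            purrr::map_chr(.data$members, 1L)) %>%
    head(1L)
}

#' Gene-set enrichment of a module by the hypergeometric test
#'
#' For each gene set, the upper-tail hypergeometric p-value of the overlap
#' between the module members and the set, drawing `|module|` genes from the
#' universe with `|set intersect universe|` successes, adjusted across sets
#' by Benjamini-Hochberg.
#'
#' @param members Character vector of module members (must lie in
#'   `universe`).
#' @param gene_sets A named list of character vectors (e.g. from
#'   [read_gmt()]) or a tibble with `set_id` and `genes` list column.
#' @param universe Character vector: the enrichment universe, normally all
#'   network nodes.
#' @return A tibble: `set_id`, `set_size` (in universe), `overlap`,
#'   `p_value`, `adjusted_p`, sorted by p-value.
#' @export
enrich_module <- function(members, gene_sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) {
    abort("`universe` must be non-empty.", class = "mirkey_parameter_error")
  }
  members <- unique(as.character(members))
  if (!all(members %in% universe)) {
    abort("All module members must lie in the universe.", class = "mirkey_input_error")
  }
  sets <- as_gene_set_list(gene_sets)
  n_univ <- length(universe)
  n_mod <- length(members)
  res <- purrr::imap_dfr(sets, function(genes, id) {
    in_univ <- intersect(unique(genes), universe)
    k <- length(intersect(members, in_univ))
    tibble(
      set_id = id, set_size = length(in_univ), overlap = k,
      p_value = phyper(k - 1L, length(in_univ), n_univ - length(in_univ),
                       n_mod, lower.tail = FALSE)
    )
  })
  res %>%
    mutate(adjusted_p = p.adjust(.data$p_value, method = "BH")) %>%
    arrange(.data$p_value, .data$set_id)
}

#' Modules and enrichment for each miRNA's target subnetwork
#'
#' For each miRNA, takes the subgraph induced by its in-network target
#' genes, discovers modules with [cluster_one()], keeps the largest, and
#' scores it against the gene sets over the whole-network universe.
#'
#' @param net A `ppi_network`.
#' @param target_map Data frame with `mirna_id`, `gene_id`.
#' @param gene_sets As in [enrich_module()].
#' @param mirnas Optional subset of miRNA ids to process (default all).
#' @inheritParams cluster_one
#' @return A list with `modules` (per-miRNA largest module; zero rows for
#'   miRNAs without one) and `enrichment` (per-miRNA, per-set).
#' @export
mirna_modules <- function(net, target_map, gene_sets, mirnas = NULL,
                          penalty = 2, min_size = 3, min_density = 0.5,
                          overlap_merge = 0.8) {
  check_ppi(net)
  check_target_map(target_map)
  universe <- network_nodes(net)
  by_mirna <- split(as.character(target_map$gene_id), as.character(target_map$mirna_id))
  if (!is.null(mirnas)) by_mirna <- by_mirna[intersect(names(by_mirna), mirnas)]
  mods <- list(); enr <- list()
  for (id in names(by_mirna)) {
    sub <- induced_subnetwork(net, by_mirna[[id]])
    found <- cluster_one(sub, penalty = penalty, min_size = min_size,
                         min_density = min_density, overlap_merge = overlap_merge)
    if (nrow(found) == 0L) next
    top <- largest_module(found) %>% mutate(mirna_id = id, .before = 1L)
    mods[[id]] <- top
    enr[[id]] <- enrich_module(top$members[[1L]], gene_sets, universe) %>%
      mutate(mirna_id = id, .before = 1L)
  }
  list(
    modules = if (length(mods)) bind_rows(mods) else
      mutate(empty_modules(), mirna_id = character(0), .before = 1L),
    enrichment = if (length(enr)) bind_rows(enr) else
      tibble(mirna_id = character(0), set_id = character(0),
             set_size = integer(0), overlap = integer(0),
             p_value = double(0), adjusted_p = double(0))
  )
}

# ---- internal -------------------------------------------------------------

empty_modules <- function() {
  tibble(module_id = character(0), members = list(), size = integer(0),
         cohesiveness = double(0), density = double(0))
}

internal_density <- function(net, members) {
  n <- length(members)
  if (n < 2L) return(0)
  el <- network_edges(net)
  w_in <- sum(el$confidence[el$protein_a %in% members & el$protein_b %in% members])
  w_in / (n * (n - 1) / 2)
}

as_gene_set_list <- function(gene_sets) {
  if (is.data.frame(gene_sets)) {
    if (!all(c("set_id", "genes") %in% names(gene_sets))) {
      abort("Gene-set tibble needs `set_id` and `genes` columns.",
            class = "mirkey_input_error")
    }
    return(setNames(gene_sets$genes, gene_sets$set_id))
  }
  if (!is.list(gene_sets) || is.null(names(gene_sets))) {
    abort("`gene_sets` must be a named list or a tibble.", class = "mirkey_input_error")
  }
  gene_sets
}
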