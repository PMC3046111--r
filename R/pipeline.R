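#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis with the published
#' defaults: the dysregulation threshold (log2 0.5), reversal fold (1.5),
#' edge confidence threshold (0.7), static-score offset (3.3) and
#' enhancement cutoff (0.6), mass-action association constant (1),
#' perturbation folds (0.5 repress / 2 de-repress), subgroup thresholds
#' (1.2, 2.0), clustering parameters, and the target-credibility p cutoff
#' (0.01).
#'
#' @param dysregulation_threshold,fold_threshold Expression-stage
#'   thresholds.
#' @param confidence_threshold Edge confidence cutoff.
#' @param static_offset,static_cutoff Static-score constants.
#' @param K,fold_up,fold_down,subgroup_thresholds,equil_tol,max_iter,damping
#'   Perturbation-stage parameters.
#' @param penalty,min_size,min_density,overlap_merge Clustering parameters.
#' @param p_cutoff Target-credibility cutoff.
#' @param groups Optional group-label remapping (see
#'   [detect_dysregulated()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dysregulation_threshold = 0.5, fold_threshold = 1.5,
                            confidence_threshold = 0.7, static_offset = 3.3,
                            static_cutoff = 0.6, K = 1, fold_up = 0.5,
                            fold_down = 2, subgroup_thresholds = c(1.2, 2),
                            equil_tol = 1e-10, max_iter = 10000, damping = 0.5,
                            penalty = 2, min_size = 3, min_density = 0.5,
                            overlap_merge = 0.8, p_cutoff = 0.01, groups = NULL) {
  cfg <- as.list(environment())
  stopifnot(dysregulation_threshold > 0, fold_threshold > 1,
            confidence_threshold >= 0, confidence_threshold <= 1,
            static_cutoff >= 0, K >= 0, fold_up > 0, fold_down > 0,
            all(subgroup_thresholds >= 1), min_size >= 1,
            p_cutoff > 0, p_cutoff <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Run the full key-miRNA prioritization pipeline
#'
#' Executes every stage on tabular inputs: dysregulation and drug-reversal
#' classification, static topological scoring on the confidence-filtered
#' PPI network (two networks when `edges2` is given), mass-action
#' perturbation scoring, between-group similarity, the dynamic-score versus
#' target-abundance correlation, per-miRNA module discovery with gene-set
#' enrichment, and the final ranking.  The run is a pure function of its
#' inputs and configuration.
#'
#' @param expression Four-group expression table (see
#'   [detect_dysregulated()]).
#' @param edges Weighted PPI edge list (see [build_network()]).
#' @param target_map miRNA -> target-gene records with `evidence` and
#'   `p_value`.
#' @param abundance Per-gene linear abundance table (`gene_id`,
#'   `abundance`).
#' @param gene_sets Named list of gene-id vectors (e.g. [read_gmt()]).
#' @param edges2 Optional second edge list; when absent, the two-network
#'   enhancement flag degrades to the single-network flag.
#' @param config A [pipeline_config()].
#' @return A `mirna_report`: list with `scores` (one row per miRNA),
#'   `similarity`, `correlation`, `modules`, `enrichment`, `ranking`,
#'   `manifest`.
#' @export
run_pipeline <- function(expression, edges, target_map, abundance, gene_sets,
                         edges2 = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))

  # expression stage
  calls <- detect_dysregulated(expression, threshold = config$dysregulation_threshold,
                               groups = config$groups)
  calls <- identify_prmirs(calls, expression, fold_threshold = config$fold_threshold,
                           groups = config$groups)
  dmirs <- calls$mirna_id[calls$is_dysregulated]

  # network stage
  net1 <- build_network(edges, confidence_threshold = config$confidence_threshold)
  if (!any(as.character(target_map$gene_id) %in% network_nodes(net1))) {
    abort(paste0(
      "Identifier spaces do not overlap: no target gene appears in the network ",
      "(examples: ",
      paste(head(unique(as.character(target_map$gene_id)), 3L), collapse = ", "),
      " vs ", paste(head(network_nodes(net1), 3L), collapse = ", "), ")."
    ), class = "mirkey_input_error")
  }
  net1 <- set_abundance(net1, abundance)
  static1 <- static_scores(net1, target_map, offset = config$static_offset,
                           cutoff = config$static_cutoff)
  static2 <- NULL
  if (!is.null(edges2)) {
    net2 <- build_network(edges2, confidence_threshold = config$confidence_threshold)
    static2 <- static_scores(net2, target_map, offset = config$static_offset,
                             cutoff = config$static_cutoff)
  }
  enhanced <- classify_enhanced(static1, static2, cutoff = config$static_cutoff)

  # dynamic stage (dysregulated miRNAs are the ones under study)
  dyn <- score_mirna_dynamics(
    net1, target_map %>% filter(as.character(.data$mirna_id) %in% dmirs),
    calls = calls, fold_up = config$fold_up, fold_down = config$fold_down,
    thresholds = config$subgroup_thresholds, K = config$K,
    tol = config$equil_tol, max_iter = config$max_iter, damping = config$damping
  )

  similarity <- similarity_matrix(expression, dmirs, groups = config$groups)
  correlation <- correlate_scores(dyn$dynamic_score, dyn$mean_log2_abundance)
  credibility <- target_confidence_summary(target_map, p_cutoff = config$p_cutoff)

  # module stage: drug-reversed miRNAs with enhanced regulation
  focus <- calls$mirna_id[calls$is_prmir]
  focus <- intersect(focus, enhanced$mirna_id[enhanced$enhanced_both %in% TRUE])
  mod <- mirna_modules(net1, target_map, gene_sets, mirnas = focus,
                       penalty = config$penalty, min_size = config$min_size,
                       min_density = config$min_density,
                       overlap_merge = config$overlap_merge)

  top_enrichment <- mod$enrichment %>%
    group_by(.data$mirna_id) %>%
    dplyr::slice_min(.data$adjusted_p, n = 1L, with_ties = FALSE) %>%
    ungroup() %>%
    select("mirna_id", top_set = "set_id", top_overlap = "overlap",
           top_adjusted_p = "adjusted_p")

  scores <- calls %>%
    left_join(static1 %>% select("mirna_id", static_score_net1 = "static_score"),
              by = "mirna_id") %>%
    {
      if (!is.null(static2)) {
        left_join(., static2 %>% select("mirna_id", static_score_net2 = "static_score"),
                  by = "mirna_id")
      } else mutate(., static_score_net2 = NA_real_)
    } %>%
    left_join(enhanced %>% select("mirna_id", "enhanced_net1", "enhanced_net2",
                                  "enhanced_both"), by = "mirna_id") %>%
    left_join(dyn %>% select("mirna_id", "n_targets_in_network", "dynamic_score",
                             "mean_log2_abundance"), by = "mirna_id") %>%
    left_join(credibility %>% select("mirna_id", "credible_fraction"),
              by = "mirna_id") %>%
    left_join(mod$modules %>% select("mirna_id", module_size = "size",
                                     module_cohesiveness = "cohesiveness"),
              by = "mirna_id") %>%
    left_join(top_enrichment, by = "mirna_id")

  ranking <- rank_key_mirnas(scores)

  report <- structure(
    list(
      scores = scores,
      similarity = similarity,
      correlation = correlation,
      modules = mod$modules,
      enrichment = mod$enrichment,
      ranking = ranking,
      manifest = list(
        config = unclass(config),
        input_hashes = list(
          expression = rlang::hash(expression), edges = rlang::hash(edges),
          target_map = rlang::hash(target_map), abundance = rlang::hash(abundance),
          gene_sets = rlang::hash(gene_sets),
          edges2 = if (is.null(edges2)) NULL else rlang::hash(edges2)
        ),
        n_networks = if (is.null(edges2)) 1L else 2L
      )
    ),
    class = "mirna_report"
  )
  report
}

#' Rank candidate key miRNAs
#'
#' Codifies the narrative prioritization as an explicit filter-then-sort:
#' keep drug-reversed miRNAs with enhanced static regulation (on both
#' networks when two were scored), then order by the disease-set enrichment
#' of the largest regulated module (smaller adjusted p first; miRNAs
#' without a module rank last) and by dynamic score (larger first), with
#' deterministic ties on the identifier.
#'
#' @param scores The per-miRNA score table of a [run_pipeline()] report
#'   (columns `is_prmir`, `enhanced_both`, `top_adjusted_p`,
#'   `dynamic_score`).
#' @return The filtered, ordered tibble with a `rank` column (possibly
#'   empty, with a warning).
#' @export
rank_key_mirnas <- function(scores) {
  kept <- scores %>%
    filter(.data$is_prmir %in% TRUE, .data$enhanced_both %in% TRUE)
  if (nrow(kept) == 0L) {
    warning("No drug-reversed miRNA with enhanced regulation: empty ranking.")
    return(kept %>% mutate(rank = integer(0)))
  }
  kept %>%
    mutate(
      ..p_order = ifelse(is.na(.data$top_adjusted_p), Inf, .data$top_adjusted_p),
      ..d_order = ifelse(is.na(.data$dynamic_score), -Inf, .data$dynamic_score)
    ) %>%
    arrange(.data$..p_order, desc(.data$..d_order), .data$mirna_id) %>%
    select(-"..p_order", -"..d_order") %>%
    mutate(rank = row_number(), .before = 1L)
}

#' @exportS3Method base::print
print.mirna_report <- function(x, ...) {
  s <- x$scores
  cat(sprintf(
    "<mirna_report> %d miRNAs: %d dysregulated, %d drug-reversed, %d enhanced; %d ranked candidates\n",
    nrow(s), sum(s$is_dysregulated), sum(s$is_prmir),
    sum(s$enhanced_both %in% TRUE), nrow(x$ranking)
  ))
  if (nrow(x$ranking) > 0L) {
    cat("Top candidates:", paste(head(x$ranking$mirna_id, 3L), collapse = ", "), "\n")
  }
  cat(sprintf("Dynamic score ~ mean log2 target abundance: r = %.3f, p = %.3g\n",
              x$correlation$r, x$correlation$p_value))
  invisible(x)
}
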