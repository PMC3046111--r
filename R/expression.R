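#' Classify dysregulated miRNAs from a four-group expression table
#'
#' A miRNA is called dysregulated when its log2 expression in the disease
#' group deviates from the control group by at least `threshold` log2 units
#' (the boundary counts as dysregulated).  The design is pooled: one value
#' per group per miRNA, no replicate statistics.
#'
#' @param data A data frame with one row per miRNA: a `mirna_id` column and
#'   one numeric log2-expression column per group.
#' @param threshold Dysregulation threshold in log2 units (> 0).  Default 0.5.
#' @param groups Named character vector mapping the canonical group labels
#'   (`control`, `disease`, `disease_drug`, `drug_only`) to column names in
#'   `data`.  Defaults to identity.
#'
#' @return A tibble with columns `mirna_id`, `delta_disease` (log2 deviation
#'   of disease from control), `direction` (`"up"`, `"down"` or `"none"`) and
#'   `is_dysregulated`.
#' @seealso [identify_prmirs()], [expression_similarity()]
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   mirna_id = c("miR-a", "miR-b"),
#'   control = c(8, 8), disease = c(8.6, 8.1),
#'   disease_drug = c(8.0, 8.1), drug_only = c(8, 8)
#' )
#' detect_dysregulated(tab)
detect_dysregulated <- function(data, threshold = 0.5, groups = NULL) {
  groups <- check_groups(data, groups)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort("`threshold` must be a single positive number.", class = "mirkey_parameter_error")
  }
  check_expression_values(data, groups)
  delta <- data[[groups[["disease"]]]] - data[[groups[["control"]]]]
  tibble(
    mirna_id = as.character(data$mirna_id),
    delta_disease = delta,
    direction = dplyr::case_when(
      delta >= threshold ~ "up",
      delta <= -threshold ~ "down",
      TRUE ~ "none"
    ),
    is_dysregulated = abs(delta) >= threshold
  )
}

#' Identify drug-reversed miRNAs (PRmiRs)
#'
#' Among the dysregulated miRNAs, flags those whose expression under drug
#' treatment moves back from the disease level toward the control level by
#' more than a linear fold-change threshold: the miRNA is a PRmiR when it is
#' dysregulated, the disease+drug value lies on the control side of the
#' disease value, and `2^|disease_drug - disease| > fold_threshold`.
#'
#' @param calls Output of [detect_dysregulated()] on the same table.
#' @param data The expression table the calls were derived from.
#' @param fold_threshold Linear fold-change threshold (> 1).  Default 1.5.
#' @inheritParams detect_dysregulated
#'
#' @return `calls` with added columns `reversal_fold` (linear fold change of
#'   disease+drug versus disease, oriented to be >= 1), `toward_control` and
#'   `is_prmir`.
#' @export
identify_prmirs <- function(calls, data, fold_threshold = 1.5, groups = NULL) {
  groups <- check_groups(data, groups)
  if (!is.numeric(fold_threshold) || length(fold_threshold) != 1L || fold_threshold <= 1) {
    abort("`fold_threshold` must be a single number greater than 1.",
          class = "mirkey_parameter_error")
  }
  need <- c("mirna_id", "delta_disease", "is_dysregulated")
  if (!all(need %in% names(calls))) {
    abort("`calls` must come from detect_dysregulated().", class = "mirkey_input_error")
  }
  idx <- match(calls$mirna_id, as.character(data$mirna_id))
  if (anyNA(idx)) {
    abort("`calls` contains miRNAs absent from `data`.", class = "mirkey_input_error")
  }
  disease <- data[[groups[["disease"]]]][idx]
  drug <- data[[groups[["disease_drug"]]]][idx]
  control <- data[[groups[["control"]]]][idx]
  shift <- drug - disease
  calls %>%
    mutate(
      reversal_fold = 2^abs(shift),
      toward_control = sign(shift) == sign(control - disease) & shift != 0,
      is_prmir = .data$is_dysregulated & .data$toward_control &
        .data$reversal_fold > fold_threshold
    )
}

#' Between-group expression similarity over the dysregulated set
#'
#' Pearson correlation of the deviation-from-control vectors
#' (`value_group - value_control`) of two groups, restricted to a given set
#' of dysregulated miRNAs.  Symmetric in the two groups and bounded in
#' \[-1, 1\].
#'
#' @inheritParams detect_dysregulated
#' @param group_a,group_b Canonical group labels to compare.
#' @param dmirs Character vector of miRNA ids (the dysregulated set); at
#'   least 3 required.
#'
#' @return A single number in \[-1, 1\].
#' @export
expression_similarity <- function(data, group_a, group_b, dmirs, groups = NULL) {
  groups <- check_groups(data, groups)
  for (g in c(group_a, group_b)) {
    if (!g %in% names(groups)) {
      abort(paste0("Unknown group label: '", g, "'."), class = "mirkey_input_error")
    }
  }
  if (length(dmirs) < 3L) {
    abort("Similarity is undefined for fewer than 3 miRNAs.",
          class = "mirkey_undefined_error")
  }
  idx <- match(dmirs, as.character(data$mirna_id))
  if (anyNA(idx)) {
    abort("`dmirs` contains miRNAs absent from `data`.", class = "mirkey_input_error")
  }
  ctrl <- data[[groups[["control"]]]][idx]
  a <- data[[groups[[group_a]]]][idx] - ctrl
  b <- data[[groups[[group_b]]]][idx] - ctrl
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("Similarity is undefined: a deviation vector has zero variance.",
          class = "mirkey_undefined_error")
  }
  cor(a, b)
}

#' Pairwise similarity matrix between treatment groups
#'
#' Applies [expression_similarity()] to every pair of non-control groups,
#' the standard companion display to the dysregulation calls.
#'
#' @inheritParams expression_similarity
#' @param compare Canonical labels of the groups to compare pairwise;
#'   defaults to the three non-control groups.
#'
#' @return A tibble with columns `group_a`, `group_b`, `similarity`.
#' @export
similarity_matrix <- function(data, dmirs, compare = c("disease", "disease_drug", "drug_only"),
                              groups = NULL) {
  pairs <- t(utils::combn(compare, 2L))
  purrr::map2_dfr(pairs[, 1L], pairs[, 2L], function(a, b) {
    tibble(group_a = a, group_b = b,
           similarity = expression_similarity(data, a, b, dmirs, groups = groups))
  })
}

# ---- internal -------------------------------------------------------------

check_groups <- function(data, groups) {
  if (is.null(groups)) groups <- setNames(.mirkey_groups, .mirkey_groups)
  if (is.null(names(groups))) names(groups) <- .mirkey_groups
  missing_canon <- setdiff(.mirkey_groups, names(groups))
  if (length(missing_canon) > 0L) {
    abort(paste0("`groups` must map the canonical labels; missing: ",
                 paste(missing_canon, collapse = ", "), "."),
          class = "mirkey_input_error")
  }
  if (!"mirna_id" %in% names(data)) {
    abort("`data` must have a `mirna_id` column.", class = "mirkey_input_error")
  }
  absent <- groups[!groups %in% names(data)]
  if (length(absent) > 0L) {
    abort(paste0("Expression table is missing group column(s): ",
                 paste(sprintf("'%s' (%s)", absent, names(absent)), collapse = ", "), "."),
          class = "mirkey_input_error")
  }
  groups
}

check_expression_values <- function(data, groups) {
  for (g in groups) {
    v <- data[[g]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      abort(paste0("Expression values in column '", g, "' must be finite numbers."),
            class = "mirkey_input_error")
    }
  }
  invisible(TRUE)
}
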