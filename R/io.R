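#' Read and write the pipeline's tabular input formats
#'
#' Thin TSV readers/writers for the standard inputs: the four-group
#' expression table (`mirna_id`, `control`, `disease`, `disease_drug`,
#' `drug_only`), the weighted edge list (`protein_a`, `protein_b`,
#' `confidence` or STRING-style `combined_score`), the target map
#' (`mirna_id`, `gene_id`, `evidence`, `p_value`; `p_value` empty for
#' validated records), and the abundance table (`gene_id`, `abundance`).
#'
#' @param path File path.
#' @return A tibble.
#' @name mirkey-io
NULL

#' @rdname mirkey-io
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"mirna_id" %in% names(df)) {
    abort("Expression TSV must have a `mirna_id` column.", class = "mirkey_input_error")
  }
  df
}

#' @rdname mirkey-io
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname mirkey-io
#' @export
read_target_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(p_value = readr::col_double(),
                                                .default = readr::col_character()))
  check_target_map(df)
  df
}

#' @rdname mirkey-io
#' @export
read_abundance_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "abundance") %in% names(df))) {
    abort("Abundance TSV needs `gene_id` and `abundance` columns.",
          class = "mirkey_input_error")
  }
  df
}

#' @rdname mirkey-io
#' @param x A data frame to write.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' `read_gmt()` wraps `fgsea::gmtPathways()` and returns a named list of
#' gene-id vectors; `write_gmt()` writes one set per line
#' (`set_id<TAB>description<TAB>gene...`).
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @return `read_gmt()`: a named list; `write_gmt()`: the path, invisibly.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets))) {
    abort("`sets` must be a named list.", class = "mirkey_input_error")
  }
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated study to a directory
#'
#' Writes the expression, edge-list, target, and abundance TSVs, the GMT
#' gene sets, and a JSON truth/metadata file (including the seed) so a
#' simulated study can round-trip through the file-based interface.
#'
#' @param study An `mi_study` from [simulate_mi_study()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_mi_study <- function(study, dir) {
  stopifnot(inherits(study, "mi_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_table(study$expression, file.path(dir, "expression.tsv"))
  write_tsv_table(study$edges, file.path(dir, "edges.tsv"))
  write_tsv_table(study$target_map, file.path(dir, "targets.tsv"))
  write_tsv_table(study$abundance, file.path(dir, "abundance.tsv"))
  write_gmt(study$gene_sets, file.path(dir, "gene_sets.gmt"))
  truth <- study$truth
  jsonlite::write_json(
    list(
      rng_seed = truth$rng_seed,
      planted_dysregulated = truth$planted_dysregulated,
      planted_prmirs = truth$planted_prmirs,
      planted_key_mirnas = truth$planted_key_mirnas,
      planted_modules = truth$planted_modules,
      planted_disease_genes = truth$planted_disease_genes,
      effects = truth$effects
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
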