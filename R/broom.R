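#' Tidy a pipeline report
#'
#' @param x A `mirna_report` from [run_pipeline()].
#' @param ... Unused.
#' @return The per-miRNA score table (one row per miRNA).
#' @export
tidy.mirna_report <- function(x, ...) {
  x$scores
}

#' One-row summary of a pipeline report
#'
#' @inheritParams tidy.mirna_report
#' @return A one-row tibble: counts per classification stage, the
#'   dynamic-score/abundance correlation, and the top-ranked miRNA.
#' @export
glance.mirna_report <- function(x, ...) {
  s <- x$scores
  tibble(
    n_mirnas = nrow(s),
    n_dysregulated = sum(s$is_dysregulated),
    n_prmirs = sum(s$is_prmir),
    n_enhanced = sum(s$enhanced_both %in% TRUE),
    n_ranked = nrow(x$ranking),
    top_mirna = if (nrow(x$ranking) > 0L) x$ranking$mirna_id[1L] else NA_character_,
    abundance_cor = x$correlation$r,
    abundance_cor_p = x$correlation$p_value
  )
}

#' Tidy an equilibrium state
#'
#' @param x An `equilibrium_state` from [equilibrate()].
#' @param ... Unused.
#' @return A tibble with `node`, `total`, `free`, `bound`.
#' @export
tidy.equilibrium_state <- function(x, ...) {
  tibble(
    node = names(x$free),
    total = unname(x$totals),
    free = unname(x$free),
    bound = unname(x$totals - x$free)
  )
}

#' One-row solver summary of an equilibrium state
#'
#' @inheritParams tidy.equilibrium_state
#' @return A one-row tibble: `n_nodes`, `iterations`, `residual`, `K`.
#' @export
glance.equilibrium_state <- function(x, ...) {
  tibble(n_nodes = length(x$free), iterations = x$iterations,
         residual = x$residual, K = x$K)
}
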