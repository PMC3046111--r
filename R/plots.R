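#' Plot a pipeline report
#'
#' @param object A `mirna_report` from [run_pipeline()].
#' @param type One of `"scores"` (static vs dynamic score, classification
#'   colour-coded), `"abundance"` (dynamic score vs mean log2 target
#'   abundance, the efficiency-dilution relationship), or `"similarity"`
#'   (between-group similarity heatmap).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirna_report <- function(object, type = c("scores", "abundance", "similarity"),
                                  ...) {
  type <- match.arg(type)
  s <- object$scores
  if (type == "scores") {
    df <- s %>%
      filter(.data$is_dysregulated) %>%
      mutate(class = ifelse(.data$is_prmir, "drug-reversed", "not reversed"))
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$static_score_net1,
                                       y = .data$dynamic_score,
                                       colour = .data$class)) +
        ggplot2::geom_point(size = 2, na.rm = TRUE) +
        ggplot2::labs(x = "static score (capacity)", y = "dynamic score (efficiency)",
                      colour = NULL) +
        ggplot2::theme_minimal()
    )
  }
  if (type == "abundance") {
    return(
      ggplot2::ggplot(filter(s, .data$is_dysregulated),
                      ggplot2::aes(x = .data$mean_log2_abundance,
                                   y = .data$dynamic_score)) +
        ggplot2::geom_point(size = 2, na.rm = TRUE) +
        ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                             colour = "grey40", na.rm = TRUE) +
        ggplot2::labs(x = "mean target abundance (log2)", y = "dynamic score") +
        ggplot2::theme_minimal()
    )
  }
  sim <- object$similarity
  both <- bind_rows(sim, sim %>% rename(group_a = "group_b", group_b = "group_a"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$group_a, y = .data$group_b,
                                     fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$similarity))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
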