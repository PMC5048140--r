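#' Plot a stage-index profile
#'
#' Line plot of the index across developmental stages, with the bootstrap
#' confidence band as a ribbon when `ci_low`/`ci_high` are present.
#'
#' @param object A `stage_profile` (from [tai()], [tpi()],
#'   [bootstrap_ci()], ...).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stage_profile <- function(object, ...) {
  kind <- attr(object, "index_kind") %||% "index"
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$stage, y = .data$value,
                                    group = 1))
  if (all(c("ci_low", "ci_high") %in% names(object)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "grey80")
  p +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "developmental stage", y = kind) +
    ggplot2::theme_minimal()
}

#' Plot a cross-species similarity grid
#'
#' One line per focal-species stage, Spearman rho against every partner
#' stage; the maximum of each line is marked.
#'
#' @param object A `similarity_grid` from [stage_similarity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.similarity_grid <- function(object, ...) {
  best <- suppressMessages(best_matching_stage(object))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$stage_b, y = .data$rho,
                               colour = .data$stage_a,
                               group = .data$stage_a)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(best, .data$flag == "ok"),
                        ggplot2::aes(x = .data$best_stage_b, y = .data$rho),
                        size = 2.4) +
    ggplot2::labs(x = "partner-species stage", y = "Spearman ρ",
                  colour = "focal stage") +
    ggplot2::theme_minimal()
}

#' Plot relative expression levels as per-phylostratum small multiples
#'
#' @param object A `rel_matrix` from [rel_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rel_matrix <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$stage, y = .data$rel, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~phylostratum) +
    ggplot2::labs(x = "developmental stage", y = "REL") +
    ggplot2::theme_minimal()
}
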