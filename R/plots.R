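#' Plot a pathway graph
#'
#' Simple layered layout with degradation edges solid and regulation edges
#' dashed.
#'
#' @param object A `pathway_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pathway_graph <- function(object, ...) {
  ig <- as_igraph(object)
  set.seed(42) # layout only
  xy <- igraph::layout_with_sugiyama(ig)$layout
  nodes <- tibble::tibble(id = object$nodes$id, x = xy[, 1], y = xy[, 2])
  edges <- dplyr::left_join(object$edges,
                            dplyr::rename(nodes, source = "id",
                                          x0 = "x", y0 = "y"),
                            by = "source")
  edges <- dplyr::left_join(edges,
                            dplyr::rename(nodes, target = "id",
                                          x1 = "x", y1 = "y"),
                            by = "target")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges[edges$source != edges$target, ],
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linetype = .data$kind),
      arrow = ggplot2::arrow(length = ggplot2::unit(2.5, "mm")),
      colour = "grey40"
    ) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$id)) +
    ggplot2::scale_linetype_manual(
      values = c(degradation = "solid", regulation = "dashed")) +
    ggplot2::theme_void() +
    ggplot2::labs(linetype = "edge")
}

#' Forest plot of a fitted model's standardized coefficients
#'
#' @param object A `sem_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sem_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$class %in% c("path", "loading"), ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "estimate (95% Wald CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Trace plot of posterior draws
#'
#' @param object A `sem_chains` object.
#' @param parameters Optional subset of parameter labels.
#' @param thin Plot every `thin`-th iteration (default keeps about 1000
#'   points per chain).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sem_chains <- function(object, parameters = NULL, thin = NULL, ...) {
  len <- nrow(object$draws[[1]])
  if (is.null(thin)) thin <- max(1L, len %/% 1000L)
  idx <- seq(1, len, by = thin)
  long <- purrr::imap_dfr(object$draws, function(d, k) {
    d <- d[idx, , drop = FALSE]
    tibble::as_tibble(d) |>
      dplyr::mutate(iteration = idx, chain = as.character(k)) |>
      tidyr::pivot_longer(-c("iteration", "chain"),
                          names_to = "term", values_to = "value")
  })
  if (!is.null(parameters)) long <- long[long$term %in% parameters, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(y = NULL)
}

#' Gelman-Rubin psrf evolution plot
#'
#' Shows the running potential scale reduction factor per parameter over the
#' chain iterations, with the multivariate psrf overlaid; flat lines at 1
#' indicate convergence.
#'
#' @param chains A `sem_chains` object.
#' @param n_bins Number of prefix lengths (default 20).
#' @return A ggplot object.
#' @export
plot_psrf_evolution <- function(chains, n_bins = 20) {
  ev <- psrf_evolution(chains, n_bins)
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$iteration, y = .data$psrf,
                                   group = .data$label)) +
    ggplot2::geom_line(colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mpsrf), colour = "black",
                       linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(y = "potential scale reduction factor",
                  x = "iterations used") +
    ggplot2::theme_minimal()
}
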