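#' Tidy an epistasis network into its edge tibble
#'
#' @param x An `epinet`.
#' @param ... Unused.
#' @return The edge tibble (`node_a`, `node_b`, `weight`, plus provenance
#'   columns where present).
#' @method tidy epinet
#' @export
tidy.epinet <- function(x, ...) x$edges

#' One-row topology summary of an epistasis network
#'
#' @param x An `epinet`.
#' @param ground_truth,universe Optional gene sets enabling the `auc` and
#'   `p_value` columns.
#' @param ... Unused.
#' @return A one-row tibble: `level`, `measure`, `nodes`, `edges`,
#'   `components`, `r2`, `auc`, `p_value`, and `intersection_edges` for
#'   integrated networks.
#' @method glance epinet
#' @export
glance.epinet <- function(x, ground_truth = NULL, universe = NULL, ...) {
  out <- dplyr::bind_cols(
    tibble(level = x$level, measure = x$measure),
    topology_report(x, ground_truth, universe)
  )
  if (!is.null(attr(x, "intersection_edges"))) {
    out$intersection_edges <- attr(x, "intersection_edges")
  }
  out
}

#' @method tidy threshold_spec
#' @export
tidy.threshold_spec <- function(x, ...) x$edge_means

#' @method glance threshold_spec
#' @export
glance.threshold_spec <- function(x, ...) {
  tibble(theta = x$theta, measure = x$measure, aggregator = x$aggregator,
         n_permutations = x$n_permutations, seed = x$seed)
}

#' Log-log degree-distribution plot of an epistasis network
#'
#' Scatter of `log10 P(k)` against `log10 k` with the least-squares line
#' whose R-squared is reported by [scale_free_r2()].
#'
#' @param object An `epinet`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epinet
#' @export
autoplot.epinet <- function(object, ...) {
  deg <- node_degrees(object, include_isolated = FALSE)
  tab <- table(deg[deg >= 1L])
  df <- tibble(k = as.numeric(names(tab)),
               pk = as.numeric(tab) / sum(tab))
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$k),
                                   y = log10(.data$pk))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(x = "log10 degree k", y = "log10 P(k)",
                  title = sprintf("Degree distribution (%s, %s level)",
                                  object$measure, object$level)) +
    ggplot2::theme_minimal()
}

#' Plot an alpha scan
#'
#' Shows node/edge/component counts and the scale-free R-squared (plus AUC
#' when present) across the sparsity grid; flagged local R-squared maxima
#' are highlighted.
#'
#' @param object A tibble from [alpha_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epigain_scan
#' @export
autoplot.epigain_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "alpha", "nodes", "edges", "components", "r2",
                  dplyr::any_of(c("auc"))),
    -"alpha", names_to = "metric", values_to = "value"
  )
  flagged <- object[object$r2_local_max, , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$alpha, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = flagged$alpha, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(alpha), y = NULL,
                  title = "Sparsity scan (dotted: local R-squared maxima)") +
    ggplot2::theme_minimal()
}
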