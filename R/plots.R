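# ggplot2 methods for the package's result objects.

#' Plot a concordance curve
#'
#' Concordance against candidate rank, with the selected rank highlighted.
#'
#' @param object a `concordance_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.concordance_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$concordance)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::scale_x_continuous(breaks = df$rank) +
    ggplot2::labs(x = "factorization rank", y = "concordance index",
                  title = sprintf("Selected rank: %d", object$selected_rank)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a similarity matrix
#'
#' @param object a `similarity_matrix`.
#' @param ordering optional `ordering` used to arrange rows and columns
#'   (e.g. from [select_affinity_scale()]).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.similarity_matrix <- function(object, ordering = NULL, ...) {
  ids <- rownames(object)
  lv <- if (is.null(ordering)) ids else ordering$ids
  df <- as_tibble(object) %>%
    mutate(id_1 = factor(.data$id_1, levels = lv),
           id_2 = factor(.data$id_2, levels = lv))
  ggplot2::ggplot(df, ggplot2::aes(.data$id_1, .data$id_2,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "similarity",
                  title = sprintf("%s similarity", attr(object, "kind"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Heatmap of a distance matrix
#'
#' @param object a `distance_matrix`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.distance_matrix <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$id_1, .data$id_2,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s distance", attr(object, "kind"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Permutation-null histogram of a Mantel test
#'
#' Histogram of the permuted statistics with the observed statistic marked.
#'
#' @param object a `mantel_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mantel_result <- function(object, ...) {
  df <- tibble(statistic = object$perm)
  ggplot2::ggplot(df, ggplot2::aes(.data$statistic)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "firebrick") +
    ggplot2::labs(x = sprintf("%s Mantel statistic under permutation",
                              object$kind),
                  y = "count",
                  title = sprintf("observed r = %.3f, p = %.3g",
                                  object$statistic, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Divergence trace of an NMF fit
#'
#' @param object an `nmf_fit`.
#' @param ... unused.
#' @return a ggplot of KL divergence against iteration (log-scaled y).
#' @export
autoplot.nmf_fit <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$divergence_trace),
               divergence = object$divergence_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$divergence)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "KL divergence",
                  title = sprintf("rank-%d fit, %s", object$rank,
                                  if (object$converged) "converged"
                                  else "max_iter reached")) +
    ggplot2::theme_minimal()
}

#' Distance-decay scatter of two distance matrices
#'
#' Scatter of the off-diagonal site pairs of `d_y` against `d_x` with a
#' least-squares line — the standard way to display how functional distance
#' tracks environmental or geographic distance.
#'
#' @param d_x,d_y aligned `distance_matrix` objects.
#' @return a ggplot.
#' @export
plot_distance_decay <- function(d_x, d_y) {
  check_aligned(d_x, d_y)
  df <- tibble(x = upper_tri_vec(as.matrix(unclass(d_x))),
               y = upper_tri_vec(as.matrix(unclass(d_y))))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.5, colour = "grey30") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         colour = "firebrick", se = FALSE) +
    ggplot2::labs(x = sprintf("%s distance", attr(d_x, "kind")),
                  y = sprintf("%s distance", attr(d_y, "kind"))) +
    ggplot2::theme_minimal()
}
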