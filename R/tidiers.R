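# broom-style tidiers for the package's fitted objects.

#' Tidy an NMF fit
#'
#' Long-format factor loadings: the site profiles (`matrix = "H"`, default)
#' as one row per component-sample pair, or the functional profiles
#' (`matrix = "W"`) as one row per family-component pair.
#'
#' @param x an `nmf_fit`.
#' @param matrix `"H"` or `"W"`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.nmf_fit <- function(x, matrix = c("H", "W"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "H") {
    as_tibble(x$H, rownames = "component") %>%
      tidyr::pivot_longer(-"component", names_to = "sample_id",
                          values_to = "weight")
  } else {
    as_tibble(x$W, rownames = "family_id") %>%
      tidyr::pivot_longer(-"family_id", names_to = "component",
                          values_to = "loading")
  }
}

#' @rdname tidy.nmf_fit
#' @export
glance.nmf_fit <- function(x, ...) {
  tibble(rank = x$rank,
         n_families = nrow(x$W),
         n_samples = ncol(x$H),
         divergence = x$divergence_trace[x$n_iter],
         n_iter = x$n_iter,
         converged = x$converged,
         seed = x$seed)
}

#' Tidy a concordance curve
#'
#' @param x a `concordance_curve` from [select_rank()].
#' @param ... unused.
#' @return a tibble with `rank`, `concordance`, `selected`.
#' @export
tidy.concordance_curve <- function(x, ...) {
  tibble(rank = x$ranks, concordance = x$concordance,
         selected = x$ranks == x$selected_rank)
}

#' @rdname tidy.concordance_curve
#' @export
glance.concordance_curve <- function(x, ...) {
  tibble(selected_rank = x$selected_rank, n_runs = x$n_runs,
         policy = x$policy,
         max_concordance = max(x$concordance))
}

#' Tidy a Mantel test result
#'
#' @param x a `mantel_result`.
#' @param ... unused.
#' @return a one-row tibble with `kind`, `statistic`, `p.value`,
#'   `n.permutations`.
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble(kind = x$kind,
         statistic = x$statistic,
         p.value = x$p_value,
         n.permutations = x$n_permutations)
}

#' @rdname tidy.mantel_result
#' @export
glance.mantel_result <- function(x, ...) tidy(x)

#' Tidy a naive distance regression
#'
#' @param x a `dist_regression`.
#' @param ... unused.
#' @return coefficient tibble (`tidy`) or one-row fit summary (`glance`).
#' @export
tidy.dist_regression <- function(x, ...) x$coefficients

#' @rdname tidy.dist_regression
#' @export
glance.dist_regression <- function(x, ...) {
  tibble(r.squared = x$r_squared,
         adj.r.squared = x$adj_r_squared,
         n.pairs = x$n_pairs,
         collinear = x$collinear)
}

#' @export
as_tibble.similarity_matrix <- function(x, ...) {
  as_tibble(as.matrix(unclass(x)), rownames = "id_1") %>%
    tidyr::pivot_longer(-"id_1", names_to = "id_2", values_to = "similarity")
}

#' @export
as_tibble.distance_matrix <- function(x, ...) {
  as_tibble(as.matrix(unclass(x)), rownames = "id_1") %>%
    tidyr::pivot_longer(-"id_1", names_to = "id_2", values_to = "distance")
}
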