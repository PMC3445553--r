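check_aligned <- function(...) {
  mats <- list(...)
  ids <- rownames(mats[[1]])
  for (m in mats) {
    if (!identical(dim(m)[1], dim(mats[[1]])[1])) abort("distance matrices differ in size")
    if (!is.null(ids) && !is.null(rownames(m)) && !identical(rownames(m), ids)) {
      abort("distance matrices have mismatched site identifiers")
    }
  }
  invisible(TRUE)
}

mantel_kind_of <- function(m) {
  k <- attr(m, "kind")
  if (is.null(k)) NA_character_ else k
}

#' Mantel permutation test between two distance matrices
#'
#' Tests whether two distance (or dissimilarity) matrices over the same
#' sites are correlated, the standard question in distance-decay ecology.
#' The statistic is the Pearson correlation of the vectorized
#' off-diagonal triangles; the null distribution is built by jointly
#' permuting the rows and columns of `d1`, and the one-tailed (greater)
#' p-value uses the add-one convention
#' `p = (1 + #\{permuted statistic >= observed\}) / (1 + n_perm)`.
#' Computation is delegated to `vegan::mantel()` under a seeded permutation
#' stream.
#'
#' @param d1,d2 aligned `distance_matrix` objects (or symmetric matrices).
#' @param n_perm number of permutations; the conventional choice is 999.
#' @param seed integer seed for the permutation stream.
#' @return a `mantel_result`: list with `statistic`, `p_value`,
#'   `n_permutations`, `kind = "simple"`, `seed`, `perm` (the permuted
#'   statistics), `matrix_kinds`.
#' @export
mantel <- function(d1, d2, n_perm = 999L, seed = 1L) {
  check_aligned(d1, d2)
  if (n_perm < 1) abort("n_perm must be at least 1")
  v1 <- upper_tri_vec(as.matrix(unclass(d1)))
  v2 <- upper_tri_vec(as.matrix(unclass(d2)))
  if (sd(v1) == 0 || sd(v2) == 0) {
    abort("degenerate input: constant off-diagonal entries")
  }
  res <- withr::with_seed(derive_seed(seed, 0L), {
    vegan::mantel(unclass(d1), unclass(d2), method = "pearson",
                  permutations = n_perm, parallel = 1)
  })
  structure(list(statistic = unname(res$statistic),
                 p_value = unname(res$signif),
                 n_permutations = as.integer(n_perm),
                 kind = "simple",
                 controlled = NULL,
                 seed = as.integer(seed),
                 perm = res$perm,
                 matrix_kinds = c(mantel_kind_of(d1), mantel_kind_of(d2))),
            class = "mantel_result")
}

#' Partial Mantel test controlling for a third matrix
#'
#' First-order partial correlation between the off-diagonal triangles of
#' `d1` and `d2` given `d_control`,
#' `r12.3 = (r12 - r13 r23) / sqrt((1 - r13^2)(1 - r23^2))`,
#' with the null built by permuting `d1` and the same one-tailed add-one
#' p-value as [mantel()]. Used to ask whether functional distance tracks
#' environmental distance once geographic distance is held fixed (and vice
#' versa). Delegated to `vegan::mantel.partial()` under a seeded stream.
#'
#' @param d1,d2,d_control aligned `distance_matrix` objects.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return a `mantel_result` with `kind = "partial"`.
#' @export
partial_mantel <- function(d1, d2, d_control, n_perm = 999L, seed = 1L) {
  check_aligned(d1, d2, d_control)
  if (n_perm < 1) abort("n_perm must be at least 1")
  v1 <- upper_tri_vec(as.matrix(unclass(d1)))
  v2 <- upper_tri_vec(as.matrix(unclass(d2)))
  v3 <- upper_tri_vec(as.matrix(unclass(d_control)))
  if (sd(v1) == 0 || sd(v2) == 0 || sd(v3) == 0) {
    abort("degenerate input: constant off-diagonal entries")
  }
  r13 <- cor(v1, v3)
  r23 <- cor(v2, v3)
  if (abs(r13) >= 1 - 1e-12 || abs(r23) >= 1 - 1e-12) {
    abort("degenerate control: perfectly correlated with an input matrix")
  }
  res <- withr::with_seed(derive_seed(seed, 0L), {
    vegan::mantel.partial(unclass(d1), unclass(d2), unclass(d_control),
                          method = "pearson", permutations = n_perm,
                          parallel = 1)
  })
  structure(list(statistic = unname(res$statistic),
                 p_value = unname(res$signif),
                 n_permutations = as.integer(n_perm),
                 kind = "partial",
                 controlled = mantel_kind_of(d_control),
                 seed = as.integer(seed),
                 perm = res$perm,
                 matrix_kinds = c(mantel_kind_of(d1), mantel_kind_of(d2))),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> %s Mantel r = %.4f, p = %.4g (%d permutations)\n",
              x$kind, x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' Naive regression of one distance matrix on others
#'
#' Ordinary least squares of the response's off-diagonal triangle on the
#' predictors' triangles, with intercept. The site pairs are not independent
#' observations, so inference from this fit is not meaningful — the model is
#' deliberately naive and only its adjusted R-squared,
#' `1 - (1 - R^2)(n - 1)/(n - p - 1)` with `n` the number of pairs, is used
#' as a summary of how much pairwise functional variation the predictor
#' distances explain. Collinear predictors are flagged and coefficients
#' computed by the minimum-norm least-squares solution.
#'
#' @param response a `distance_matrix`.
#' @param predictors named list of aligned `distance_matrix` objects.
#' @return a `dist_regression`: list with `coefficients` tibble,
#'   `adj_r_squared`, `r_squared`, `n_pairs`, `collinear` flag.
#' @export
distance_regression <- function(response, predictors) {
  if (!is.list(predictors) || length(predictors) == 0) {
    abort("predictors must be a non-empty list of distance matrices")
  }
  do.call(check_aligned, c(list(response), predictors))
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    names(predictors) <- paste0("predictor_", seq_along(predictors))
  }
  y <- upper_tri_vec(as.matrix(unclass(response)))
  xmat <- vapply(predictors, function(p) upper_tri_vec(as.matrix(unclass(p))),
                 numeric(length(y)))
  n <- length(y)
  design <- cbind(`(intercept)` = 1, xmat)
  qrd <- qr(design)
  collinear <- qrd$rank < ncol(design)
  if (collinear) {
    warn("collinear predictors; reporting the minimum-norm solution")
    coefs <- drop(MASS::ginv(design) %*% y)
    names(coefs) <- colnames(design)
  } else {
    coefs <- qr.coef(qrd, y)
  }
  fitted <- drop(design %*% coefs)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  p <- ncol(xmat)
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(list(
    coefficients = tibble(term = names(coefs), estimate = unname(coefs)),
    r_squared = r2,
    adj_r_squared = adj,
    n_pairs = n,
    collinear = collinear
  ), class = "dist_regression")
}

#' @export
print.dist_regression <- function(x, ...) {
  cat(sprintf("<dist_regression> %d site pairs, adjusted R^2 = %.4f%s\n",
              x$n_pairs, x$adj_r_squared,
              if (x$collinear) " (collinear predictors)" else ""))
  print(x$coefficients)
  invisible(x)
}
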