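#' Score protein families against components
#'
#' Ranks every family against every component of a factorization by one of
#' three criteria:
#'
#' * `"correlation"` — Pearson correlation, across sites, between the
#'   family's relative-abundance profile (a row of `X`) and the component's
#'   site profile (a row of `H`). Robust to a family being globally rare or
#'   globally abundant, which is why it is the default selection method.
#' * `"similarity"` — cosine between the same two site vectors after scaling
#'   each to unit Euclidean norm.
#' * `"specificity"` — the share of the family's total loading carried by the
#'   component, `W[f, c] / sum(W[f, ])`. Sensitive to sampling density:
#'   under-sampled families tend to look spuriously specific.
#'
#' Degenerate rows (constant, for correlation; all-zero, for similarity or
#' specificity) receive a score of 0 (or `1/rank` for specificity) and are
#' flagged rather than dropped, keeping the table rectangular.
#'
#' @param x a normalized [profile_matrix()] (required for `"correlation"` and
#'   `"similarity"`; ignored for `"specificity"`).
#' @param fit an `nmf_fit` sharing `x`'s sample ordering.
#' @param method scoring criterion.
#' @return an `association_table`: a tibble with columns `family_id`,
#'   `component`, `method`, `score`, `flag` (`NA` or `"degenerate"`).
#' @export
associate_families <- function(x = NULL, fit,
                               method = c("correlation", "similarity",
                                          "specificity")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "nmf_fit"))
  if (method == "specificity") {
    scores_flags <- specificity_scores(fit)
  } else {
    if (is.null(x)) abort(sprintf("method '%s' requires the profile matrix x", method))
    xv <- if (inherits(x, "profile_matrix")) x$values else x
    if (ncol(xv) != ncol(fit$H) ||
        (!is.null(colnames(xv)) && !identical(colnames(xv), colnames(fit$H)))) {
      abort("x and fit must share the same samples in the same order")
    }
    if (!identical(rownames(xv), rownames(fit$W))) {
      # allow matrices without names, but reject genuine mismatches
      if (!is.null(rownames(xv)) && !is.null(rownames(fit$W))) {
        abort("x and fit must share the same families in the same order")
      }
    }
    scores_flags <- if (method == "correlation") {
      correlation_scores(xv, fit$H)
    } else {
      cosine_scores(xv, fit$H)
    }
  }
  scores <- scores_flags$scores
  fam <- rownames(scores)
  if (is.null(fam)) fam <- paste0("F", seq_len(nrow(scores)))
  out <- as_tibble(scores, rownames = "family_id") %>%
    tidyr::pivot_longer(-"family_id", names_to = "component",
                        values_to = "score") %>%
    mutate(method = method,
           flag = ifelse(.data$family_id %in% scores_flags$degenerate,
                         "degenerate", NA_character_)) %>%
    dplyr::select("family_id", "component", "method", "score", "flag")
  class(out) <- c("association_table", class(out))
  out
}

correlation_scores <- function(xv, h) {
  fam_sd <- apply(xv, 1, sd)
  comp_sd <- apply(h, 1, sd)
  const_fam <- fam_sd == 0
  scores <- matrix(0, nrow(xv), nrow(h),
                   dimnames = list(rownames(xv), rownames(h)))
  ok_comp <- comp_sd > 0
  if (any(!const_fam) && any(ok_comp)) {
    scores[!const_fam, ok_comp] <-
      cor(t(xv[!const_fam, , drop = FALSE]), t(h[ok_comp, , drop = FALSE]))
  }
  list(scores = scores,
       degenerate = rownames(xv)[const_fam])
}

cosine_scores <- function(xv, h) {
  fam_nrm <- sqrt(rowSums(xv^2))
  comp_nrm <- sqrt(rowSums(h^2))
  if (any(comp_nrm == 0)) abort("component with all-zero site profile")
  zero_fam <- fam_nrm == 0
  xn <- xv / ifelse(fam_nrm == 0, 1, fam_nrm)
  scores <- xn %*% t(h / comp_nrm)
  scores[zero_fam, ] <- 0
  dimnames(scores) <- list(rownames(xv), rownames(h))
  list(scores = scores, degenerate = rownames(xv)[zero_fam])
}

specificity_scores <- function(fit) {
  w <- fit$W
  tot <- rowSums(w)
  zero <- tot == 0
  scores <- w / ifelse(tot == 0, 1, tot)
  scores[zero, ] <- 1 / fit$rank
  list(scores = scores, degenerate = rownames(w)[zero])
}

#' Top-k families for a component
#'
#' The `k` most strongly associated families for one component, by
#' descending score; ties broken by lexical family identifier so selections
#' are deterministic.
#'
#' @param table an `association_table` from [associate_families()].
#' @param component component label (e.g. `"component_1"`).
#' @param k selection size; the conventional choice for functional
#'   inspection is 100.
#' @return a tibble of `k` rows with `rank`, `family_id`, `score`.
#' @export
select_top <- function(table, component, k = 100L) {
  if (!is.numeric(k) || k < 1) abort("k must be a positive integer")
  sub <- filter(table, .data$component == !!component)
  if (nrow(sub) == 0) abort(sprintf("component '%s' not present in table", component))
  if (k > nrow(sub)) abort("k exceeds the number of families")
  sub %>%
    arrange(desc(.data$score), .data$family_id) %>%
    slice_head(n = k) %>%
    mutate(rank = dplyr::row_number()) %>%
    dplyr::select("rank", "family_id", "score")
}

#' Count families scoring at or above a threshold
#'
#' @param table an `association_table`.
#' @param component component label.
#' @param threshold score cutoff (for correlation scores, in `[-1, 1]`).
#' @return integer count.
#' @export
count_above <- function(table, component, threshold) {
  sub <- filter(table, .data$component == !!component)
  if (nrow(sub) == 0) abort(sprintf("component '%s' not present in table", component))
  sum(sub$score >= threshold)
}

#' Ubiquity of families across components
#'
#' Scores how evenly a family's loading spreads over the components, as the
#' normalized entropy of its specificity vector: 1 for a perfectly even
#' (ubiquitous) family, 0 for a single-component family. Supports selecting
#' the "ubiquitous" cluster of families — typically core functions present
#' everywhere — as the complement of the component-characteristic blocks.
#'
#' @param fit an `nmf_fit` with rank at least 2.
#' @return a tibble with `family_id`, `ubiquity`, `flag` (`"zero_loading"`
#'   with `NA` score for families with no loading at all), sorted by
#'   descending ubiquity.
#' @export
ubiquity_score <- function(fit) {
  stopifnot(inherits(fit, "nmf_fit"))
  if (fit$rank < 2) abort("ubiquity is undefined for a rank-1 factorization")
  w <- fit$W
  tot <- rowSums(w)
  p <- w / ifelse(tot == 0, 1, tot)
  plogp <- ifelse(p > 0, p * log(p), 0)
  ent <- unname(-rowSums(plogp) / log(fit$rank))
  ent[tot == 0] <- NA_real_
  tibble(family_id = rownames(w),
         ubiquity = ent,
         flag = ifelse(unname(tot) == 0, "zero_loading", NA_character_)) %>%
    arrange(desc(.data$ubiquity), .data$family_id)
}
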