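#' Concordance index of an NMF rank over random restarts
#'
#' Measures how stable the site-similarity structure of a rank-`rank`
#' factorization is across random restarts. The matrix is fitted `n_runs`
#' times from seeds derived from `seed` by fixed increments; for each run the
#' site similarity `S = t(Hn) %*% Hn` is built from the unit-Euclidean-norm
#' columns of `H`, and `d` is the mean, over all run pairs, of the mean
#' squared difference between corresponding off-diagonal entries of `S`. The
#' concordance index is `C = 1 - d`: 1 when every restart sees the same site
#' structure, lower when the decomposition is unstable (typically, when the
#' rank over- or under-fits).
#'
#' @param x a normalized [profile_matrix()] or non-negative matrix.
#' @param rank factorization rank.
#' @param n_runs number of random restarts (at least 2).
#' @param seed master seed; restart `i` uses `seed + i`.
#' @param ... passed to [nmf_kl()] (`max_iter`, `tol`).
#' @return a single number in `[0, 1]`.
#' @export
concordance_index <- function(x, rank, n_runs = 20L, seed = 1L, ...) {
  if (n_runs < 2) abort("n_runs must be at least 2")
  sims <- lapply(seq_len(n_runs), function(i) {
    fit <- nmf_kl(x, rank = rank, seed = derive_seed(seed, i), ...)
    hn <- unit_norm_cols(fit$H, what = "site column")
    crossprod(hn)
  })
  off <- upper.tri(sims[[1]])
  pairs <- utils::combn(n_runs, 2)
  d <- mean(apply(pairs, 2, function(pr) {
    mean((sims[[pr[1]]][off] - sims[[pr[2]]][off])^2)
  }))
  1 - d
}

#' Select the factorization rank by restart concordance
#'
#' Computes the concordance index for every rank in `rank_range` and selects
#' a rank by `policy`: `"max"` (default) takes the arg-max of the concordance
#' curve, breaking ties toward the smaller rank; `"threshold"` takes the
#' largest rank whose concordance is at least `threshold`, falling back to
#' the arg-max when no rank reaches it.
#'
#' @param x a normalized [profile_matrix()] or non-negative matrix.
#' @param rank_range integer vector of candidate ranks.
#' @param n_runs restarts per rank.
#' @param seed master seed; rank `r` uses restart seeds derived from
#'   `seed + 10000 * r`.
#' @param policy `"max"` or `"threshold"`.
#' @param threshold concordance level for the threshold policy.
#' @param ... passed to [nmf_kl()].
#' @return a `concordance_curve` object: list with `ranks`, `concordance`,
#'   `n_runs`, `selected_rank`, `policy`.
#' @export
select_rank <- function(x, rank_range = 2:10, n_runs = 20L, seed = 1L,
                        policy = c("max", "threshold"), threshold = 0.95,
                        ...) {
  policy <- match.arg(policy)
  rank_range <- sort(unique(as.integer(rank_range)))
  if (length(rank_range) == 0) abort("rank_range must be non-empty")
  vals <- if (inherits(x, "profile_matrix")) x$values else x
  if (max(rank_range) > min(dim(vals))) {
    abort(sprintf("rank_range exceeds matrix dimensions (max rank %d)",
                  min(dim(vals))))
  }
  conc <- vapply(rank_range, function(r) {
    if (r == 1L) return(1)  # unit-norm scalars: S is all ones in every run
    concordance_index(x, rank = r, n_runs = n_runs,
                      seed = derive_seed(seed, 10000L * r), ...)
  }, numeric(1))
  selected <- if (policy == "max") {
    rank_range[which.max(conc)]
  } else {
    ok <- which(conc >= threshold)
    if (length(ok) == 0) rank_range[which.max(conc)] else rank_range[max(ok)]
  }
  structure(list(ranks = rank_range, concordance = conc,
                 n_runs = as.integer(n_runs), selected_rank = selected,
                 policy = policy, seed = as.integer(seed)),
            class = "concordance_curve")
}

#' @export
print.concordance_curve <- function(x, ...) {
  cat(sprintf("<concordance_curve> ranks %d..%d, %d restarts; selected rank %d (policy %s)\n",
              min(x$ranks), max(x$ranks), x$n_runs, x$selected_rank, x$policy))
  print(tibble(rank = x$ranks, concordance = x$concordance), n = length(x$ranks))
  invisible(x)
}
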