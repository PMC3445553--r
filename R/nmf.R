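#' Non-negative matrix factorization under generalized KL divergence
#'
#' Factorizes a non-negative family-by-site matrix `X` as `W %*% H` with
#' `W >= 0` (functional profiles, one column per component) and `H >= 0`
#' (site profiles, one row per component), minimizing the generalized
#' Kullback-Leibler divergence
#' \deqn{D(X \| WH) = \sum_{ij} x_{ij} \log\frac{x_{ij}}{(WH)_{ij}}
#'   - x_{ij} + (WH)_{ij},}
#' with the convention \eqn{0 \log 0 = 0}, by Lee-Seung multiplicative
#' updates from a seeded uniform-random positive start. Each iteration
#' updates `H` then `W`; the divergence is recorded after every iteration
#' and is non-increasing (to numerical tolerance) by the monotonicity of
#' the updates. Iteration stops when the relative divergence change over a
#' 10-iteration window drops below `tol`, or at `max_iter`.
#'
#' @param x a normalized [profile_matrix()] or a non-negative matrix. A
#'   non-normalized input is accepted with a warning (the factorization is
#'   defined for any non-negative matrix, but the package's similarity and
#'   distance constructions assume relative abundances).
#' @param rank number of components, between 1 and `min(dim(x))`.
#' @param seed integer seed for the random start.
#' @param max_iter maximum number of multiplicative-update iterations.
#' @param tol relative divergence change (per 10 iterations) below which the
#'   fit is declared converged.
#' @return an `nmf_fit` object: list with `W`, `H`, `rank`,
#'   `divergence_trace`, `n_iter`, `seed`, `converged`.
#' @examples
#' x <- matrix(runif(60), 10, 6)
#' fit <- nmf_kl(x, rank = 2, seed = 1)
#' glance(fit)
#' @export
nmf_kl <- function(x, rank, seed = 1L, max_iter = 2000L, tol = 1e-6) {
  if (inherits(x, "profile_matrix")) {
    if (!x$normalized) {
      warn("profile matrix is not column-normalized; fitting raw values")
    }
    x <- x$values
  }
  if (!is.matrix(x) || any(x < 0)) abort("x must be a non-negative matrix")
  p <- nrow(x)
  n <- ncol(x)
  rank <- as.integer(rank)
  if (rank < 1 || rank > min(p, n)) {
    abort(sprintf("rank must lie in [1, %d]", min(p, n)))
  }
  eps <- .EPS
  pos <- x > 0
  xpos <- x[pos]
  kl_div <- function(wh) {
    sum(xpos * log(xpos / (wh[pos] + eps))) - sum(xpos) + sum(wh)
  }
  withr::with_seed(seed, {
    W <- matrix(runif(p * rank), p, rank)
    H <- matrix(runif(rank * n), rank, n)
  })
  trace <- numeric(max_iter)
  converged <- FALSE
  it <- 0L
  d_window <- Inf
  for (it in seq_len(max_iter)) {
    wh <- W %*% H
    ratio <- x / (wh + eps)
    H <- H * crossprod(W, ratio) / (colSums(W) + eps)
    wh <- W %*% H
    ratio <- x / (wh + eps)
    W <- W * (ratio %*% t(H)) / rep(rowSums(H) + eps, each = p)
    d <- kl_div(W %*% H)
    trace[it] <- d
    if (it %% 10L == 0L) {
      if (is.finite(d_window) &&
          abs(d_window - d) <= tol * max(abs(d_window), eps)) {
        converged <- TRUE
        break
      }
      d_window <- d
    }
  }
  structure(list(
    W = `dimnames<-`(W, list(rownames(x), paste0("component_", seq_len(rank)))),
    H = `dimnames<-`(H, list(paste0("component_", seq_len(rank)), colnames(x))),
    rank = rank,
    divergence_trace = trace[seq_len(it)],
    n_iter = it,
    seed = as.integer(seed),
    converged = converged
  ), class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf(paste0("<nmf_fit> rank %d, %d families x %d sites; ",
                     "KL divergence %.4g after %d iterations (%s)\n"),
              x$rank, nrow(x$W), ncol(x$H),
              x$divergence_trace[x$n_iter], x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Normalize NMF factors for similarity or mixing use
#'
#' Different downstream uses require different scalings of the factor pair.
#' `target = "similarity"` scales the columns of `H` (sites) and the rows of
#' `W` (families) to unit Euclidean norm, so that the similarity matrices
#' built from them have ones down the diagonal. `target = "mixing"` scales
#' each column of `H` to unit sum, giving the mixing proportions used by the
#' filtered functional distance. The scaling factors are recorded in
#' attribute `"scaling"` so that raw factors remain recoverable; either
#' normalization is idempotent.
#'
#' @param fit an `nmf_fit`.
#' @param target `"similarity"` or `"mixing"`.
#' @return an `nmf_fit` with rescaled factors.
#' @export
normalize_factors <- function(fit, target = c("similarity", "mixing")) {
  stopifnot(inherits(fit, "nmf_fit"))
  target <- match.arg(target)
  out <- fit
  if (target == "similarity") {
    h_nrm <- sqrt(colSums(fit$H^2))
    w_nrm <- sqrt(rowSums(fit$W^2))
    if (any(h_nrm == 0)) abort("degenerate all-zero site column in H")
    if (any(w_nrm == 0)) abort("degenerate all-zero family row in W")
    out$H <- sweep(fit$H, 2, h_nrm, "/")
    out$W <- fit$W / w_nrm
    attr(out, "scaling") <- list(target = "similarity", h = h_nrm, w = w_nrm)
  } else {
    h_sum <- colSums(fit$H)
    if (any(h_sum <= 0)) abort("degenerate non-positive site column in H")
    out$H <- sweep(fit$H, 2, h_sum, "/")
    attr(out, "scaling") <- list(target = "mixing", h = h_sum)
  }
  out
}

#' Cosine similarity between components
#'
#' Compares the components of a factorization with each other, either
#' through their site profiles (rows of `H` — do two components occupy the
#' same sites?) or their functional profiles (columns of `W` — do they draw
#' on the same families?).
#'
#' @param fit an `nmf_fit`.
#' @param basis `"site"` or `"functional"`.
#' @return a rank-by-rank `similarity_matrix` (kind `"component"`).
#' @export
component_similarity <- function(fit, basis = c("site", "functional")) {
  stopifnot(inherits(fit, "nmf_fit"))
  basis <- match.arg(basis)
  v <- if (basis == "site") t(fit$H) else fit$W
  nrm <- sqrt(colSums(v^2))
  if (any(nrm == 0)) {
    abort(sprintf("component %s has an all-zero %s profile",
                  paste(which(nrm == 0), collapse = ", "), basis))
  }
  s <- crossprod(sweep(v, 2, nrm, "/"))
  diag(s) <- 1
  similarity_matrix((s + t(s)) / 2, ids = colnames(fit$W), kind = "component")
}
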