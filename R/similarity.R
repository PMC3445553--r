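#' Similarity matrix container
#'
#' Square symmetric matrix with unit diagonal over sites, families,
#' components or environmental records. Entries are cosines of non-negative
#' vectors (or a distance-derived similarity), hence lie in `[0, 1]`.
#'
#' @param values square symmetric numeric matrix.
#' @param ids identifiers; defaults to the row names.
#' @param kind one of `"site"`, `"family"`, `"component"`, `"environmental"`.
#' @return a `similarity_matrix` object (matrix with attributes).
#' @export
similarity_matrix <- function(values, ids = NULL,
                              kind = c("site", "family", "component",
                                       "environmental")) {
  kind <- match.arg(kind)
  values <- check_square_ids(values, ids)
  if (max(abs(values - t(values))) > 1e-10) abort("similarity matrix must be symmetric")
  if (max(abs(diag(values) - 1)) > 1e-10) abort("similarity matrix must have unit diagonal")
  structure(values, kind = kind, class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d, kind '%s'\n",
              nrow(x), ncol(x), attr(x, "kind")))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' NMF-filtered site similarity
#'
#' Cosine similarity between sites as seen through the decomposition:
#' `S = t(Hn) %*% Hn` with the columns of `H` scaled to unit Euclidean norm.
#' Two sites are similar when the same components, in the same proportions,
#' explain their functional profiles.
#'
#' @param fit an `nmf_fit`.
#' @return an n_sites x n_sites `similarity_matrix` (kind `"site"`).
#' @export
site_similarity <- function(fit) {
  stopifnot(inherits(fit, "nmf_fit"))
  hn <- unit_norm_cols(fit$H, what = "site column")
  s <- crossprod(hn)
  diag(s) <- 1
  similarity_matrix((s + t(s)) / 2, ids = colnames(fit$H), kind = "site")
}

#' NMF-filtered family similarity
#'
#' Cosine similarity between protein families through their component
#' loadings: `S = Wn %*% t(Wn)` over unit-Euclidean-norm rows of `W`.
#' Families loading on the same components are similar regardless of their
#' absolute abundances. Optionally restricted to a subset of families (large
#' surveys are typically displayed through a random subset).
#'
#' @param fit an `nmf_fit`.
#' @param subset optional character vector of family identifiers or integer
#'   indices.
#' @return a `similarity_matrix` (kind `"family"`). Families with all-zero
#'   loadings are excluded with a warning and listed in attribute
#'   `"excluded"`.
#' @export
family_similarity <- function(fit, subset = NULL) {
  stopifnot(inherits(fit, "nmf_fit"))
  w <- fit$W
  if (!is.null(subset)) w <- w[subset, , drop = FALSE]
  nrm <- sqrt(rowSums(w^2))
  excluded <- rownames(w)[nrm == 0]
  if (length(excluded) > 0) {
    warn(sprintf("%d zero-loading families excluded from family similarity",
                 length(excluded)))
    w <- w[nrm > 0, , drop = FALSE]
    nrm <- nrm[nrm > 0]
  }
  wn <- w / nrm
  s <- tcrossprod(wn)
  diag(s) <- 1
  out <- similarity_matrix((s + t(s)) / 2, ids = rownames(w), kind = "family")
  attr(out, "excluded") <- excluded
  out
}

#' Gaussian affinity transformation of a similarity matrix
#'
#' Maps similarities to graph edge weights through a Gaussian kernel on the
#' dissimilarity `1 - S`:
#' `A[i, j] = exp(-(1 - S[i, j])^2 / (2 * sigma^2))` off the diagonal, 1 on
#' it. Small `sigma` sharpens block structure before spectral reordering;
#' large `sigma` flattens the matrix toward all ones.
#'
#' @param s a `similarity_matrix` (or symmetric matrix).
#' @param sigma positive kernel scale.
#' @return a symmetric non-negative matrix with unit diagonal.
#' @export
affinity_transform <- function(s, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    abort("sigma must be a single positive number")
  }
  a <- exp(-(1 - unclass(s))^2 / (2 * sigma^2))
  diag(a) <- 1
  dimnames(a) <- dimnames(s)
  a
}

# connected components of the graph with edges where a > threshold,
# by breadth-first search on the adjacency pattern
graph_components <- function(a, threshold = 0) {
  n <- nrow(a)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(a[v, ] > threshold & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

two_sum_objective <- function(m, perm) {
  pos <- integer(length(perm))
  pos[perm] <- seq_along(perm)
  sum(unclass(m) * outer(pos, pos, function(i, j) (i - j)^2))
}

#' Spectral reordering of a similarity graph
#'
#' Treats a symmetric non-negative matrix as a weighted graph adjacency and
#' orders its nodes by the Fiedler vector — the eigenvector of the
#' second-smallest eigenvalue of the graph Laplacian `L = D - A`
#' (unnormalized by default). Sorting nodes by their Fiedler coordinates
#' places strongly connected nodes next to each other, exposing block
#' structure without committing to a hard clustering. The sign of the
#' eigenvector is fixed so that its first nonzero entry is positive, making
#' the ordering deterministic up to this convention.
#'
#' If the graph is disconnected, each connected component is ordered
#' separately and the components are concatenated in decreasing size order;
#' the result is flagged via `disconnected = TRUE`.
#'
#' @param a symmetric non-negative matrix (e.g. from [affinity_transform()]).
#' @param normalized_laplacian use the symmetric normalized Laplacian
#'   `I - D^{-1/2} A D^{-1/2}` instead of `D - A`.
#' @return an `ordering` object: list with `permutation` (index of the
#'   original node at each position), `objective_value` (the 2-sum
#'   `sum_ij A_ij (pos_i - pos_j)^2` of the returned ordering on `a`),
#'   `scale_used` (`NA` here; set by [select_affinity_scale()]),
#'   `disconnected`, `ids`.
#' @export
spectral_order <- function(a, normalized_laplacian = FALSE) {
  a <- unclass(a)
  if (!is.matrix(a) || nrow(a) != ncol(a)) abort("a must be a square matrix")
  if (max(abs(a - t(a))) > 1e-8) abort("a must be symmetric")
  if (any(a < 0)) abort("a must be non-negative")
  n <- nrow(a)
  ids <- rownames(a)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  comp <- graph_components(a)
  n_comp <- max(comp)
  order_component <- function(idx) {
    if (length(idx) <= 2) return(idx)
    sub <- a[idx, idx, drop = FALSE]
    d <- rowSums(sub)
    lap <- if (normalized_laplacian) {
      di <- 1 / sqrt(pmax(d, .EPS))
      diag(length(idx)) - sub * tcrossprod(di)
    } else {
      diag(d) - sub
    }
    ev <- eigen((lap + t(lap)) / 2, symmetric = TRUE)
    fiedler <- ev$vectors[, length(idx) - 1L]
    nz <- which(abs(fiedler) > 1e-12)
    if (length(nz) > 0 && fiedler[nz[1]] < 0) fiedler <- -fiedler
    idx[order(fiedler)]
  }
  if (n_comp == 1L) {
    perm <- order_component(seq_len(n))
    disconnected <- FALSE
  } else {
    sizes <- tabulate(comp)
    perm <- unlist(lapply(order(sizes, decreasing = TRUE), function(g) {
      order_component(which(comp == g))
    }))
    disconnected <- TRUE
    warn(sprintf("graph is disconnected (%d components); ordered per component", n_comp))
  }
  structure(list(permutation = as.integer(perm),
                 objective_value = two_sum_objective(a, perm),
                 scale_used = NA_real_,
                 disconnected = disconnected,
                 ids = ids[perm]),
            class = "ordering")
}

#' @export
print.ordering <- function(x, ...) {
  cat(sprintf("<ordering> %d nodes, 2-sum objective %.6g%s%s\n",
              length(x$permutation), x$objective_value,
              if (is.na(x$scale_used)) "" else sprintf(", sigma %.4g", x$scale_used),
              if (x$disconnected) " (disconnected graph)" else ""))
  invisible(x)
}

#' Choose the affinity scale for spectral reordering
#'
#' For each candidate `sigma`, reorders the affinity-transformed matrix and
#' scores the resulting permutation on the *untransformed* similarity matrix
#' by the 2-sum Laplacian criterion `sum_ij S_ij (pos_i - pos_j)^2`; the
#' ordering minimizing this criterion wins (ties to the smaller `sigma`).
#' The default grid places `sigma` at the deciles 0.1..0.9 of the
#' off-diagonal dissimilarity `1 - S`.
#'
#' @param s a `similarity_matrix`.
#' @param sigmas positive numeric grid; `NULL` for the decile default.
#' @param normalized_laplacian passed to [spectral_order()].
#' @return an `ordering` with `scale_used` set to the winning `sigma` and
#'   `objective_value` the 2-sum on the untransformed `s`.
#' @export
select_affinity_scale <- function(s, sigmas = NULL,
                                  normalized_laplacian = FALSE) {
  sm <- unclass(s)
  if (is.null(sigmas)) {
    dis <- (1 - sm)[upper.tri(sm)]
    sigmas <- unique(quantile(dis, probs = seq(0.1, 0.9, by = 0.1),
                              names = FALSE))
    sigmas <- sigmas[sigmas > 0]
    if (length(sigmas) == 0) sigmas <- 1
  }
  if (length(sigmas) == 0 || any(sigmas <= 0)) {
    abort("sigmas must be a non-empty grid of positive values")
  }
  sigmas <- sort(sigmas)
  best <- NULL
  for (sg in sigmas) {
    # a very small sigma can underflow the kernel and fragment the graph;
    # such candidates are still scored (and typically lose), so the
    # disconnection warning is deferred to the winning ordering
    ord <- withCallingHandlers(
      spectral_order(affinity_transform(s, sg),
                     normalized_laplacian = normalized_laplacian),
      warning = function(w) {
        if (grepl("disconnected", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    score <- two_sum_objective(sm, ord$permutation)
    if (is.null(best) || score < best$score) {
      ord$scale_used <- sg
      ord$objective_value <- score
      best <- list(ord = ord, score = score)
    }
  }
  if (best$ord$disconnected) {
    warn(sprintf("affinity graph disconnected at the selected scale %.4g",
                 best$ord$scale_used))
  }
  best$ord
}
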