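# Internal numerical helpers shared across modules.

# Small positive guard used inside divisions and logarithms; keeps the
# multiplicative updates monotone to numerical tolerance without moving
# fixed points appreciably.
.EPS <- 1e-12

#' Extract the upper triangle of a square matrix as a vector
#'
#' Off-diagonal entries above the diagonal, in column-major order. Distance
#' and similarity matrices in this package are symmetric, so the upper
#' triangle carries all pairwise information.
#'
#' @param m square matrix.
#' @return numeric vector of length `n * (n - 1) / 2`.
#' @keywords internal
#' @noRd
upper_tri_vec <- function(m) {
  m[upper.tri(m)]
}

# Scale columns of a matrix to unit Euclidean norm. Zero columns trigger an
# error unless `allow_zero` drops them from scaling (left as zero).
unit_norm_cols <- function(m, allow_zero = FALSE, what = "column") {
  nrm <- sqrt(colSums(m^2))
  if (any(nrm == 0)) {
    if (!allow_zero) {
      abort(sprintf("degenerate %s with zero Euclidean norm at index %s",
                    what, paste(which(nrm == 0), collapse = ", ")))
    }
    nrm[nrm == 0] <- 1
  }
  sweep(m, 2, nrm, "/")
}

unit_sum_cols <- function(m, what = "column") {
  s <- colSums(m)
  if (any(s <= 0)) {
    abort(sprintf("degenerate %s with non-positive sum at index %s",
                  what, paste(which(s <= 0), collapse = ", ")))
  }
  sweep(m, 2, s, "/")
}

# All permutations of 1..n as a list; used by small exhaustive oracles and
# exact component matching. Only sensible for n <= 8.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Match estimated components to reference components
#'
#' Finds the permutation of estimated components maximizing the total cosine
#' similarity with reference components (columns of two non-negative
#' matrices). Exhaustive over permutations for small ranks, greedy otherwise.
#'
#' @param ref,est matrices with the same number of rows; components as columns.
#' @return list with `perm` (for each reference column, the index of the
#'   matched estimated column) and `cosines` (per matched pair).
#' @export
match_components <- function(ref, est) {
  stopifnot(nrow(ref) == nrow(est), ncol(ref) == ncol(est))
  k <- ncol(ref)
  cs <- crossprod(unit_norm_cols(ref, allow_zero = TRUE),
                  unit_norm_cols(est, allow_zero = TRUE))
  if (k <= 8L) {
    best <- NULL
    best_val <- -Inf
    for (p in all_permutations(k)) {
      v <- sum(cs[cbind(seq_len(k), p)])
      if (v > best_val) {
        best_val <- v
        best <- p
      }
    }
  } else {
    # greedy: repeatedly take the best remaining (ref, est) pair
    best <- integer(k)
    cs2 <- cs
    for (i in seq_len(k)) {
      ij <- arrayInd(which.max(cs2), dim(cs2))
      best[ij[1]] <- ij[2]
      cs2[ij[1], ] <- -Inf
      cs2[, ij[2]] <- -Inf
    }
  }
  list(perm = as.integer(best), cosines = cs[cbind(seq_len(k), best)])
}

# Validate a square symmetric matrix with ids; shared by similarity and
# distance constructors.
check_square_ids <- function(values, ids) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    abort("values must be a square matrix")
  }
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  if (length(ids) != nrow(values)) abort("ids length must match matrix dimension")
  if (anyDuplicated(ids)) abort("ids must be unique")
  dimnames(values) <- list(ids, ids)
  values
}

derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2147483647L
}
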