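# Shared fixture builders; everything is generated in code at test time.

# Small planted dataset used across recovery tests.
small_config <- function(seed = 1L, ...) {
  args <- list(n_families = 200L, n_sites = 30L, true_rank = 4L,
               families_per_component = 40L, ubiquitous_fraction = 0.1,
               sequencing_depth = 1e4, env_link_strength = 5, seed = seed)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

# Noiseless profile matrix: exact product of planted factors (depth -> Inf).
noiseless_profile <- function(config) {
  comp <- generate_components(config)
  site <- generate_site_profiles(config)
  x <- comp$true_W %*% site$true_H
  list(x = profile_matrix(sweep(x, 2, colSums(x), "/"), normalized = TRUE),
       true_W = comp$true_W, true_H = site$true_H,
       membership = comp$membership, metadata = site$metadata)
}

# Random Euclidean distance matrix over n sites (a valid metric).
random_distance <- function(n, seed, kind = "environmental", dim = 3) {
  set.seed(seed)
  pts <- matrix(rnorm(n * dim), n)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(paste0("S", seq_len(n)), paste0("S", seq_len(n)))
  distance_matrix(m, kind = kind)
}

# Independent 2-sum evaluation used as the reordering oracle.
two_sum_oracle <- function(m, perm) {
  pos <- integer(length(perm))
  pos[perm] <- seq_along(perm)
  sum(unclass(m) * outer(pos, pos, function(i, j) (i - j)^2))
}

# All permutations of 1..n, for exhaustive oracles (n <= 8).
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_oracle(n - 1)) {
    for (k in 0:(n - 1)) out[[length(out) + 1]] <- append(p, n, after = k)
  }
  out
}

expect_valid_similarity <- function(s) {
  m <- unclass(s)
  expect_lte(max(abs(m - t(m))), 1e-10)
  expect_lte(max(abs(diag(m) - 1)), 1e-10)
}

expect_valid_distance <- function(d) {
  m <- unclass(d)
  expect_lte(max(abs(m - t(m))), 1e-10)
  expect_identical(unname(diag(m)), rep(0, nrow(m)))
  expect_true(all(m >= 0))
}
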