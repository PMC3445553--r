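#' Distance matrix container
#'
#' Square symmetric non-negative matrix with an exactly zero diagonal over
#' sampling sites, tagged with the kind of distance it holds.
#'
#' @param values square symmetric non-negative matrix.
#' @param ids site identifiers; defaults to row names.
#' @param kind one of `"functional_filtered"`, `"functional_unfiltered"`,
#'   `"functional_pca"`, `"environmental"`, `"geographic"`,
#'   `"geographic_logged"`.
#' @return a `distance_matrix` object (matrix with attributes).
#' @export
distance_matrix <- function(values, ids = NULL,
                            kind = c("functional_filtered",
                                     "functional_unfiltered",
                                     "functional_pca", "environmental",
                                     "geographic", "geographic_logged")) {
  kind <- match.arg(kind)
  values <- check_square_ids(values, ids)
  if (max(abs(values - t(values))) > 1e-10) abort("distance matrix must be symmetric")
  values <- (values + t(values)) / 2
  if (any(values < 0)) abort("distance matrix must be non-negative")
  diag(values) <- 0
  structure(values, kind = kind, class = c("distance_matrix", "matrix", "array"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d x %d, kind '%s'\n",
              nrow(x), ncol(x), attr(x, "kind")))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

dist_to_matrix <- function(d, ids, kind) {
  m <- as.matrix(d)
  dimnames(m) <- list(ids, ids)
  distance_matrix(m, kind = kind)
}

#' NMF-filtered functional distance between sites
#'
#' Euclidean distance between sites in component space: the columns of `H`
#' are first scaled to unit sum (mixing proportions), then compared
#' pairwise. Using the factorization as a noise filter, this distance
#' ignores variation that the components do not capture.
#'
#' @param fit an `nmf_fit`.
#' @return a `distance_matrix` (kind `"functional_filtered"`).
#' @export
filtered_functional_distance <- function(fit) {
  stopifnot(inherits(fit, "nmf_fit"))
  hn <- unit_sum_cols(fit$H, what = "site column")
  dist_to_matrix(dist(t(hn)), colnames(fit$H), "functional_filtered")
}

#' Unfiltered functional distance between sites
#'
#' Euclidean distance between the raw relative-abundance columns of the
#' profile matrix, with no dimension reduction.
#'
#' @param x a normalized [profile_matrix()].
#' @return a `distance_matrix` (kind `"functional_unfiltered"`).
#' @export
unfiltered_functional_distance <- function(x) {
  stopifnot(inherits(x, "profile_matrix"))
  if (!x$normalized) warn("computing functional distance on unnormalized counts")
  dist_to_matrix(dist(t(x$values)), colnames(x$values), "functional_unfiltered")
}

#' PCA-filtered functional distance between sites
#'
#' Baseline filter for comparison with the NMF-filtered distance: family
#' rows are centered across sites, site columns are projected onto the top
#' `n_components` principal directions, and sites are compared by Euclidean
#' distance in score space. With all components retained this reproduces the
#' unfiltered distance (rotation invariance).
#'
#' @param x a normalized [profile_matrix()].
#' @param n_components number of principal components, at most
#'   `min(n_families, n_sites - 1)`.
#' @return a `distance_matrix` (kind `"functional_pca"`).
#' @export
pca_filtered_distance <- function(x, n_components) {
  stopifnot(inherits(x, "profile_matrix"))
  v <- x$values
  max_comp <- min(nrow(v), ncol(v) - 1L)
  if (!is.numeric(n_components) || n_components < 1 || n_components > max_comp) {
    abort(sprintf("n_components must lie in [1, %d]", max_comp))
  }
  pc <- prcomp(t(v), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  dist_to_matrix(dist(scores), colnames(v), "functional_pca")
}

#' Environmental distance between sites
#'
#' Euclidean distance over standardized environmental variables: water depth
#' is square-root transformed (very deep ocean otherwise dominates), missing
#' cells are imputed with the per-variable mean of the observed values, each
#' variable is z-scored across sites, and sites are compared in the
#' resulting space. A variable with zero variance after imputation carries
#' no information and is dropped with a warning.
#'
#' @param metadata a tibble with `sample_id` and the six environmental
#'   variables (see [read_metadata()]).
#' @param variables environmental variable names to use.
#' @return a `distance_matrix` (kind `"environmental"`) with attribute
#'   `"dropped_variables"`.
#' @export
environmental_distance <- function(metadata, variables = env_var_names()) {
  missing_cols <- setdiff(variables, names(metadata))
  if (length(missing_cols) > 0) {
    abort(sprintf("metadata lacks variables: %s", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(metadata) < 2) abort("need at least two sites")
  z <- sapply(variables, function(v) {
    col <- metadata[[v]]
    if (v == "water_depth") {
      if (any(col < 0, na.rm = TRUE)) abort("water_depth must be non-negative")
      col <- sqrt(col)
    }
    if (all(is.na(col))) col[] <- 0 else col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  sds <- apply(z, 2, sd)
  dropped <- variables[sds == 0]
  if (length(dropped) > 0) {
    warn(sprintf("zero-variance environmental variables dropped: %s",
                 paste(dropped, collapse = ", ")))
  }
  keep <- sds > 0
  if (!any(keep)) abort("no environmental variable with positive variance")
  z <- scale(z[, keep, drop = FALSE])
  out <- dist_to_matrix(dist(z), metadata$sample_id, "environmental")
  attr(out, "dropped_variables") <- dropped
  out
}

#' Great-circle geographic distance between sites
#'
#' Haversine distance on a sphere between every pair of sampling locations.
#' Longitudes in `[-180, 360)` are accepted and canonicalized to
#' `[-180, 180)`.
#'
#' @param metadata a tibble with `sample_id`, `latitude`, `longitude` in
#'   decimal degrees.
#' @param radius_km sphere radius; default the IUGG mean Earth radius.
#' @return a `distance_matrix` (kind `"geographic"`) in kilometres.
#' @export
geographic_distance <- function(metadata, radius_km = 6371.0088) {
  lat <- metadata$latitude
  lon <- metadata$longitude
  bad <- which(is.na(lat) | is.na(lon) | lat < -90 | lat > 90 |
                 lon < -180 | lon >= 360)
  if (length(bad) > 0) {
    abort(sprintf("invalid coordinates for site '%s'",
                  metadata$sample_id[bad[1]]))
  }
  lon <- ((lon + 180) %% 360) - 180
  n <- length(lat)
  coords <- cbind(lon, lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    d[i, js] <- geosphere::distHaversine(coords[i, , drop = FALSE],
                                         coords[js, , drop = FALSE],
                                         r = radius_km)
    d[js, i] <- d[i, js]
  }
  dist_to_matrix(d, metadata$sample_id, "geographic")
}

#' Log-transform a geographic distance matrix
#'
#' Maps every entry through `log10(d + 1)` (distance in km) so that very
#' large ocean-basin separations do not dominate correlation analyses; the
#' diagonal stays zero and the ordering of the off-diagonal entries is
#' preserved.
#'
#' @param d a `distance_matrix` (typically kind `"geographic"`).
#' @return a `distance_matrix` (kind `"geographic_logged"`).
#' @export
log_transform_distance <- function(d) {
  stopifnot(inherits(d, "distance_matrix"))
  distance_matrix(log10(unclass(d) + 1), kind = "geographic_logged")
}

#' Similarity from a distance matrix
#'
#' Linear rescaling `S = 1 - d / max(d)` off the diagonal, 1 on it: the
#' closest pair gets similarity near 1, the farthest pair exactly 0. Used to
#' put environmental distance on the same footing as functional similarity
#' when exporting top site-pair links. If all distances are zero the result
#' is the all-ones matrix.
#'
#' @param d a `distance_matrix`.
#' @return a `similarity_matrix` (kind `"environmental"`).
#' @export
similarity_from_distance <- function(d) {
  stopifnot(inherits(d, "distance_matrix"))
  dm <- unclass(d)
  mx <- max(dm)
  s <- if (mx == 0) matrix(1, nrow(dm), ncol(dm)) else 1 - dm / mx
  diag(s) <- 1
  dimnames(s) <- dimnames(dm)
  similarity_matrix(s, kind = "environmental")
}
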