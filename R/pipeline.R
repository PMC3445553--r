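#' Export the strongest site-pair links from a similarity matrix
#'
#' The `k` off-diagonal site pairs with the highest similarity, descending;
#' ties broken lexically by the pair of identifiers. This is the tabular
#' form of a map in which the most functionally (or environmentally)
#' similar sites are connected, whatever their geographic separation.
#'
#' @param s a `similarity_matrix`.
#' @param k number of pairs; at most `n * (n - 1) / 2`.
#' @return a tibble with `rank`, `id_1`, `id_2`, `similarity`.
#' @export
export_top_links <- function(s, k = 120L) {
  sm <- unclass(s)
  n <- nrow(sm)
  n_pairs <- n * (n - 1) / 2
  if (!is.numeric(k) || k < 1 || k > n_pairs) {
    abort(sprintf("k must lie in [1, %d]", n_pairs))
  }
  ids <- rownames(sm)
  ut <- which(upper.tri(sm), arr.ind = TRUE)
  tibble(id_1 = ids[ut[, 1]], id_2 = ids[ut[, 2]],
         similarity = sm[ut]) %>%
    arrange(desc(.data$similarity), .data$id_1, .data$id_2) %>%
    slice_head(n = as.integer(k)) %>%
    mutate(rank = dplyr::row_number()) %>%
    dplyr::select("rank", "id_1", "id_2", "similarity")
}

#' Run the full functional-biogeography analysis
#'
#' Orchestrates the whole pipeline: load (or generate) a family-count table
#' and site metadata, filter low-coverage samples, column-normalize, select
#' the factorization rank by restart concordance, fit the final NMF at the
#' selected rank, build family/site/component similarity matrices with
#' spectral orderings, score family-component associations and top-k
#' selections, compute the five distance matrices, and run the Mantel,
#' partial Mantel and naive-regression comparisons of functional versus
#' environmental and geographic distance. If metadata is absent the
#' distance and Mantel stages are skipped with a message; earlier stages are
#' still produced. All randomness derives from `seed`.
#'
#' @param counts a `profile_matrix` of raw counts, a path to a counts TSV,
#'   or `NULL` to generate data from `synthetic`.
#' @param metadata a metadata tibble, a path to a metadata TSV, or `NULL`.
#' @param synthetic a [synthetic_config()] used when `counts` is `NULL`.
#' @param rank_range candidate ranks for concordance selection.
#' @param n_runs restarts per rank.
#' @param rank_policy `"max"` or `"threshold"` (see [select_rank()]).
#' @param min_total minimum assignment count for a sample to be retained.
#' @param exclude sample identifiers to drop regardless of coverage.
#' @param association_method scoring method for family selection.
#' @param top_k families selected per component.
#' @param n_perm Mantel permutations.
#' @param n_links site pairs exported per similarity matrix.
#' @param seed master seed.
#' @param max_iter,tol passed to [nmf_kl()].
#' @param out_dir optional directory; when given, every result table and a
#'   manifest JSON (parameters, seed, dimensions, stage log) are written.
#' @return a named list with elements `profile`, `rank_selection`, `fit`,
#'   `similarities`, `orderings`, `associations`, `top_families`,
#'   `distances`, `tests`, `regressions`, `top_links`, `manifest`.
#' @export
run_nmf_biogeography <- function(counts = NULL,
                                 metadata = NULL,
                                 synthetic = NULL,
                                 rank_range = 2:8,
                                 n_runs = 20L,
                                 rank_policy = "max",
                                 min_total = 1L,
                                 exclude = character(),
                                 association_method = "correlation",
                                 top_k = 100L,
                                 n_perm = 999L,
                                 n_links = 120L,
                                 seed = 1L,
                                 max_iter = 2000L,
                                 tol = 1e-6,
                                 out_dir = NULL) {
  if (is.null(counts) && is.null(synthetic)) {
    abort("provide either counts (matrix or path) or a synthetic config")
  }
  if (!is.null(counts) && !is.null(synthetic)) {
    abort("provide exactly one of counts and synthetic")
  }
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  if (!is.null(synthetic)) {
    say("stage simulate: generating synthetic dataset (seed %d)", synthetic$seed)
    ds <- generate_dataset(synthetic)
    counts <- ds$counts
    metadata <- ds$metadata
  } else {
    if (is.character(counts)) counts <- read_counts(counts)
    if (is.character(metadata)) metadata <- read_metadata(metadata)
    ds <- NULL
  }
  say("stage profile: %d families x %d samples", nrow(counts$values),
      ncol(counts$values))
  filtered <- filter_samples(counts, min_total = min_total, exclude = exclude)
  dropped <- attr(filtered, "dropped")
  if (nrow(dropped) > 0) {
    say("stage filter: dropped %d samples (%s)", nrow(dropped),
        paste(dropped$sample_id, collapse = ", "))
  }
  x <- normalize_profile(filtered)
  if (!is.null(metadata)) {
    metadata <- metadata[match(colnames(x$values), metadata$sample_id), ]
    if (any(is.na(metadata$sample_id))) {
      abort("metadata lacks entries for some retained samples")
    }
  }

  say("stage rank: concordance over ranks %s (%d restarts)",
      paste(range(rank_range), collapse = ".."), n_runs)
  curve <- select_rank(x, rank_range = rank_range, n_runs = n_runs,
                       seed = seed, policy = rank_policy,
                       max_iter = max_iter, tol = tol)
  say("stage rank: selected rank %d", curve$selected_rank)

  fit <- nmf_kl(x, rank = curve$selected_rank, seed = derive_seed(seed, 77L),
                max_iter = max_iter, tol = tol)
  say("stage decompose: KL divergence %.6g after %d iterations",
      fit$divergence_trace[fit$n_iter], fit$n_iter)

  sims <- list(
    site = site_similarity(fit),
    family = family_similarity(fit),
    component_site = component_similarity(fit, "site"),
    component_functional = component_similarity(fit, "functional")
  )
  orderings <- list(
    site = select_affinity_scale(sims$site),
    family = select_affinity_scale(sims$family)
  )
  say("stage structure: site ordering sigma %.4g, family ordering sigma %.4g",
      orderings$site$scale_used, orderings$family$scale_used)

  assoc <- associate_families(x, fit, method = association_method)
  comps <- colnames(fit$W)
  top_fams <- lapply(setNames(comps, comps), function(cc) {
    select_top(assoc, cc, k = min(top_k, nrow(fit$W)))
  })
  ubiq <- ubiquity_score(fit)
  say("stage associate: %s scores for %d families x %d components",
      association_method, nrow(fit$W), fit$rank)

  dists <- list(
    functional_filtered = filtered_functional_distance(fit),
    functional_unfiltered = unfiltered_functional_distance(x),
    functional_pca = pca_filtered_distance(x, fit$rank)
  )
  tests <- list()
  regressions <- list()
  top_links <- list(functional = export_top_links(
    sims$site, k = min(n_links, ncol(x$values) * (ncol(x$values) - 1) / 2)))

  if (is.null(metadata)) {
    say("stage distances: no metadata; environmental/geographic stages skipped")
  } else {
    dists$environmental <- environmental_distance(metadata)
    dists$geographic <- geographic_distance(metadata)
    dists$geographic_logged <- log_transform_distance(dists$geographic)
    say("stage distances: all five distance matrices over %d sites",
        nrow(metadata))
    tests <- list(
      mantel_env = mantel(dists$functional_filtered, dists$environmental,
                          n_perm = n_perm, seed = derive_seed(seed, 11L)),
      mantel_geo = mantel(dists$functional_filtered, dists$geographic_logged,
                          n_perm = n_perm, seed = derive_seed(seed, 12L)),
      partial_env_given_geo = partial_mantel(
        dists$functional_filtered, dists$environmental,
        dists$geographic_logged, n_perm = n_perm,
        seed = derive_seed(seed, 13L)),
      partial_geo_given_env = partial_mantel(
        dists$functional_filtered, dists$geographic_logged,
        dists$environmental, n_perm = n_perm,
        seed = derive_seed(seed, 14L))
    )
    say("stage mantel: r_env %.3f (p %.3g), r_geo %.3f (p %.3g); partial %.3f vs %.3f",
        tests$mantel_env$statistic, tests$mantel_env$p_value,
        tests$mantel_geo$statistic, tests$mantel_geo$p_value,
        tests$partial_env_given_geo$statistic,
        tests$partial_geo_given_env$statistic)
    predictors <- list(environmental = dists$environmental,
                       geographic_logged = dists$geographic_logged)
    regressions <- list(
      filtered = distance_regression(dists$functional_filtered, predictors),
      unfiltered = distance_regression(dists$functional_unfiltered, predictors),
      pca = distance_regression(dists$functional_pca, predictors)
    )
    say("stage regression: adjusted R^2 filtered %.3f, unfiltered %.3f, PCA %.3f",
        regressions$filtered$adj_r_squared,
        regressions$unfiltered$adj_r_squared,
        regressions$pca$adj_r_squared)
    env_sim <- similarity_from_distance(dists$environmental)
    top_links$environmental <- export_top_links(
      env_sim, k = min(n_links, nrow(metadata) * (nrow(metadata) - 1) / 2))
  }

  manifest <- list(
    package = "nmfbiogeo",
    version = as.character(utils::packageVersion("nmfbiogeo")),
    seed = as.integer(seed),
    parameters = list(
      rank_range = rank_range, n_runs = n_runs, rank_policy = rank_policy,
      min_total = min_total, exclude = exclude,
      association_method = association_method, top_k = top_k,
      n_perm = n_perm, n_links = n_links, max_iter = max_iter, tol = tol,
      synthetic = if (!is.null(ds)) unclass(ds$config) else NULL
    ),
    dimensions = list(n_families = nrow(x$values), n_samples = ncol(x$values),
                      selected_rank = curve$selected_rank),
    dropped_samples = dropped$sample_id,
    log = log_lines
  )

  result <- list(profile = x, rank_selection = curve, fit = fit,
                 similarities = sims, orderings = orderings,
                 associations = assoc, top_families = top_fams,
                 ubiquity = ubiq, distances = dists, tests = tests,
                 regressions = regressions, top_links = top_links,
                 manifest = manifest,
                 truth = if (!is.null(ds)) ds else NULL)
  if (!is.null(out_dir)) write_results(result, out_dir)
  result
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  readr::write_tsv(as_tibble(as.matrix(unclass(m)), rownames = id_col), path)
}

#' Write a pipeline result bundle to disk
#'
#' Writes every table of a [run_nmf_biogeography()] result in plain-text
#' form: matrices as TSV with identifier headers, orderings as rank/id TSV,
#' Mantel and regression results plus the manifest as JSON.
#'
#' @param result a result list from [run_nmf_biogeography()].
#' @param dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
write_results <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix_tsv(result$profile$values, file.path(dir, "profile_matrix.tsv"),
                   "family_id")
  write_matrix_tsv(result$fit$W, file.path(dir, "W.tsv"), "family_id")
  write_matrix_tsv(result$fit$H, file.path(dir, "H.tsv"), "component")
  readr::write_tsv(tidy(result$rank_selection),
                   file.path(dir, "concordance_curve.tsv"))
  for (nm in names(result$similarities)) {
    write_matrix_tsv(result$similarities[[nm]],
                     file.path(dir, paste0("similarity_", nm, ".tsv")))
  }
  for (nm in names(result$orderings)) {
    ord <- result$orderings[[nm]]
    readr::write_tsv(tibble(rank = seq_along(ord$ids), id = ord$ids),
                     file.path(dir, paste0("ordering_", nm, ".tsv")))
  }
  readr::write_tsv(result$associations, file.path(dir, "associations.tsv"))
  for (nm in names(result$top_families)) {
    readr::write_tsv(result$top_families[[nm]],
                     file.path(dir, paste0("top_families_", nm, ".tsv")))
  }
  readr::write_tsv(result$ubiquity, file.path(dir, "ubiquity.tsv"))
  for (nm in names(result$distances)) {
    write_matrix_tsv(result$distances[[nm]],
                     file.path(dir, paste0("distance_", nm, ".tsv")))
  }
  for (nm in names(result$top_links)) {
    readr::write_tsv(result$top_links[[nm]],
                     file.path(dir, paste0("top_links_", nm, ".tsv")))
  }
  stats_out <- list(
    tests = lapply(result$tests, function(t) {
      t$perm <- NULL
      unclass(t)
    }),
    regressions = lapply(result$regressions, unclass)
  )
  jsonlite::write_json(stats_out, file.path(dir, "matrix_stats.json"),
                       digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
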