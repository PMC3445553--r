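#' Configuration for the synthetic community generator
#'
#' Describes a planted low-rank functional structure: each of `true_rank`
#' components owns a block of "characteristic" families that load mostly on
#' that component, one block of "ubiquitous" families loads comparably on
#' every component (core metabolism), and the remaining "background" families
#' carry a small constant loading. Site mixing weights are Dirichlet-like so
#' that some components concentrate on a handful of sites. Environmental
#' variables are driven by the component site-weights while coordinates are
#' drawn independently of them — the contrast the downstream Mantel analysis
#' is designed to detect.
#'
#' @param n_families number of protein families (rows).
#' @param n_sites number of sampling sites (columns).
#' @param true_rank number of planted components.
#' @param families_per_component size of each characteristic block.
#' @param ubiquitous_fraction fraction of families in the ubiquitous block.
#' @param overlap_fraction fraction of characteristic families that also load
#'   on a second component, in `[0, 1)`.
#' @param sequencing_depth assignment count drawn per site (multinomial trials).
#' @param env_link_strength signal-to-noise of the environment-to-component
#'   coupling; 0 means environmental variables are pure noise.
#' @param missing_rate fraction of environmental cells set missing
#'   (missing completely at random).
#' @param dirichlet_conc concentration of the per-site Dirichlet mixing
#'   weights; values below 1 make components site-restricted.
#' @param seed integer seed; identical configurations yield bit-identical
#'   datasets.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_families = 500L,
                             n_sites = 45L,
                             true_rank = 4L,
                             families_per_component = 100L,
                             ubiquitous_fraction = 0.1,
                             overlap_fraction = 0,
                             sequencing_depth = 1e5,
                             env_link_strength = 5,
                             missing_rate = 0.05,
                             dirichlet_conc = 0.5,
                             seed = 1L) {
  cfg <- list(
    n_families = as.integer(n_families),
    n_sites = as.integer(n_sites),
    true_rank = as.integer(true_rank),
    families_per_component = as.integer(families_per_component),
    ubiquitous_fraction = ubiquitous_fraction,
    overlap_fraction = overlap_fraction,
    sequencing_depth = as.double(sequencing_depth),
    env_link_strength = env_link_strength,
    missing_rate = missing_rate,
    dirichlet_conc = dirichlet_conc,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_families < 1 || n_sites < 1 || true_rank < 1) {
      abort("n_families, n_sites and true_rank must be positive")
    }
    if (families_per_component < 1) abort("families_per_component must be positive")
    if (ubiquitous_fraction < 0 || ubiquitous_fraction > 1) {
      abort("ubiquitous_fraction must lie in [0, 1]")
    }
    if (overlap_fraction < 0 || overlap_fraction >= 1) {
      abort("overlap_fraction must lie in [0, 1)")
    }
    if (missing_rate < 0 || missing_rate > 1) abort("missing_rate must lie in [0, 1]")
    if (sequencing_depth < 1) abort("sequencing_depth must be at least 1")
    if (env_link_strength < 0) abort("env_link_strength must be non-negative")
    if (dirichlet_conc <= 0) abort("dirichlet_conc must be positive")
    n_char <- families_per_component * true_rank
    n_ubiq <- round(ubiquitous_fraction * n_families)
    if (n_char + n_ubiq > n_families) {
      abort(sprintf(
        "block sizes exceed n_families: %d characteristic + %d ubiquitous > %d",
        n_char, n_ubiq, n_families))
    }
  })
  structure(cfg, class = "synthetic_config")
}

env_var_names <- function() {
  c("salinity", "sample_depth", "chlorophyll", "temperature",
    "water_depth", "insolation")
}

#' Planted functional profiles (true W) and family memberships
#'
#' Builds the family-by-component loading matrix the generator plants:
#' characteristic blocks, a ubiquitous block, an overlap subset loading on a
#' second component, and a small constant background loading of
#' `1/(10 * n_families)` for everything else (strictly positive so that
#' multiplicative updates never stall on exact zeros). Columns are scaled to
#' sum to one.
#'
#' @param config a [synthetic_config()].
#' @return list with `true_W` (family x rank matrix) and `membership`, a
#'   tibble with one row per family: `family_id`, `component` (label
#'   `"component_<j>"`, `"ubiquitous"` or `"background"`), and
#'   `second_component` (`NA` unless the family is in the overlap subset).
#' @export
generate_components <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(derive_seed(config$seed, 101L), {
    p <- config$n_families
    k <- config$true_rank
    m <- config$families_per_component
    n_ubiq <- round(config$ubiquitous_fraction * p)
    bg <- 1 / (10 * p)
    W <- matrix(bg, nrow = p, ncol = k)
    fam_ids <- sprintf("F%05d", seq_len(p))
    comp_label <- rep("background", p)
    second <- rep(NA_character_, p)
    n_overlap <- round(config$overlap_fraction * m)
    for (j in seq_len(k)) {
      rows <- ((j - 1L) * m + 1L):(j * m)
      W[rows, j] <- runif(m, 0.8, 1.2)
      comp_label[rows] <- paste0("component_", j)
      if (n_overlap > 0 && k > 1) {
        ov_rows <- rows[seq_len(n_overlap)]
        other <- if (j < k) j + 1L else 1L
        W[ov_rows, other] <- 0.5 * W[ov_rows, j]
        second[ov_rows] <- paste0("component_", other)
      }
    }
    if (n_ubiq > 0) {
      rows <- (k * m + 1L):(k * m + n_ubiq)
      W[rows, ] <- matrix(runif(n_ubiq * k, 0.8, 1.2), nrow = n_ubiq)
      comp_label[rows] <- "ubiquitous"
    }
    rownames(W) <- fam_ids
    colnames(W) <- paste0("component_", seq_len(k))
    list(
      true_W = sweep(W, 2, colSums(W), "/"),
      membership = tibble(family_id = fam_ids, component = comp_label,
                          second_component = second)
    )
  })
}

rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = k)
  sweep(g, 2, colSums(g), "/")
}

#' Planted site profiles (true H) and site metadata
#'
#' Draws per-site component mixing weights from a symmetric Dirichlet with
#' concentration `dirichlet_conc` (columns sum to one), then generates six
#' environmental variables as linear functions of the component weights,
#' scaled by `env_link_strength`, plus unit Gaussian noise; each variable is
#' finally mapped onto a plausible oceanographic scale. Latitude and
#' longitude are drawn uniformly over a lat [-60, 60], lon [-180, 180) box,
#' independently of the component weights. A `missing_rate` fraction of
#' environmental cells is blanked at random.
#'
#' @param config a [synthetic_config()].
#' @return list with `true_H` (rank x site matrix, columns summing to one)
#'   and `metadata`, a tibble with `sample_id`, `latitude`, `longitude` and
#'   the six environmental variables.
#' @export
generate_site_profiles <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(derive_seed(config$seed, 202L), {
    n <- config$n_sites
    k <- config$true_rank
    H <- rdirichlet_mat(n, rep(config$dirichlet_conc, k))
    rownames(H) <- paste0("component_", seq_len(k))
    site_ids <- sprintf("S%03d", seq_len(n))
    colnames(H) <- site_ids

    vars <- env_var_names()
    B <- matrix(rnorm(length(vars) * k), nrow = length(vars))
    signal <- B %*% H                       # 6 x n linear responses
    # standardize each signal row so env_link_strength is a signal-to-noise
    # ratio on a common scale; guard rank-1 (H rows constant => sd 0)
    sds <- apply(signal, 1, sd)
    sds[sds == 0] <- 1
    raw <- config$env_link_strength * (signal - rowMeans(signal)) / sds +
      matrix(rnorm(length(vars) * n), nrow = length(vars))
    dimnames(raw) <- list(vars, NULL)

    meta <- tibble(
      sample_id = site_ids,
      latitude = runif(n, -60, 60),
      longitude = runif(n, -180, 180),
      salinity = 35 + raw["salinity", ],
      sample_depth = exp(1 + 0.4 * raw["sample_depth", ]),
      chlorophyll = exp(-1 + 0.5 * raw["chlorophyll", ]),
      temperature = 18 + 4 * raw["temperature", ],
      water_depth = exp(5 + raw["water_depth", ]),
      insolation = 200 + 30 * raw["insolation", ]
    )
    if (config$missing_rate > 0) {
      for (v in vars) {
        miss <- runif(n) < config$missing_rate
        meta[[v]][miss] <- NA_real_
      }
    }
    list(true_H = H, metadata = meta)
  })
}

#' Draw multinomial sequencing counts from planted factors
#'
#' For each site, `depth` assignment counts are drawn multinomially with
#' probabilities proportional to the site's column of `true_W %*% true_H` —
#' the count-noise model for a relative-abundance profile at finite
#' sequencing depth.
#'
#' @param true_W family x rank non-negative matrix.
#' @param true_H rank x site non-negative matrix.
#' @param depth number of trials per site.
#' @param seed integer seed.
#' @return integer family x site matrix whose columns each sum to `depth`.
#' @export
sample_counts <- function(true_W, true_H, depth, seed = 1L) {
  stopifnot(all(true_W >= 0), all(true_H >= 0), depth >= 1)
  expected <- true_W %*% true_H
  cs <- colSums(expected)
  if (any(cs <= 0)) {
    abort(sprintf("site %d has an all-zero expected profile",
                  which(cs <= 0)[1]))
  }
  withr::with_seed(derive_seed(seed, 303L), {
    counts <- vapply(seq_len(ncol(expected)), function(s) {
      rmultinom(1, size = depth, prob = expected[, s])[, 1]
    }, numeric(nrow(expected)))
    storage.mode(counts) <- "integer"
    dimnames(counts) <- dimnames(expected)
    counts
  })
}

#' Generate a full synthetic dataset with known ground truth
#'
#' Composes [generate_components()], [generate_site_profiles()] and
#' [sample_counts()] into a dataset carrying the planted factors, the family
#' membership labels, the sampled counts and the site metadata — the ground
#' truth every downstream recovery test compares against.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_dataset` list with elements `counts` (profile_matrix,
#'   raw counts), `true_W`, `true_H`, `membership`, `metadata`, `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  comp <- generate_components(config)
  site <- generate_site_profiles(config)
  counts <- sample_counts(comp$true_W, site$true_H,
                          depth = config$sequencing_depth,
                          seed = config$seed)
  structure(list(
    counts = profile_matrix(counts, normalized = FALSE),
    true_W = comp$true_W,
    true_H = site$true_H,
    membership = comp$membership,
    metadata = site$metadata,
    config = config
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_dataset> %d families x %d sites, ",
                     "planted rank %d, depth %g, seed %d\n"),
              x$config$n_families, x$config$n_sites, x$config$true_rank,
              x$config$sequencing_depth, x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to fixture files
#'
#' Counts as TSV (first column `family_id`, header of sample identifiers),
#' metadata as TSV (empty cell = missing), and the ground truth (factors,
#' membership, configuration echo) as a JSON sidecar.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory, created if needed.
#' @return named character vector of the files written, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_counts(dataset$counts, paths["counts"])
  readr::write_tsv(dataset$metadata, paths["metadata"], na = "")
  truth <- list(
    true_W = dataset$true_W,
    true_H = dataset$true_H,
    membership = dataset$membership,
    config = unclass(dataset$config)
  )
  jsonlite::write_json(truth, paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Read site metadata from TSV
#'
#' Expects columns `sample_id`, `latitude`, `longitude` and the six
#' environmental variables (`salinity`, `sample_depth`, `chlorophyll`,
#' `temperature`, `water_depth`, `insolation`); empty cells are missing.
#'
#' @param path path to a tab-separated metadata file.
#' @return a tibble.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    .default = readr::col_double()), na = c("", "NA"))
  need <- c("sample_id", "latitude", "longitude", env_var_names())
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort(sprintf("metadata is missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  meta
}
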