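#' Profile matrices of family counts or relative abundances
#'
#' A `profile_matrix` holds a protein-family-by-site matrix: raw assignment
#' counts straight from a homology search, or column-normalized relative
#' abundances once [normalize_profile()] has been applied. Rows are protein
#' families (e.g. Pfam accessions), columns are sampling sites. All analyses
#' in the package consume this container.
#'
#' @param values non-negative numeric matrix, families in rows, sites in
#'   columns, with row and column names (unique identifiers).
#' @param normalized logical; `TRUE` once every column sums to one.
#' @return a `profile_matrix` object.
#' @export
profile_matrix <- function(values, normalized = FALSE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("F", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) abort("duplicate family identifiers")
  if (anyDuplicated(colnames(values))) abort("duplicate sample identifiers")
  if (any(!is.finite(values))) abort("profile matrix contains non-finite cells")
  if (any(values < 0)) {
    ij <- arrayInd(which(values < 0)[1], dim(values))
    abort(sprintf("negative cell at family '%s', sample '%s'",
                  rownames(values)[ij[1]], colnames(values)[ij[2]]))
  }
  if (normalized) {
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-12)) {
      abort("normalized = TRUE but column sums deviate from 1 beyond 1e-12")
    }
  }
  structure(list(values = values, normalized = normalized),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d families x %d sites (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "relative abundances" else "raw counts"))
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$values)

#' @rdname profile_matrix
#' @param x a `profile_matrix`.
#' @param ... unused.
#' @export
as_tibble.profile_matrix <- function(x, ...) {
  as_tibble(x$values, rownames = "family_id") %>%
    tidyr::pivot_longer(-"family_id", names_to = "sample_id",
                        values_to = "abundance")
}

#' Read a family-count table from TSV
#'
#' Expects a header row of sample identifiers and a first column of family
#' identifiers; every remaining cell must parse as a non-negative number.
#' Integer counts are preserved exactly.
#'
#' @param path path to a tab-separated file.
#' @return an unnormalized [profile_matrix()].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  prob <- readr::stop_for_problems(tab)
  if (nrow(tab) == 0 || ncol(tab) < 2) abort("empty or column-less count table")
  fam <- tab[[1]]
  if (anyDuplicated(fam)) {
    abort(sprintf("duplicate family identifier '%s'", fam[anyDuplicated(fam)]))
  }
  body <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(apply(body, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(body), dimnames = dimnames(body))
  bad <- which(is.na(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric or negative cell at family '%s', sample '%s'",
                  fam[bad[1, 1]], colnames(body)[bad[1, 2]]))
  }
  rownames(num) <- fam
  profile_matrix(num, normalized = FALSE)
}

#' Write a profile matrix to TSV
#'
#' Inverse of [read_counts()]: first column `family_id`, one column per sample.
#'
#' @param m a `profile_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path) {
  stopifnot(inherits(m, "profile_matrix"))
  tab <- as_tibble(m$values, rownames = "family_id")
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Drop low-coverage samples from a count table
#'
#' Removes samples whose total assignment count falls below `min_total`,
#' mirroring the routine exclusion of samples with very few reads. An
#' explicit `exclude` list of sample identifiers supports dataset-specific
#' curation without encoding it as an algorithm.
#'
#' @param m an unnormalized `profile_matrix`.
#' @param min_total minimum column sum a sample must reach to be retained.
#' @param exclude character vector of sample identifiers to drop regardless
#'   of coverage.
#' @return a `profile_matrix` with attribute `"dropped"`: a tibble of the
#'   removed samples and the reason (`low_count` or `excluded`).
#' @export
filter_samples <- function(m, min_total = 1L, exclude = character()) {
  stopifnot(inherits(m, "profile_matrix"))
  if (m$normalized) abort("filter_samples expects raw counts, not normalized abundances")
  totals <- colSums(m$values)
  low <- totals < min_total
  excl <- colnames(m$values) %in% exclude
  drop <- low | excl
  if (all(drop)) abort("all samples dropped; lower min_total or shorten exclude list")
  dropped <- tibble(
    sample_id = colnames(m$values)[drop],
    total = totals[drop],
    reason = ifelse(excl[drop], "excluded", "low_count")
  )
  out <- profile_matrix(m$values[, !drop, drop = FALSE], normalized = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Column-normalize a count table to relative abundances
#'
#' Divides each sample's counts by the sample's total so that every column
#' sums to one — the profile matrix consumed by the factorization. Idempotent.
#'
#' @param m a `profile_matrix`; every column must have a positive sum.
#' @return a normalized `profile_matrix`.
#' @export
normalize_profile <- function(m) {
  stopifnot(inherits(m, "profile_matrix"))
  cs <- colSums(m$values)
  if (any(cs <= 0)) {
    abort(sprintf("sample '%s' has zero total; run filter_samples() first",
                  colnames(m$values)[which(cs <= 0)[1]]))
  }
  profile_matrix(sweep(m$values, 2, cs, "/"), normalized = TRUE)
}
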