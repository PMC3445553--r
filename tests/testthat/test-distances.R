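test_that("filtered functional distance matches a brute-force pairwise loop", {
  set.seed(71)
  H <- matrix(runif(4 * 8), 4, 8, dimnames = list(NULL, paste0("S", 1:8)))
  fit <- structure(list(W = matrix(runif(40), 10, 4), H = H, rank = 4L),
                   class = "nmf_fit")
  d <- filtered_functional_distance(fit)
  expect_valid_distance(d)
  hn <- sweep(H, 2, colSums(H), "/")
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(unclass(d)[i, j], sqrt(sum((hn[, i] - hn[, j])^2)),
                 tolerance = 1e-12)
  }
  # pure mixtures (1,0) vs (0,1) are sqrt(2) apart
  fit2 <- structure(list(H = cbind(a = c(1, 0), b = c(0, 1)), rank = 2L),
                    class = "nmf_fit")
  expect_equal(unclass(filtered_functional_distance(fit2))[1, 2], sqrt(2))
  # identical mixing vectors are at distance zero
  fit3 <- structure(list(H = cbind(a = c(2, 1), b = c(4, 2)), rank = 2L),
                    class = "nmf_fit")
  expect_equal(unclass(filtered_functional_distance(fit3))[1, 2], 0)
})

test_that("unfiltered distance reproduces hand arithmetic and the metric laws", {
  x <- profile_matrix(cbind(a = c(0.2, 0.3, 0.5), b = c(0.5, 0.3, 0.2),
                            c = c(0.2, 0.3, 0.5)), normalized = TRUE)
  rownames(x$values) <- paste0("f", 1:3)
  x <- profile_matrix(x$values, normalized = TRUE)
  d <- unfiltered_functional_distance(x)
  expect_equal(unclass(d)["a", "b"], sqrt(2 * 0.09), tolerance = 1e-12)
  expect_equal(unclass(d)["a", "c"], 0)
  # triangle inequality on random triples
  set.seed(72)
  xr <- matrix(runif(20 * 10), 20, 10)
  xr <- sweep(xr, 2, colSums(xr), "/")
  dr <- unclass(unfiltered_functional_distance(
    profile_matrix(xr, normalized = TRUE)))
  for (t in 1:100) {
    ijk <- sample.int(10, 3)
    expect_lte(dr[ijk[1], ijk[2]],
               dr[ijk[1], ijk[3]] + dr[ijk[3], ijk[2]] + 1e-12)
  }
})

test_that("full-dimensional PCA filtering reproduces the unfiltered distance", {
  set.seed(73)
  xr <- matrix(runif(30 * 8), 30, 8)
  xr <- sweep(xr, 2, colSums(xr), "/")
  x <- profile_matrix(xr, normalized = TRUE)
  d_full <- pca_filtered_distance(x, n_components = 7)
  d_raw <- unfiltered_functional_distance(x)
  expect_equal(unclass(d_full), unclass(d_raw), tolerance = 1e-8,
               ignore_attr = TRUE)
  # exactly rank-2 data needs only 2 components
  W <- matrix(runif(60), 30, 2)
  H <- matrix(runif(16), 2, 8)
  x2m <- W %*% H
  x2 <- profile_matrix(sweep(x2m, 2, colSums(x2m), "/"), normalized = TRUE)
  expect_equal(unclass(pca_filtered_distance(x2, 2)),
               unclass(unfiltered_functional_distance(x2)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_filtered_distance(x, 0), "n_components")
  expect_error(pca_filtered_distance(x, 50), "n_components")
})

test_that("environmental distance applies sqrt, imputation and z-scoring", {
  meta <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    latitude = 0, longitude = 0,
    salinity = c(30, 35, 40),
    sample_depth = c(1, NA, 3),
    chlorophyll = c(NA, NA, NA),
    temperature = c(10, 20, 30),
    water_depth = c(100, 400, 900),
    insolation = c(150, 150, 150))
  expect_warning(d <- environmental_distance(meta), "zero-variance")
  expect_valid_distance(d)
  expect_setequal(attr(d, "dropped_variables"), c("chlorophyll", "insolation"))
  # explicit arithmetic oracle: z-score each used variable by hand
  z <- function(v) (v - mean(v)) / sd(v)
  cols <- cbind(z(c(30, 35, 40)), z(c(1, 2, 3)), z(c(10, 20, 30)),
                z(sqrt(c(100, 400, 900))))
  want <- as.matrix(dist(cols))
  expect_equal(unclass(d), want, tolerance = 1e-12, ignore_attr = TRUE)
  # identical rows at distance zero
  meta2 <- meta[c(1, 1, 3), ]
  meta2$sample_id <- c("a", "b", "c")
  expect_warning(d2 <- environmental_distance(meta2), "zero-variance")
  expect_equal(unclass(d2)["a", "b"], 0)
  # affine rescaling of a variable does not change the distance
  meta3 <- meta
  meta3$temperature <- 32 + 1.8 * meta3$temperature
  expect_warning(d3 <- environmental_distance(meta3), "zero-variance")
  expect_equal(unclass(d3), unclass(d), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("great-circle distances reproduce analytic values", {
  meta <- tibble::tibble(sample_id = c("o", "anti", "quarter", "same"),
                         latitude = c(0, 0, 0, 0),
                         longitude = c(0, 180, 90, 0))
  d <- unclass(geographic_distance(meta))
  expect_equal(d["o", "anti"], pi * 6371.0088, tolerance = 1e-6)
  expect_equal(d["o", "quarter"], pi * 6371.0088 / 2, tolerance = 1e-6)
  expect_equal(d["o", "same"], 0)
  # longitudes in [180, 360) are canonicalized
  meta2 <- tibble::tibble(sample_id = c("a", "b"), latitude = c(0, 0),
                          longitude = c(270, -90))
  expect_equal(unclass(geographic_distance(meta2))["a", "b"], 0,
               tolerance = 1e-9)
  bad <- tibble::tibble(sample_id = "x", latitude = 95, longitude = 0)
  expect_error(geographic_distance(bad), "x")
})

test_that("log transform is monotone with the documented anchor points", {
  meta <- tibble::tibble(sample_id = c("a", "b", "c"),
                         latitude = c(0, 0, 10), longitude = c(0, 8.98, 40))
  d <- geographic_distance(meta)
  ld <- log_transform_distance(d)
  expect_valid_distance(ld)
  m <- matrix(c(0, 999, 999, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  d999 <- distance_matrix(m, kind = "geographic")
  expect_equal(unclass(log_transform_distance(d999))["a", "b"], 3)
  # order of off-diagonal entries preserved
  v <- upper.tri(unclass(d))
  expect_identical(order(unclass(d)[v]), order(unclass(ld)[v]))
})

test_that("distance-derived similarity anchors its extremes", {
  d <- random_distance(6, seed = 74)
  s <- similarity_from_distance(d)
  expect_valid_similarity(s)
  dm <- unclass(d)
  sm <- unclass(s)
  far <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  expect_equal(sm[far[1], far[2]], 0)
  # zero distances map to similarity 1
  zm <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  sz <- similarity_from_distance(distance_matrix(zm, kind = "geographic"))
  expect_true(all(unclass(sz) == 1))
})

test_that("filtered and unfiltered distances agree in rank on noiseless data", {
  nl <- noiseless_profile(small_config(seed = 75L))
  fit <- nmf_kl(nl$x, rank = 4, seed = 1, max_iter = 3000, tol = 1e-9)
  df <- unclass(filtered_functional_distance(fit))
  du <- unclass(unfiltered_functional_distance(nl$x))
  rho <- cor(df[upper.tri(df)], du[upper.tri(du)], method = "spearman")
  expect_gte(rho, 0.9)
})
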