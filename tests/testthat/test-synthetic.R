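test_that("planted components have the promised block structure", {
  cfg <- synthetic_config(n_families = 500L, true_rank = 5L,
                          families_per_component = 50L,
                          ubiquitous_fraction = 0.1, overlap_fraction = 0,
                          seed = 3L)
  comp <- generate_components(cfg)
  W <- comp$true_W
  expect_true(all(W >= 0))
  expect_equal(unname(colSums(W)), rep(1, 5))
  # with no overlap and excluding ubiquitous families, each characteristic
  # family has exactly one dominant component
  char <- grepl("^component_", comp$membership$component)
  dominant <- apply(W[char, ], 1, function(r) sum(r > 10 * min(r)))
  expect_true(all(dominant == 1))
  # membership labels partition families
  expect_identical(nrow(comp$membership), 500L)
  expect_setequal(unique(comp$membership$component),
                  c(paste0("component_", 1:5), "ubiquitous", "background"))
})

test_that("overlap_fraction plants the stated number of two-component families", {
  cfg <- synthetic_config(n_families = 500L, true_rank = 5L,
                          families_per_component = 60L,
                          ubiquitous_fraction = 0.1, overlap_fraction = 0.1,
                          seed = 11L)
  comp <- generate_components(cfg)
  n_two <- sum(!is.na(comp$membership$second_component))
  expect_identical(n_two, as.integer(round(0.1 * 5 * 60)))
})

test_that("rank-1 components reduce to a single normalized column", {
  cfg <- synthetic_config(n_families = 50L, true_rank = 1L,
                          families_per_component = 20L, seed = 2L)
  comp <- generate_components(cfg)
  expect_identical(ncol(comp$true_W), 1L)
  expect_equal(sum(comp$true_W), 1)
})

test_that("site profiles are normalized and coordinates stay in range", {
  cfg <- small_config(seed = 5L)
  site <- generate_site_profiles(cfg)
  expect_true(all(site$true_H >= 0))
  expect_equal(unname(colSums(site$true_H)), rep(1, cfg$n_sites))
  expect_true(all(site$metadata$latitude >= -60 & site$metadata$latitude <= 60))
  expect_true(all(site$metadata$longitude >= -180 & site$metadata$longitude < 180))
})

test_that("environment-component coupling scales with env_link_strength", {
  # no link: correlations near zero over many sites
  cfg0 <- small_config(seed = 7L, n_sites = 1000L, env_link_strength = 0,
                       missing_rate = 0)
  site0 <- generate_site_profiles(cfg0)
  vars <- c("salinity", "temperature", "insolation")
  cors0 <- sapply(vars, function(v) {
    max(abs(cor(site0$metadata[[v]], t(site0$true_H))))
  })
  expect_lt(max(cors0), 0.1)
  # strong link: at least one variable strongly tracks a component
  cfg1 <- small_config(seed = 7L, n_sites = 200L, env_link_strength = 10,
                       missing_rate = 0)
  site1 <- generate_site_profiles(cfg1)
  cors1 <- sapply(c("salinity", "temperature"), function(v) {
    max(abs(cor(site1$metadata[[v]], t(site1$true_H))))
  })
  expect_gt(max(cors1), 0.8)
})

test_that("multinomial counts hit the configured depth and converge in law", {
  cfg <- small_config(seed = 9L)
  comp <- generate_components(cfg)
  site <- generate_site_profiles(cfg)
  counts <- sample_counts(comp$true_W, site$true_H, depth = 5000, seed = 9L)
  expect_true(all(colSums(counts) == 5000))
  expect_identical(sample_counts(comp$true_W, site$true_H, 5000, seed = 9L),
                   counts)
  # law of large numbers at high depth, single site
  big <- sample_counts(comp$true_W[, 1, drop = FALSE],
                       matrix(1, 1, 1), depth = 1e7, seed = 1L)
  p <- comp$true_W[, 1] / sum(comp$true_W[, 1])
  expect_lt(max(abs(big[, 1] / 1e7 - p)), 1e-3)
})

test_that("datasets are reproducible and round-trip through fixture files", {
  cfg <- small_config(seed = 21L, sequencing_depth = 2000)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$counts$values, ds2$counts$values)
  expect_identical(ds1$metadata, ds2$metadata)
  expect_true(all(colSums(ds1$counts$values) == 2000))

  dir <- withr::local_tempdir()
  paths <- write_dataset(ds1, dir)
  reread <- read_counts(paths[["counts"]])
  expect_equal(reread$values, ds1$counts$values, ignore_attr = "storage.mode")
  meta <- read_metadata(paths[["metadata"]])
  expect_equal(meta$latitude, ds1$metadata$latitude)
  expect_equal(meta$water_depth, ds1$metadata$water_depth)
})

test_that("a survey-scale dataset generates quickly", {
  cfg <- synthetic_config(n_families = 8214L, n_sites = 45L, true_rank = 5L,
                          families_per_component = 200L,
                          sequencing_depth = 1e5, seed = 13L)
  ds <- generate_dataset(cfg)
  expect_identical(dim(ds$counts$values), c(8214L, 45L))
  expect_true(all(colSums(ds$counts$values) == 1e5))
  expect_identical(dim(ds$true_W), c(8214L, 5L))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_families = 100, true_rank = 5,
                                families_per_component = 30),
               "exceed")
  expect_error(synthetic_config(overlap_fraction = 1), "overlap_fraction")
  expect_error(synthetic_config(sequencing_depth = 0), "depth")
  expect_error(sample_counts(matrix(0, 3, 2), matrix(1, 2, 2), 10), "all-zero")
})
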