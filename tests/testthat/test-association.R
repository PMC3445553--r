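make_fit <- function(W, H) {
  if (is.null(rownames(W))) rownames(W) <- paste0("F", seq_len(nrow(W)))
  colnames(W) <- paste0("component_", seq_len(ncol(W)))
  rownames(H) <- colnames(W)
  if (is.null(colnames(H))) colnames(H) <- paste0("S", seq_len(ncol(H)))
  structure(list(W = W, H = H, rank = ncol(W)), class = "nmf_fit")
}

test_that("correlation scores match an independent Pearson oracle", {
  set.seed(51)
  X <- matrix(runif(200), 20, 10,
              dimnames = list(paste0("F", 1:20), paste0("S", 1:10)))
  H <- matrix(runif(30), 3, 10)
  fit <- make_fit(matrix(runif(60), 20, 3), H)
  colnames(X) <- colnames(fit$H)
  tab <- associate_families(X, fit, method = "correlation")
  for (i in sample.int(20, 5)) {
    for (cc in 1:3) {
      want <- cor(X[i, ], H[cc, ])
      got <- tab$score[tab$family_id == paste0("F", i) &
                         tab$component == paste0("component_", cc)]
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  # a family equal to an affine shift of a component profile scores 1
  X[1, ] <- 0.2 + 3 * H[2, ]
  tab2 <- associate_families(X, fit, method = "correlation")
  expect_equal(tab2$score[tab2$family_id == "F1" &
                            tab2$component == "component_2"], 1,
               tolerance = 1e-12)
})

test_that("constant rows get a flagged zero correlation", {
  X <- matrix(runif(40), 4, 10, dimnames = list(paste0("F", 1:4), NULL))
  X[2, ] <- 0.5
  fit <- make_fit(matrix(runif(8), 4, 2), matrix(runif(20), 2, 10))
  colnames(X) <- colnames(fit$H)
  tab <- associate_families(X, fit, method = "correlation")
  f2 <- tab[tab$family_id == "F2", ]
  expect_true(all(f2$score == 0))
  expect_true(all(f2$flag == "degenerate"))
  expect_true(all(is.na(tab$flag[tab$family_id != "F2"])))
})

test_that("random families have correlations centred on zero", {
  set.seed(52)
  H <- matrix(runif(2 * 45), 2, 45)
  X <- matrix(runif(1000 * 45), 1000, 45,
              dimnames = list(paste0("F", 1:1000), NULL))
  fit <- make_fit(matrix(runif(2000), 1000, 2), H)
  colnames(X) <- colnames(fit$H)
  tab <- associate_families(X, fit, method = "correlation")
  expect_lt(abs(mean(tab$score)), 0.05)
})

test_that("similarity scores are cosines with the documented edge cases", {
  H <- rbind(c(1, 0, 0, 0), c(0, 0, 1, 1))
  W <- matrix(runif(8), 4, 2)
  fit <- make_fit(W, H)
  X <- rbind(3 * H[1, ], c(0, 1, 0, 0), runif(4), H[2, ])
  rownames(X) <- paste0("F", 1:4)
  colnames(X) <- colnames(fit$H)
  tab <- associate_families(X, fit, method = "similarity")
  score <- function(f, cc) tab$score[tab$family_id == f & tab$component == cc]
  expect_equal(score("F1", "component_1"), 1, tolerance = 1e-12)  # proportional
  expect_equal(score("F2", "component_1"), 0)                     # disjoint
  a <- X[3, ]; b <- H[2, ]
  expect_equal(score("F3", "component_2"),
               sum(a * b) / sqrt(sum(a^2) * sum(b^2)), tolerance = 1e-12)
})

test_that("specificity rows are simplex vectors with the trivial cases", {
  W <- rbind(c(1, 0, 0, 0, 0), rep(0.3, 5), c(0.2, 0.2, 0.1, 0, 0))
  fit <- make_fit(W, matrix(runif(10), 5, 2))
  tab <- associate_families(fit = fit, method = "specificity")
  wide <- tidyr::pivot_wider(tab[, c("family_id", "component", "score")],
                             names_from = "component", values_from = "score")
  scores <- as.matrix(wide[, -1])
  expect_equal(unname(rowSums(scores)), rep(1, 3), tolerance = 1e-12)
  expect_equal(tab$score[tab$family_id == "F1" & tab$component == "component_1"], 1)
  expect_equal(tab$score[tab$family_id == "F2"], rep(0.2, 5),
               tolerance = 1e-12)
})

test_that("top-k selection is ordered, deterministic, and bounded", {
  tab <- tibble::tibble(
    family_id = c("b", "a", "c", "d", "e"),
    component = "component_1",
    method = "correlation",
    score = c(0.9, 0.9, 0.2, -0.1, 0.8),
    flag = NA_character_)
  class(tab) <- c("association_table", class(tab))
  top <- select_top(tab, "component_1", k = 3)
  expect_identical(top$family_id, c("a", "b", "e"))  # lexical tie-break
  expect_identical(select_top(tab, "component_1", k = 1)$family_id, "a")
  expect_identical(count_above(tab, "component_1", 0.8), 3L)
  expect_identical(count_above(tab, "component_1", -1), 5L)
  expect_identical(count_above(tab, "component_1", 1.01), 0L)
  expect_error(select_top(tab, "component_1", k = 0), "positive")
  expect_error(select_top(tab, "component_1", k = 9), "exceeds")
  expect_error(select_top(tab, "component_9", k = 1), "not present")
})

test_that("ubiquity separates even loadings from specific ones", {
  W <- rbind(rep(0.2, 5), c(1, 0, 0, 0, 0), c(0.5, 0.5, 0, 0, 0), rep(0, 5))
  rownames(W) <- paste0("F", 1:4)
  fit <- make_fit(W, matrix(runif(25), 5, 5))
  ub <- ubiquity_score(fit)
  get <- function(f) ub$ubiquity[ub$family_id == f]
  expect_equal(get("F1"), 1)
  expect_equal(get("F2"), 0)
  expect_equal(get("F3"), log(2) / log(5), tolerance = 1e-12)
  expect_true(is.na(get("F4")))
  expect_identical(ub$flag[ub$family_id == "F4"], "zero_loading")
})

test_that("planted ubiquitous families rank above characteristic ones", {
  cfg <- small_config(seed = 61L, ubiquitous_fraction = 0.15)
  comp <- generate_components(cfg)
  fit <- make_fit(comp$true_W, matrix(runif(4 * 10), 4, 10))
  rownames(fit$W) <- comp$membership$family_id
  ub <- ubiquity_score(fit)
  merged <- merge(ub, comp$membership, by = "family_id")
  is_ub <- merged$component == "ubiquitous"
  is_char <- grepl("^component_", merged$component)
  # AUC via the Wilcoxon statistic: ubiquitous vs characteristic families
  n1 <- sum(is_ub)
  n2 <- sum(is_char)
  w <- sum(rank(c(merged$ubiquity[is_ub], merged$ubiquity[is_char]))[seq_len(n1)]) -
    n1 * (n1 + 1) / 2
  auc <- w / (n1 * n2)
  expect_gte(auc, 0.95)
})

test_that("all methods agree on the dominant component for planted families", {
  nl <- noiseless_profile(small_config(seed = 62L, ubiquitous_fraction = 0,
                                       overlap_fraction = 0))
  fit <- nmf_kl(nl$x, rank = 4, seed = 1, max_iter = 3000, tol = 1e-9)
  m <- match_components(nl$true_W, fit$W)
  char <- grepl("^component_", nl$membership$component)
  planted <- match(nl$membership$component[char],
                   paste0("component_", seq_len(4)))
  tabs <- list(
    corr = associate_families(nl$x, fit, "correlation"),
    sim = associate_families(nl$x, fit, "similarity"),
    spec = associate_families(fit = fit, method = "specificity"))
  for (tab in tabs) {
    wide <- tidyr::pivot_wider(tab[, c("family_id", "component", "score")],
                               names_from = "component", values_from = "score")
    scores <- as.matrix(wide[, -1])[char, m$perm]
    expect_gte(mean(apply(scores, 1, which.max) == planted), 0.98)
  }
})
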