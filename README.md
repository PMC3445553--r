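# nmfbiogeo

Functional biogeography of microbial communities via non-negative matrix
factorization.

## The problem

Shotgun metagenomic surveys of the ocean summarize each sampling site as a
vector of protein-family abundances — thousands of Pfam counts per sample.
Two questions follow immediately. First, can the thousands of families be
compressed into a handful of interpretable *functional components*, each
with its own geographic footprint? Second, once sites are described in
component space, does the functional distance between sites track their
environmental differences (temperature, salinity, chlorophyll, ...) or
their geographic separation?

`nmfbiogeo` implements an end-to-end framework for both questions, aimed at
microbial ecologists working with family-by-site count tables:

* **Decomposition.** The column-normalized profile matrix `X` (families x
  sites, column sums 1) is factorized as `X ≈ WH` with `W, H ≥ 0`,
  minimizing the generalized Kullback–Leibler divergence
  `D(X‖WH) = Σ x log(x/ŷ) − x + ŷ` by Lee–Seung multiplicative updates.
  Columns of `W` are functional profiles; rows of `H` are site profiles.
* **Rank selection.** The rank `k` is chosen by a concordance index
  `C = 1 − d`, where `d` is the mean squared difference between
  off-diagonal entries of the site-similarity matrix `S = Hnᵀ Hn` across
  random restarts: stable decompositions score near 1.
* **Structure.** NMF-filtered cosine similarity matrices for families,
  sites and components, exposed by spectral reordering (Fiedler vector of
  the graph Laplacian after a Gaussian affinity transform, with the kernel
  scale chosen by a 2-sum criterion on the untransformed matrix).
* **Association.** Families ranked against components by Pearson
  correlation of site profiles (default), cosine similarity, or
  specificity; top-`k` selections and an entropy-based ubiquity score.
* **Distances & tests.** NMF-filtered, unfiltered and PCA-filtered
  functional distances; environmental distance (z-scored variables, √water
  depth, mean imputation); great-circle geographic distance with log₁₀
  transform; Mantel and partial Mantel permutation tests (999 permutations)
  and a naive distance regression summarized by adjusted R².
* **Synthetic ground truth.** A generator that plants component-specific
  family blocks, a ubiquitous block, Dirichlet site mixtures, multinomial
  count noise at configurable sequencing depth, and environmental variables
  coupled to component weights while coordinates stay independent — so
  every stage can be validated against known truth.

## Worked example

```r
library(nmfbiogeo)

# simulate a survey with 4 planted components over 45 sites
cfg <- synthetic_config(seed = 1)   # 500 families, depth 1e5, env-linked
res <- run_nmf_biogeography(synthetic = cfg, rank_range = 2:8,
                            n_runs = 20, max_iter = 300, tol = 1e-5,
                            seed = 1)
#> stage rank: selected rank 4
#> stage mantel: r_env 0.658 (p 0.001), r_geo 0.015 (p 0.286); partial 0.658 vs 0.012
#> stage regression: adjusted R^2 filtered 0.432, unfiltered 0.428, PCA 0.427

tidy(res$rank_selection)
#> # A tibble: 7 × 3
#>    rank concordance selected
#>   <int>       <dbl> <lgl>
#> 1     2       0.900 FALSE
#> 2     3       0.932 FALSE
#> 3     4       1.00  TRUE
#> 4     5       0.993 FALSE
#> ...
```

The concordance curve peaks at the planted rank 4. The Mantel line is the
headline biology: the partial correlation between NMF-filtered functional
distance and environmental distance, controlling for geography (0.658), is
far higher than the partial correlation with geographic distance
controlling for environment (0.012) — microbial community function follows
the environment, not the map. `autoplot(res$rank_selection)`,
`autoplot(res$similarities$site, res$orderings$site)` and
`autoplot(res$tests$partial_env_given_geo)` draw the standard figures;
`tidy()`/`glance()` methods return tibbles for every fitted object.

With real data, replace the synthetic block by file paths:

```r
res <- run_nmf_biogeography(counts = "counts.tsv", metadata = "metadata.tsv",
                            min_total = 1000, seed = 1, out_dir = "results/")
```

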