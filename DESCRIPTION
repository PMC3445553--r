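Package: nmfbiogeo
Title: Functional Biogeography of Microbial Communities via Non-Negative
    Matrix Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes protein-family-by-site relative-abundance matrices
    from metagenomic surveys into a small number of non-negative components
    by Kullback-Leibler non-negative matrix factorization, selects the
    factorization rank by a concordance (stability) criterion over random
    restarts, builds NMF-filtered similarity matrices for families and
    sites with spectral reordering, associates protein families with
    components by correlation, cosine similarity and specificity, and
    tests whether functional distance between sites tracks environmental
    rather than geographic distance using Mantel and partial Mantel
    permutation tests. Includes a synthetic-data generator with planted
    low-rank structure so that rank selection, association and the
    environment-versus-geography contrast can be validated against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
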