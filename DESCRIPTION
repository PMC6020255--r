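Package: promote
Title: Counting Non-Overlapping Motif Embeddings in Probabilistic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts the maximum-expected number of non-overlapping (independent)
    embeddings of a small motif in an undirected network whose edges exist with
    independent probabilities. The distribution of the number of embeddings that
    overlap a focal embedding is computed exactly through a generating-polynomial
    model with per-variable collapse operators, and three scaling strategies are
    provided: priority-bound early termination, greedy collapse-ordering of the
    edge polynomials, and a memory-bounded deferred-term polynomial product.
    Includes random-network generators (Erdos-Renyi, Watts-Strogatz,
    Barabasi-Albert) with uniform edge probabilities, literature baselines
    (binary, threshold, sampling transforms with a least-overlap greedy counter),
    and brute-force oracles for validation on small inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
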