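Package: gcnbench
Title: Reconstruction, Module Detection and Benchmarking of Gene
    Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gene co-expression networks (GCNs) from normalized
    expression compendia by five association methods (Pearson and Spearman
    correlation thresholding, shrinkage partial correlation with
    empirical-Bayes edge probabilities, sparse partial correlation
    estimation by joint lasso regression, and soft-threshold adjacency
    with topological overlap), detects modules by walktrap, fast-greedy
    and label-propagation community detection, summarizes network
    structure (density, modularity, path length, diameter, hubs,
    power-law degree-distribution fits), scores module gene-set
    enrichment by Fisher's exact tests with the psi-1/psi-2 summary
    statistics, and screens and ranks candidate networks against
    regulatory gold standards, including probabilistic random edge
    addition and regulon projection. A synthetic-data generator with
    known ground truth (planted co-expression modules, annotations and
    scale-free regulatory networks) makes the whole pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
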