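Package: netdms
Title: Network-Assisted Dense Module Search for GWAS Gene-Set Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Combines SNP-level genome-wide association statistics into
    gene-wise P-values (simulation-based combination over all mapped SNPs
    or the top fraction, accounting for linkage disequilibrium, plus the
    classical minimum-P strategy), overlays the resulting z-score weights
    on a protein-protein interaction network, and extracts disjoint dense
    modules by a restricted greedy search seeded at the highest-weight
    nodes. Module scores are standardized against an empirically fitted
    normal null; module gene sets are evaluated by SNP-resampling
    (ALIGATOR-style) with Benjamini-Hochberg correction and by
    hypergeometric pathway enrichment with Bonferroni correction. A
    synthetic-data generator (LD-block genotypes, null and spiked
    association statistics, scale-free interaction networks with planted
    modules, random pathway collections) makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
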