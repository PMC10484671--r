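Package: ascgeno
Title: Allele Similarity Clusters and Genotype Inference for Immune
    Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds allele similarity clusters (ASCs) from V-gene germline
    reference sets by normalized Levenshtein distance and complete-linkage
    hierarchical clustering, assigns a similarity-based two-level naming
    scheme (allele families at 75% similarity, ASCs at 95%), and infers
    personal V-gene genotypes from annotated AIRR-seq rearrangement tables
    using absolute allele-usage frequencies compared against allele-specific
    thresholds. Includes fractional counting of multi-allele assignments,
    a gene-based relative-frequency baseline for comparison, anchor-gene
    haplotype partitioning with a binomial dominance test, a threshold
    tuning procedure driven by population usage and haplotype evidence,
    and a deterministic simulator of germline sets and repertoires with
    planted genotypes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    dplyr,
    tibble,
    readr,
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
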