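Package: bulkdiv
Title: Genetic Diversity Analysis of Bulk-Sampled Marker Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genetic diversity analysis of pooled (bulk) DNA
    samples genotyped with dominant (DArT-like), biallelic frequency
    (SNP-like) and multiallelic (SSR-like) marker systems. Implements
    Jaccard and Modified Rogers genetic distances with pairwise deletion,
    Nei gene diversity and allele summaries by passport category, UPGMA
    phenograms with cophenetic validation, principal coordinate analysis,
    model-based cluster scans over principal coordinates, distance-based
    one-way AMOVA with permutation testing, and marker-bootstrap precision
    curves. Includes a hierarchical (Balding-Nichols style) simulator of
    bulk genotyping experiments with platform-specific readout noise for
    power and recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
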