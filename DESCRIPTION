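Package: phenoclust
Title: Ontology-Based Phenotype Similarity, Clustering and Gene Discovery
    for Rare-Disease Cohorts
Version: 0.1.0
Authors@R: person("BPD", "Phenomics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotates cases in a rare-disease collection with Human
    Phenotype Ontology (HPO) terms, quantifies pairwise phenotypic
    similarity from collection-relative information content (Resnik-style
    most-informative-common-ancestor similarity with symmetric best-match
    averaging), tests groups of cases for unusually close phenotypes by
    Monte-Carlo resampling, partitions a cohort with Partitioning Around
    Medoids and characterises the clusters by Fisher-exact term
    enrichment, and prioritises candidate genes by filtering rare variants
    and scoring the phenotypic similarity of variant-sharing case groups.
    Includes a synthetic-cohort simulator (ontology, annotations,
    variants) so the whole pipeline is testable without access to
    restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
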