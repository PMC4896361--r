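Package: dartmix
Title: Diversity, Population Structure, and Trait Association for Dominant
    DArT Markers
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of binary dominant marker data (band present, absent,
    or missing) from hybridization-based genotyping platforms such as
    Diversity Arrays Technology (DArT). Provides per-marker informativeness
    statistics (present frequency, polymorphic information content,
    intensity-based quality), Jaccard similarity with pairwise handling of
    missing calls, principal coordinate analysis and neighbour-joining
    trees, a Gibbs-sampled Bayesian admixture model with Evanno delta-K
    model selection and cluster divergence, AMOVA variance partitioning
    with permutation-tested Phi-st, Shannon diversity with Bowman and
    bootstrap variances, mixed-linear-model (Q plus kinship) trait-marker
    association with permutation-corrected fixed-effect scans, descriptive
    trait statistics with varimax-rotated principal components and
    trait-profile clustering, and a seeded synthetic-data generator for
    structured dominant-marker cohorts with marker-linked phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1), methods, SummarizedExperiment
Imports: S4Vectors, stats, utils, ape, Rcpp, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), vegan, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
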