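Package: diazokit
Title: Verification of Nitrogen-Fixing Bacterial Isolates by 15N Metabolomics and Genome Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for confirming diazotrophic (nitrogen-fixing)
    bacterial isolates and characterizing their genomes. Implements the
    15N2 stable-isotope-probing biomarker assay: alignment of per-sample
    mass-spectral peak lists into a feature matrix, per-feature Welch
    t-tests with Benjamini-Hochberg false-discovery-rate control,
    fold-change filtering, and a per-isolate biological-nitrogen-fixation
    (BNF) ratio of summed relative biomarker intensities under
    15N2-enriched versus control atmospheres, with categorical group
    assignment. Companion genome-mining tools parse HMMER3 domtblout
    output, filter hits on model coverage and e-value, build per-genome
    nif-gene and carbohydrate-utilization profiles, classify genomes
    against the Dos Santos minimal nif gene model and by alternative
    nitrogenase content, compute MinHash (k = 31) genome sketches with
    all-by-all Jaccard similarity, and categorize pangenome genes into
    core, soft-core, shell and cloud classes. A synthetic-data generator
    produces ground-truthed inputs (isotopologue peak lists, planted
    domtblout fixtures, mutated genome sets, presence/absence matrices)
    so every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    Biostrings,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
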