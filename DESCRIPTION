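Package: gliaPHP
Title: Integrating Abeta-Associated Histone Acetylation, Cell-Type
    Transcriptomics and Presynaptic Homeostatic Potentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative analysis pipeline linking amyloid-beta-associated
    H3K9ac ChIP-seq dysregulation to cell-type-specific transcriptomic change
    in Alzheimer's disease, quantifying directional concordance between
    per-peak amyloid regression coefficients and single-nucleus log2 fold
    changes (exact two-sided binomial sign tests, Pearson/Spearman
    correlation), bootstrapping cell-type expression enrichment of synaptic
    gene sets across species (human to Drosophila perineurial glia), and
    analysing quantal electrophysiology of presynaptic homeostatic
    potentiation (quantal content, percent-of-baseline metrics, per-genotype
    PHP calls). A synthetic-data generator with controllable ground truth
    stands in for the deposited patient and fly datasets so that every stage
    is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
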