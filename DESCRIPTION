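Package: profsearch
Title: Target-Enhanced 2D Fingerprint Similarity Searching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ligand-based virtual screening with target-enhanced 2D
    similarity searches. Implements conventional Tanimoto similarity search
    (CSS) and five enhancements that exploit the labeled actives and
    inactives of an activity class: average-profile search (PBSS), iterative
    MAX-fusion search over active references (ISS), iterative search with
    neighbor classification against inactive references (ISC), and their
    profile-based variants (PBISS, PBISC) built on Taylor-Butina
    exclusion-sphere clustering of the reference neighborhood. Includes the
    bioactivity end-point curation and query/reference/test splitting
    protocol, a synthetic activity-class generator with scaffold families
    and activity-cliff decoys, and a recall/precision/ROC-AUC/enrichment
    benchmarking harness with paired engine comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    ChemmineR,
    ChemmineOB,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
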