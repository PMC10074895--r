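Package: triadbias
Title: Homoeolog Expression Bias in Allopolyploid Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify asymmetric (biased) expression among the A/B/D
    homoeolog triads of allohexaploid wheat at bulk and single-cell resolution.
    Each expressed triad is projected onto the 2-simplex by normalizing the
    three homoeolog expression values to sum to one, then assigned to one of
    seven bias categories (Balance, A/B/D dominant, A/B/D suppressed) by
    nearest-centroid Euclidean classification. Includes pseudobulk aggregation
    of cell clusters, bulk-versus-cluster bias breakdowns, bias dynamics along
    pseudotime trajectories, a Shannon-entropy expression-specificity index,
    cross-species cluster correlation via orthologs, and a synthetic
    allopolyploid single-cell count generator with planted per-cluster bias
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
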