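Package: schemarep
Title: Story- and Schema-Level Neural Representation Analysis for Naturalistic Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying story-specific and schematic neural
    representations during encoding and free recall of naturalistic
    narratives, and for relating them to behavioral memory. Implements
    event-wise GLM pattern extraction with a canonical double-gamma HRF,
    leave-one-subject-out intersubject pattern similarity, an ordered-state
    hidden Markov model measure of sequence reinstatement, story and schema
    contrast scores with permutation nulls, leave-one-subject-out
    brain-to-behavior regression, surface searchlight mapping with FDR
    control, k-means subclustering with silhouette selection, and
    bias-corrected bootstrap mediation. A synthetic multi-subject study
    generator plants known story, schema, modality and brain-behavior
    structure so that every stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
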