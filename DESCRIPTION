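Package: rsaid
Title: Personalized-Model Representational Similarity Analysis and
    Identity Decoding for Imagined-Scenario fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds person-specific models of imagined everyday scenarios
    from verbal descriptions (additive word-embedding composition) and
    Likert attribute ratings, compares them with fMRI activation patterns
    in representational similarity space (Spearman RSA, leave-one-out
    group-average controls, Spearman partial RSA with a residual-shuffle
    permutation test), selects stable voxels per region of interest,
    maps effects with a cubic searchlight, and decodes participant
    identity from all pairwise congruent-versus-incongruent model-to-brain
    matches.  Ships a synthetic-cohort generator with tunable
    person-specific signal strength so every stage runs with no external
    data, plus readers and writers for the standard on-disk formats
    (4D NIfTI runs, motion-parameter tables, ratings TSV, description
    text, word-embedding text).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
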