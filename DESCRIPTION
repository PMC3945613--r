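Package: nalcnscreen
Title: Candidate Accessory-Subunit Screening for the NALCN Sodium Leak Channel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A validation pipeline for linking candidate accessory-subunit
    genes to the NALCN sodium leak channel in Drosophila. Provides four
    analysis stages: a co-expression screen ranking candidate genes by
    Pearson correlation with a reference gene across tissue and
    developmental RPKM profiles; per-column conservation profiling of
    protein multiple sequence alignments with majority-gap stripping,
    cysteine-motif tracking through gapped coordinates, and a permutation
    test for regional conservation; diurnal locomotor activity analysis of
    beam-crossing counts (Trikinetics-style monitor files) with
    repeated-measures ANOVA per-bin comparisons; and social-space analysis
    computing nearest-neighbor distance distributions and the Social Space
    Index (SSI) with Dunnett many-to-one genotype comparisons. Includes
    synthetic-data generators emulating each input modality (clustered
    arena positions, rhythmic Poisson activity counts, co-regulated RPKM
    profiles, gapped alignments with conserved motifs) so the full pipeline
    is testable without external data, and from-scratch implementations of
    one-way and mixed two-way repeated-measures ANOVA and Dunnett's test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
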