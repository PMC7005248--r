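Package: asmrec
Title: Assembly Reconciliation via Adjacency Algebra and Contig Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges two or more draft genome assemblies of the same organism into a
    single, more contiguous consensus assembly. Input assemblies are ranked with a
    mapping-quality/coverage score computed from read alignments, contigs are
    classified as Uncertain or True using fragment-coverage, mate-pair and
    GC-content evidence, and high-similarity consensus blocks between assemblies
    are fused through an adjacency algebraic graph model with classification-driven
    resolution of repeat-induced misjoins. Includes a self-contained synthetic-data
    generator (genomes with planted repeats and misjoins, paired reads with
    quality strings, and truth tables) used for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
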