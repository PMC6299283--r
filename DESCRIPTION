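Package: phylostrip
Title: Fast-Site Removal Phylogenomics, Ortholog Profile Ordination and
    Transcriptome Decontamination Rules
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for slow-fast (progressive fast-site removal) phylogenomic
    support analysis: ranking alignment columns by among-site evolutionary
    rate, emitting nested stripped supermatrices, measuring bipartition
    (clade) support across bootstrap tree samples and assembling
    support-versus-removal curves.  Also implements binary ortholog
    presence/absence profiling with Pearson similarity, 1 - r dissimilarity,
    principal coordinate analysis with a broken-stick criterion and Ward
    hierarchical clustering; Markov clustering (MCL) of protein similarity
    graphs; and deterministic rule engines for taxonomic decontamination of
    transcriptome assemblies (bestsum taxon assignment, cellular-origin and
    host screens, identity-based exclusion, deduplication) plus KEGG-ortholog
    identifier transfer and thresholded presence/absence calling.  Seeded
    synthetic-data generators produce every input with known ground truth so
    the whole pipeline is testable end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn
Config/testthat/edition: 3
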