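Package: famvar
Title: Variant Enrichment at Equivalent Protein-Family Alignment Positions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study nonsynonymous variant enrichment at equivalent
    positions of protein-family alignments in diploid cohorts, with a focus
    on G-protein coupled receptors and the olfactory-receptor DRY motif.
    Provides a synthetic-data generator for cohorts, family alignments,
    diploid variant tables, coding sequences and receptor/odorant screens
    with planted structure; mapping of protein changes onto alignment
    columns with consensus and conservation calls; per-column enrichment
    statistics (observed/expected counts, log-odds, shuffle-prior binomial
    tests, Benjamini-Hochberg correction); EC50-weighted receptor activity
    statistics and loss-of-function anosmia scoring; binary genotype
    fingerprint clustering with Newick export; and an agent-based simulation
    of odorant-driven movement, mating and mutation on a grid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, VariantAnnotation, Clustering, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'abm.R'
    'mapping.R'
    'descriptive.R'
    'enrichment.R'
    'fingerprints.R'
    'io.R'
    'pharmacology.R'
    'pipeline.R'
    'synthetic-data.R'
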