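Package: cycloPan
Title: Biopanning NGS Analytics and Kinetic Triage for Macrocyclic Peptide Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-round phage-display biopanning campaigns
    of genetically encoded macrocyclic peptide libraries. Provides degenerate-codon
    library schemas with amber-suppression decoding to non-canonical residues,
    a generative simulator of capture/wash/elution/amplification selection rounds
    with planted ground-truth binders and resin-specific parasitic clones, FASTQ
    demultiplexing and variable-region extraction into peptide count tables,
    round-over-round enrichment, diversity and cross-strategy overlap analytics
    with consensus hit ranking, physicochemical peptide descriptors with UMAP
    embedding and density clustering, and global 1:1 biolayer-interferometry
    kinetic fitting with alanine-scan fold-change classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    uwot,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cycloPan-package.R'
    'pool-table.R'
    'enrichment.R'
    'genetic-code.R'
    'features.R'
    'kinetics.R'
    'schema.R'
    'ngs-ingest.R'
    'selection-sim.R'
    'pipeline.R'
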