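Package: riboscan
Title: SSU rRNA Variable-Region Tag Extraction from Shotgun Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects small-subunit (16S/18S) rRNA hypervariable-region
    boundaries directly in raw shotgun metagenome or metatranscriptome
    reads using short conserved recognition profiles (degenerate probe
    patterns combined with position-specific scoring matrices), extracts
    the adjacent hypervariable tag sequences under per-base quality
    filtering, quantifies tags per sample with an explicit model of the
    tag counts expected from single-base sequencing error, annotates tags
    taxonomically by majority vote over a reference collection, and emits
    standard community-profile outputs including BIOM. Includes a
    synthetic-community generator for end-to-end validation without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    biomformat
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'profiles.R'
    'scan.R'
    'errormodel.R'
    'tagcount.R'
    'annotate.R'
    'io.R'
    'synthetic.R'
    'evaluate.R'
    'pipeline.R'
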