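Package: zotudb
Title: Fungal ITS Metabarcoding Curation, Denoising and Biogeography Toolkit
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for building and querying a deduplicated
    reference database of fungal zero-radius OTUs (ZOTUs) from public amplicon
    sequencing archives. Mines sequence-archive accession identifiers (SRA,
    ENA, BioProject namespaces) from publication text; standardizes
    heterogeneous sample metadata into comparable annotations (ISO dates,
    decimal coordinates with country-centroid fallback and bounding-box
    correction, continent assignment, ENVO biome terms) while preserving raw
    values as provenance; processes raw ITS amplicon FASTQ reads into denoised
    ZOTUs via primer trimming, paired-end merging, expected-error filtering,
    UNOISE3-style denoising and a 70 percent-identity fungal taxonomy filter;
    maintains an incremental deduplicated ZOTU store with per-sample
    'contains' provenance; and answers biogeographic diversity queries
    (phylum-by-continent counts, shared ZOTUs among continents, taxon
    distributions within latitude bands). Includes deterministic synthetic
    data generators so the whole framework is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
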