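Package: metapep
Title: Peptide-Centric Taxonomic and Functional Annotation for
    Metaproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds non-redundant protein sequence databases from
    collections of per-strain reference proteomes, assigns each identified
    peptide the lowest common taxonomic ancestor of its protein group,
    derives consensus KEGG ortholog annotations per peptide, and produces
    intensity-weighted taxonomic and pathway-level profiles from
    peptide-level search-engine output. Ships a synthetic-data generator
    with in-silico tryptic digestion so that every stage of the workflow
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Proteomics, Metagenomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
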