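Package: imprintSAGE
Title: Prevalence of an Imprinted-Gene Panel in SAGE Transcriptome Catalogues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the share of the transcriptome contributed by
    a panel of established and candidate imprinted genes from Serial Analysis
    of Gene Expression (SAGE) catalogues. Provides virtual SAGE tag extraction
    from transcript sequences for the common anchoring enzymes (NlaIII, Sau3AI,
    RsaI), catalogue ingestion for plain TSV and GEO SOFT sample files,
    noninformative (A)10 removal and tags-per-million normalization, duplicate
    catalogue exclusion and library selection, per-library prevalence
    statistics (cumulative, average and maximum tpm, transcriptome share,
    single-gene dominance, detection profiles), K-means clustering of
    expression profiles with most-distant seeding under correlation distance,
    average-linkage hierarchical clustering with newick export, and a
    synthetic SAGE cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
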