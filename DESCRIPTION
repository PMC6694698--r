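Package: neovax
Title: Neoantigen Prioritization and Long Vaccine Peptide Design from
    Multi-Caller Somatic Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the in-silico core of a personalized-neoantigen
    discovery workflow for low mutational load tumors: merging of somatic
    variant calls from three callers into a non-redundant consensus set with
    majority-rule conflict resolution, phased linked-SNP attachment,
    construction of 31-mer mutant peptide contexts (with an optional
    frameshift open-reading-frame mode), enumeration of HLA class I (9-12
    mer) and class II (12-19 mer) mutation-spanning candidate peptides,
    position-weight-matrix scoring with decoy-calibrated percentile ranks,
    exclusion filters (tissue expression, wild-type identity, hypermutated
    genes, immunopeptidome representation), hotspot-overlap classification
    against a ligand database, optimal design of the shortest long peptide
    covering the maximum number of predicted binders, and a ranked report of
    the top candidates. A seeded synthetic-fixture generator produces
    self-consistent toy cohorts with planted ground truth, and a
    proteogenomics module emits a mutation-annotated custom protein database
    and flags mass-spectrometry-identified mutant peptides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Proteomics, VariantAnnotation, Sequencing, ImmunoOncology
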