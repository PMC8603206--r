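Package: proteovar
Title: Proteogenomic Variant Databases, Peptide Evidence and Signaling Network Drug Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for sample-specific proteogenomics: builds reference and
    alternate (variant-injected) protein sequence databases from a genome,
    transcript annotation and VCF calls; annotates amino acid variants for
    phosphorylation and cancer impact with a summed/scaled per-residue score;
    classifies mass-spectrometry peptide evidence against reference and
    alternate isoforms after in-silico tryptic digestion, including
    phospho-on-variant flagging; reconstructs filtered undirected
    protein-protein interaction networks and prioritizes drugs by target
    specificity and network degree; and provides the quantitative statistics
    stages (phosphosite normalization, s0-moderated t-test with
    permutation-based FDR, Fisher exact overrepresentation, SILAC twofold
    filtering). Seeded synthetic-data generators make the whole pipeline
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
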