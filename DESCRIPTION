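Package: lrproteo
Title: Long-Read Proteogenomics: Isoform Classification, ORF Inference and
    Novel Peptide Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for long-read transcriptome proteogenomics.
    Classifies long-read transcript models against a reference annotation into
    full splice match (FSM), novel in catalog (NIC) and novel not in catalog
    (NNIC) categories with novel-element subcategories; calls open reading
    frames on novel transcripts, projects coding regions to the genome and
    filters predicted nonsense-mediated-decay targets; classifies the encoded
    proteins (pFSM/pNIC/pNNIC); builds a hybrid target-decoy protein search
    database with multi-enzyme in-silico digestion and a peptide uniqueness
    index; detects and validates novel peptides against theoretical b/y
    fragment ions; quantifies isoforms (TPM, per-gene relative abundance,
    novel-dominant genes) with the accompanying statistical tests; and applies
    rule-based prioritization to annotated variant tables. A seeded
    synthetic-data generator produces toy genomes, catalogs, planted novel
    isoforms, expression counts and peptide-spectrum matches with ground truth
    so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
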