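# Protein-level classification (pFSM / pNIC / pNNIC): an ORF is compared to
# the reference ORFs of its gene on three structural elements — the genomic
# start codon (N-terminus), the genomic stop codon (C-terminus) and the CDS
# splice-junction chain. Termini are compared at genomic codon positions, not
# protein sequence, so UTR-only transcript variation yields pFSM while
# sequence-level deduplication is left to the database builder.

cds_junction_keys <- function(chrom, strand, blocks) {
  if (nrow(blocks) < 2L) return(character())
  sprintf("%s|%s|%d|%d", chrom, strand,
          blocks$end[-nrow(blocks)], blocks$start[-1L])
}

orf_triple <- function(chrom, strand, start_g, stop_g, blocks) {
  paste(start_g, stop_g, paste(cds_junction_keys(chrom, strand, blocks),
                               collapse = ";"), sep = "::")
}

#' Index the reference ORFs of a catalog
#'
#' Pools, per gene, the known genomic start codons, stop codons, CDS
#' junctions and full (start, stop, junction-chain) triples of every
#' reference transcript that carries a CDS.
#'
#' @param catalog Reference [gene_catalog()] with CDS blocks.
#' @return Named list (gene_id -> reference ORF sets).
#' @export
reference_orf_index <- function(catalog) {
  out <- list()
  for (tx in catalog$transcripts) {
    if (is.null(tx$cds) || !nrow(tx$cds)) next
    blocks <- tx$cds[order(tx$cds$start), , drop = FALSE]
    # genomic positions of the translation start / termination, strand-aware
    start_g <- if (tx$strand == "+") blocks$start[1L] else blocks$end[nrow(blocks)] - 1L
    stop_g <- if (tx$strand == "+") blocks$end[nrow(blocks)] - 1L else blocks$start[1L]
    g <- tx$gene_id
    ge <- out[[g]]
    if (is.null(ge))
      ge <- list(starts = integer(), stops = integer(), junctions = character(),
                 triples = character())
    ge$starts <- union(ge$starts, start_g)
    ge$stops <- union(ge$stops, stop_g)
    ge$junctions <- union(ge$junctions,
                          cds_junction_keys(tx$chrom, tx$strand, blocks))
    tr <- orf_triple(tx$chrom, tx$strand, start_g, stop_g, blocks)
    if (!tr %in% names(ge$triples)) ge$triples[tr] <- tx$transcript_id
    out[[g]] <- ge
  }
  out
}

#' Classify one ORF against its gene's reference ORFs
#'
#' pFSM: the (start, stop, CDS junction chain) triple equals a reference
#' ORF's triple. pNIC: start, stop and every junction are individually known
#' for the gene but the combination is unseen. pNNIC: at least one element is
#' novel (`novel_elements` lists which). An empty reference ORF set yields
#' pNNIC with all elements novel.
#'
#' @param orf A projected `open_reading_frame`.
#' @param tx Its [transcript_model()].
#' @param gene_ref One element of [reference_orf_index()], or NULL.
#' @return list of class `protein_call`: transcript_id, category,
#'   novel_elements, matched_reference_orf.
#' @export
classify_protein <- function(orf, tx, gene_ref) {
  blocks <- orf$cds_blocks
  start_g <- orf$start_codon_genomic
  stop_g <- orf$stop_codon_genomic
  jx <- cds_junction_keys(tx$chrom, tx$strand, blocks)
  if (is.null(gene_ref) || !length(gene_ref$triples)) {
    return(structure(list(transcript_id = orf$transcript_id, category = "pNNIC",
                          novel_elements = c("n_terminus", "c_terminus", "junction"),
                          matched_reference_orf = NA_character_),
                     class = "protein_call"))
  }
  tr <- orf_triple(tx$chrom, tx$strand, start_g, stop_g, blocks)
  if (tr %in% names(gene_ref$triples)) {
    return(structure(list(transcript_id = orf$transcript_id, category = "pFSM",
                          novel_elements = character(),
                          matched_reference_orf = unname(gene_ref$triples[tr])),
                     class = "protein_call"))
  }
  novel <- character()
  if (!start_g %in% gene_ref$starts) novel <- c(novel, "n_terminus")
  if (!stop_g %in% gene_ref$stops) novel <- c(novel, "c_terminus")
  if (!all(jx %in% gene_ref$junctions)) novel <- c(novel, "junction")
  structure(list(transcript_id = orf$transcript_id,
                 category = if (length(novel)) "pNNIC" else "pNIC",
                 novel_elements = novel,
                 matched_reference_orf = NA_character_),
            class = "protein_call")
}

#' Classify all retained ORFs of a query catalog
#'
#' @param orfs Named list of projected ORFs (any status; all are classified).
#' @param query_catalog The query [gene_catalog()].
#' @param ref_index A [reference_orf_index()].
#' @param gene_assignment Named character vector transcript_id -> gene_id
#'   (e.g. from [classify_catalog()]); transcripts without an entry fall back
#'   to their own gene_id.
#' @return data.table: transcript_id, protein_category, novel_elements
#'   (comma-joined), matched_reference_orf.
#' @export
classify_proteins <- function(orfs, query_catalog, ref_index,
                              gene_assignment = NULL) {
  rows <- lapply(orfs, function(orf) {
    tx <- query_catalog$transcripts[[orf$transcript_id]]
    g <- if (!is.null(gene_assignment) && orf$transcript_id %in% names(gene_assignment))
      gene_assignment[[orf$transcript_id]] else tx$gene_id
    cl <- classify_protein(orf, tx, ref_index[[g]])
    data.table::data.table(
      transcript_id = cl$transcript_id, gene_id = g,
      protein_category = cl$category,
      novel_elements = paste(cl$novel_elements, collapse = ","),
      matched_reference_orf = cl$matched_reference_orf)
  })
  data.table::rbindlist(rows)
}
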