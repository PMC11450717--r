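# End-to-end driver: runs the synthetic study through every pipeline stage
# and computes the recovery/precision summaries the analysis scripts and the
# acceptance checks report.

#' Run the full synthetic proteogenomic study
#'
#' Simulates the reference and planted novel isoforms, classifies the
#' queries, calls and filters ORFs, classifies proteins, builds the hybrid
#' target-decoy database and peptide index, simulates PSMs with spectra,
#' detects novel peptides, and quantifies isoform abundance. All stages are
#' seeded from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return list with all intermediate objects plus `metrics` (named list of
#'   summary numbers).
#' @export
run_synthetic_study <- function(config = sim_config()) {
  ref <- simulate_reference(config)
  planted <- plant_novel_isoforms(ref, config)
  index <- build_reference_index(ref$catalog)
  calls <- classify_catalog(planted$catalog, index)

  orf_res <- call_orfs(planted$catalog, ref$genome, min_aa = config$min_aa)
  retained <- Filter(function(o) o$status == "retained", orf_res$orfs)

  ref_orf_idx <- reference_orf_index(ref$catalog)
  assignment <- stats::setNames(calls$assigned_gene, calls$transcript_id)
  pcalls <- classify_proteins(orf_res$orfs, planted$catalog, ref_orf_idx,
                              gene_assignment = assignment)

  db <- build_hybrid_db(retained, ref$proteins)
  dbd <- add_decoys(db)
  pep_index <- build_peptide_index(dbd)

  sim_ms <- simulate_psms(dbd, pep_index, config)
  report <- detect_novel_peptides(sim_ms$psms, pep_index, db, calls = calls,
                                  spectra = sim_ms$spectra)

  # expression over reference + novel transcripts
  tx_gene <- data.table::data.table(
    transcript_id = c(names(ref$catalog$transcripts),
                      names(planted$catalog$transcripts)),
    gene_id = c(vapply(ref$catalog$transcripts, `[[`, "", "gene_id"),
                calls$assigned_gene[match(names(planted$catalog$transcripts),
                                          calls$transcript_id)]))
  novel_orf_ids <- pcalls[protein_category != "pFSM" &
                            transcript_id %in% names(retained), transcript_id]
  dominant <- utils::head(novel_orf_ids, config$n_dominant_novel)
  counts <- simulate_expression(tx_gene, config, dominant = dominant)
  expr <- compute_tpm(counts)
  abundance <- isoform_abundance(expr, stats::setNames(tx_gene$gene_id,
                                                       tx_gene$transcript_id),
                                 novel_orf_ids = novel_orf_ids)
  dominant_flags <- flag_novel_dominant(abundance, ref$catalog)

  metrics <- study_metrics(planted, calls, sim_ms, report, dominant,
                           dominant_flags, abundance)

  list(config = config, reference = ref, planted = planted, index = index,
       calls = calls, orfs = orf_res, retained = retained,
       protein_calls = pcalls, db = db, db_with_decoys = dbd,
       peptide_index = pep_index, psms = sim_ms, novel_report = report,
       counts = counts, expression = expr, abundance = abundance,
       dominant = dominant, dominant_flags = dominant_flags,
       metrics = metrics)
}

study_metrics <- function(planted, calls, sim_ms, report, dominant,
                          dominant_flags, abundance) {
  merged <- merge(planted$truth, calls, by = "transcript_id")
  cat_acc <- mean(merged$category == merged$true_category)
  sub_rec <- mean(merged$subcategories == merged$true_subcategories)
  gene_acc <- mean(merged$assigned_gene == merged$source_gene)

  truth_novel <- unique(sim_ms$truth[is_unique_novel == TRUE, peptide])
  reported <- if (nrow(report) && "uniqueness" %in% names(report))
    report[uniqueness == "unique_novel" & included == TRUE, peptide]
  else character()
  tp <- length(intersect(reported, truth_novel))
  precision <- if (length(reported)) tp / length(reported) else NA_real_
  recall <- if (length(truth_novel)) tp / length(truth_novel) else NA_real_

  flagged <- dominant_flags$flagged$gene_id
  planted_dom_genes <- unique(abundance$gene_id[abundance$transcript_id %in%
                                                  dominant])
  dom_rec <- if (length(planted_dom_genes))
    mean(planted_dom_genes %in% flagged) else NA_real_
  list(n_planted = nrow(merged), category_accuracy = cat_acc,
       subcategory_recovery = sub_rec, gene_assignment_accuracy = gene_acc,
       n_true_novel_peptides = length(truth_novel),
       n_reported_novel_peptides = length(reported),
       novel_peptide_precision = precision, novel_peptide_recall = recall,
       n_dominant_planted = length(dominant),
       n_dominant_flagged = length(flagged),
       dominant_recovery = dom_rec)
}

#' Self-classification of a reference catalog
#'
#' Classifies every transcript of a catalog against itself and summarizes
#' how many multi-exon transcripts come back FSM matched to themselves.
#'
#' @param catalog A [gene_catalog()].
#' @return list: calls (data.table), n_multi_exon, fsm_fraction,
#'   self_match_fraction.
#' @export
self_classification <- function(catalog) {
  index <- build_reference_index(catalog)
  calls <- classify_catalog(catalog, index)
  multi <- vapply(catalog$transcripts, function(tx) nrow(tx$exons) > 1L,
                  logical(1))
  sub <- calls[transcript_id %in% names(multi)[multi]]
  list(calls = calls, n_multi_exon = nrow(sub),
       fsm_fraction = mean(sub$category == "FSM"),
       self_match_fraction = mean(sub$category == "FSM" &
                                    sub$matched_reference == sub$transcript_id))
}
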