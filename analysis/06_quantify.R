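#!/usr/bin/env Rscript
# Stage 6: quantification and statistics — TPM from full-length counts,
# per-gene relative isoform abundance, genes whose dominant isoform carries
# a novel ORF, cross-sample overlap, and the accompanying statistical tests
# (chi-squared enrichment, Mann-Whitney length comparison, Spearman
# isoform-count correlation, hypergeometric over-representation with BH).

suppressPackageStartupMessages({library(lrproteo); library(data.table)})
sim <- readRDS("results/sim/sim.rds")
calls <- fread("results/classification.tsv")
pcalls <- fread("results/protein_calls.tsv")
orf_tab <- fread("results/orfs.tsv")

tx_gene <- data.table(
  transcript_id = c(names(sim$ref$catalog$transcripts), calls$transcript_id),
  gene_id = c(vapply(sim$ref$catalog$transcripts, `[[`, "", "gene_id"),
              calls$assigned_gene))
novel_orf_ids <- pcalls[protein_category != "pFSM" &
                          transcript_id %in% orf_tab[status == "retained",
                                                     transcript_id],
                        transcript_id]
dominant <- head(novel_orf_ids, sim$cfg$n_dominant_novel)
counts <- simulate_expression(tx_gene, sim$cfg, dominant = dominant)
write_counts(counts, "results/counts.tsv")

expr <- compute_tpm(counts)
ab <- isoform_abundance(expr, setNames(tx_gene$gene_id, tx_gene$transcript_id),
                        novel_orf_ids = novel_orf_ids)
fwrite(ab, "results/abundance.tsv", sep = "\t")
flags <- flag_novel_dominant(ab, sim$ref$catalog, length_cutoff = 8000)
fwrite(flags$flagged, "results/novel_dominant_genes.tsv", sep = "\t")
message(sprintf("%d genes have a novel-ORF dominant isoform (%d designated at simulation)",
                nrow(flags$flagged), length(dominant)))

samples <- setdiff(names(counts), "transcript_id")
ov <- sample_overlap(lapply(samples, function(s)
  counts$transcript_id[counts[[s]] > 0]))
message(sprintf("%.1f%% of expressed transcripts occur in >= 2 of %d samples",
                100 * ov$fraction_in_ge2, length(samples)))

## statistical tests on the study's own tables
novel_cat <- calls$category %in% c("NIC", "NNIC")
panel <- unique(tx_gene$gene_id)[1:10]           # a toy gene panel
in_panel <- calls$assigned_gene %in% panel
tab <- table(in_panel, novel_cat)
chi <- if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0) &&
           all(colSums(tab) > 0)) chi_squared(tab) else NULL

query <- read_gtf("results/sim/query.gtf")
qlen <- vapply(calls$transcript_id, function(id)
  tx_length(query$transcripts[[id]]), integer(1))
mwu <- mann_whitney(qlen[novel_cat], qlen[!novel_cat])

iso_per_gene <- tx_gene[, .N, by = gene_id]
longest <- vapply(split(names(sim$ref$catalog$transcripts),
                        vapply(sim$ref$catalog$transcripts, `[[`, "", "gene_id")),
                  function(ids) max(vapply(sim$ref$catalog$transcripts[ids],
                                           tx_length, integer(1))), numeric(1))
common <- intersect(iso_per_gene$gene_id, names(longest))
sp <- spearman(iso_per_gene[match(common, gene_id), N], longest[common])

top_genes <- ab[, .(tot = sum(total_count)), by = gene_id][order(-tot)][1:10,
                                                                        gene_id]
set.seed(sim$cfg$seed)
terms <- list(term_high = top_genes[1:5],
              term_random = sample(unique(tx_gene$gene_id), 8))
enr <- overrepresentation(top_genes, unique(tx_gene$gene_id), terms)

stats_out <- rbindlist(list(
  if (!is.null(chi)) data.table(test = "chi_squared_panel_enrichment",
                                statistic = chi$statistic, p = chi$p_value),
  data.table(test = "mann_whitney_novel_vs_known_length",
             statistic = mwu$statistic, p = mwu$p_value),
  data.table(test = "spearman_isoforms_vs_longest_tx",
             statistic = sp$statistic, p = sp$p_value)))
fwrite(stats_out, "results/stats_summary.tsv", sep = "\t")
fwrite(enr, "results/enrichment.tsv", sep = "\t")
message("tests:")
print(stats_out)
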