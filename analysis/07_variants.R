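#!/usr/bin/env Rscript
# Stage 7: rule-based variant prioritization against a gene panel drawn from
# the simulated catalog: the SNV frequency gate and score thresholds, and
# the SV exon-spanning / inversion-breakpoint rules.

suppressPackageStartupMessages({library(lrproteo); library(data.table)})
sim <- readRDS("results/sim/sim.rds")

snvs <- data.table(
  variant_id = sprintf("snv%02d", 1:10),
  population_af = c(0.02, 0.001, 0.002, 0.001, 0.003, 0.001, 0.004, 0.001,
                    0.001, 0.001),
  consequence = c("missense", "stop_gain", "frameshift", "deep_intronic",
                  "deep_intronic", "missense", "missense", "silent", "silent",
                  "other"),
  spliceai = c(NA, NA, NA, 0.45, 0.05, NA, NA, NA, NA, NA),
  phylop = c(6, NA, NA, NA, NA, 3.0, 1.5, 2.9, 1.0, NA),
  cadd_phred = c(35, NA, NA, NA, NA, 12, 11, 10, 9, NA),
  grantham = c(120, NA, NA, NA, NA, 60, 55, NA, NA, NA))
dec_snv <- prioritize_snv(snvs)
fwrite(dec_snv, "results/variant_decisions_snv.tsv", sep = "\t")
message(sprintf("SNVs prioritized: %d of %d",
                sum(dec_snv$prioritized, na.rm = TRUE), nrow(dec_snv)))

# panel = first three simulated genes; exons and gene bodies from the catalog
panel_ids <- head(sim$ref$catalog$genes$gene_id, 3)
exons <- rbindlist(lapply(sim$ref$catalog$transcripts, function(tx)
  if (tx$gene_id %in% panel_ids)
    data.table(chrom = tx$chrom, start = tx$exons$start, end = tx$exons$end,
               gene = tx$gene_id)))
bodies <- exons[, .(start = min(start), end = max(end)), by = .(chrom, gene)]
panel <- list(exons = unique(exons), genes = bodies)

ex1 <- panel$exons[1]
svs <- data.table(
  sv_id = sprintf("sv%d", 1:4),
  type = c("deletion", "deletion", "inversion", "inversion"),
  chrom = ex1$chrom,
  start = c(ex1$start - 50, ex1$start - 50, ex1$start + 10, 1),
  end = c(ex1$end + 50, ex1$end + 50, ex1$end + 99999, 100),
  inhouse_af = c(0.001, 0.02, 0.001, 0.001))
dec_sv <- prioritize_sv(svs, panel)
fwrite(dec_sv, "results/variant_decisions_sv.tsv", sep = "\t")
message("SV decisions:")
print(dec_sv)
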