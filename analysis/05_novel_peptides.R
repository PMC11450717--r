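#!/usr/bin/env Rscript
# Stage 5: simulate the mass-spectrometry side (PSMs with b/y spectra from
# expressed ORFs), detect peptides unique to novel ORFs, validate their
# spectra against theoretical fragment ions, and emit genome-browser tracks
# for the validated novel peptides.

suppressPackageStartupMessages({library(lrproteo); library(data.table)})
sim <- readRDS("results/sim/sim.rds")
dbs <- readRDS("results/db.rds")
orf_res <- readRDS("results/orfs.rds")
calls <- fread("results/classification.tsv")
query <- read_gtf("results/sim/query.gtf", source_tag = "query")

ms <- simulate_psms(dbs$dbd, dbs$index, sim$cfg)
fwrite(ms$psms, "results/psms.tsv", sep = "\t")
write_peaklist(ms$spectra, "results/spectra.mgf")

report <- detect_novel_peptides(ms$psms, dbs$index, dbs$db, calls = calls,
                                spectra = ms$spectra)
fwrite(report, "results/novel_peptides.tsv", sep = "\t")

novel <- report[uniqueness == "unique_novel" & included == TRUE]
truth <- unique(ms$truth[is_unique_novel == TRUE, peptide])
message(sprintf("reported %d novel peptides; planted %d (precision %.0f%%, recall %.0f%%)",
                nrow(novel), length(truth),
                100 * mean(novel$peptide %in% truth),
                100 * mean(truth %in% novel$peptide)))
print(novel[, .(peptide, event, n_psms, best_probability, passes_validation)])

# BED12 track of validated novel peptides
beds <- list()
for (i in seq_len(nrow(novel))) {
  for (txid in strsplit(novel$novel_transcripts[i], ";")[[1]]) {
    orf <- orf_res$orfs[[txid]]
    if (is.null(orf)) next
    beds[[length(beds) + 1]] <-
      map_peptide_to_genome(novel$peptide[i], orf, query$transcripts[[txid]])
  }
}
if (length(beds))
  write_bed12(rbindlist(beds), "results/novel_peptides.bed12")
message("wrote results/novel_peptides.bed12")
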