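#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs — a toy genome, a multi-isoform
# reference catalog, query transcripts with planted novel events, CAGE-like
# TSS peaks and full-length counts over three replicates — and write them in
# the standard formats the rest of the workflow reads back.

suppressPackageStartupMessages({library(lrproteo); library(data.table)})
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 42)
ref <- simulate_reference(cfg)
planted <- plant_novel_isoforms(ref, cfg)

write_fasta(ref$genome, "results/sim/genome.fa")
write_gtf(ref$catalog, "results/sim/reference.gtf")
write_gtf(planted$catalog, "results/sim/query.gtf")
fwrite(planted$truth, "results/sim/truth.tsv", sep = "\t")
write_fasta(ref$proteins, "results/sim/reference_proteins.fa")

# CAGE-like peaks: a peak at ~70% of reference TSSs, small jitter
set.seed(cfg$seed + 9)
tss <- unique(rbindlist(lapply(ref$catalog$transcripts, function(tx)
  data.table(chrom = tx$chrom, pos = tx_tss(tx), strand = tx$strand))))
tss <- tss[runif(.N) < 0.7]
peaks <- tss[, .(chrom, start = pmax(0L, pos - sample(5:30, .N, TRUE)),
                 end = pos + sample(5:30, .N, TRUE))]
fwrite(peaks, "results/sim/cage_peaks.bed", sep = "\t", col.names = FALSE)

saveRDS(list(cfg = cfg, ref = ref, planted = planted),
        "results/sim/sim.rds")

message(sprintf("simulated %d reference transcripts (%d genes) and %d planted novel isoforms",
                length(ref$catalog), nrow(ref$catalog$genes), nrow(planted$truth)))
message("event mix planted:")
print(planted$truth[, .N, by = event][order(-N)])
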