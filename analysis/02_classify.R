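#!/usr/bin/env Rscript
# Stage 2: classify the query transcripts against the reference annotation
# (FSM/NIC/NNIC + novel-element subcategories), score CAGE support of their
# TSSs, and compare the calls with the planted truth.

suppressPackageStartupMessages({library(lrproteo); library(data.table)})

ref_catalog <- read_gtf("results/sim/reference.gtf", source_tag = "reference")
query <- read_gtf("results/sim/query.gtf", source_tag = "query")
truth <- fread("results/sim/truth.tsv")
peaks <- read_bed("results/sim/cage_peaks.bed")

index <- build_reference_index(ref_catalog)
calls <- classify_catalog(query, index)

cage <- rbindlist(lapply(query$transcripts, function(tx)
  as.data.table(cage_support(tx, peaks, window = 50))))
calls <- merge(calls, cage, by = "transcript_id")
fwrite(calls, "results/classification.tsv", sep = "\t")

m <- merge(truth, calls, by = "transcript_id")
message(sprintf("category accuracy %.1f%%, subcategory recovery %.1f%% on %d planted isoforms",
                100 * mean(m$category == m$true_category),
                100 * mean(m$subcategories == m$true_subcategories), nrow(m)))
message("category counts:")
print(calls[, .N, by = category])
message(sprintf("TSS CAGE support within 50 bp: %.1f%% of queries",
                100 * mean(calls$supported)))
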