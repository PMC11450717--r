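#!/usr/bin/env Rscript
# Stage 3: call ORFs on the novel transcripts, filter NMD/truncated/unlikely
# predictions, and classify the retained proteins against the reference ORFs
# (pFSM/pNIC/pNNIC).

suppressPackageStartupMessages({library(lrproteo); library(data.table)})
sim <- readRDS("results/sim/sim.rds")
query <- read_gtf("results/sim/query.gtf", source_tag = "query")
genome <- read_fasta("results/sim/genome.fa", type = "DNA")
calls <- fread("results/classification.tsv")

orf_res <- call_orfs(query, genome, min_aa = sim$cfg$min_aa)
fwrite(orf_res$table, "results/orfs.tsv", sep = "\t")
message("ORF status counts:")
print(orf_res$table[, .N, by = status])

ref_orfs <- reference_orf_index(sim$ref$catalog)
assignment <- setNames(calls$assigned_gene, calls$transcript_id)
pcalls <- classify_proteins(orf_res$orfs, query, ref_orfs,
                            gene_assignment = assignment)
fwrite(pcalls, "results/protein_calls.tsv", sep = "\t")
message("protein category counts (all called ORFs):")
print(pcalls[, .N, by = protein_category])

# transcript x protein classification cross-tab (novel ORFs only)
cross <- merge(calls[, .(transcript_id, category)], pcalls,
               by = "transcript_id")
message("transcript x protein cross-tabulation:")
print(table(cross$category, cross$protein_category))

retained <- Filter(function(o) o$status == "retained", orf_res$orfs)
prot <- vapply(retained, `[[`, "", "protein")
write_fasta(prot, "results/novel_proteins.fa")
saveRDS(orf_res, "results/orfs.rds")
message(sprintf("%d of %d ORFs retained for the search database",
                length(retained), nrow(orf_res$table)))
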