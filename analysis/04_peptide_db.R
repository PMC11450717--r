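#!/usr/bin/env Rscript
# Stage 4: build the hybrid novel+reference protein database, add reversed
# decoys, digest in silico with the three enzyme schemes and index peptide
# uniqueness (unique to a novel ORF / unique to the reference / shared).

suppressPackageStartupMessages({library(lrproteo); library(data.table)})
orf_res <- readRDS("results/orfs.rds")
ref_proteins <- read_fasta("results/sim/reference_proteins.fa")

retained <- Filter(function(o) o$status == "retained", orf_res$orfs)
db <- build_hybrid_db(retained, ref_proteins)
dbd <- add_decoys(db)
write_db_fasta(dbd, "results/hybrid_db.fa")
message(sprintf("hybrid database: %d reference + %d novel targets (+%d decoys)",
                sum(db$origin == "reference"), sum(db$origin == "novel"),
                sum(dbd$decoy)))

index <- build_peptide_index(dbd,
                             enzymes = list("stricttrypsin", "chymotrypsin",
                                            "aspn+lysc"),
                             max_missed = 2, min_len = 7)
out <- copy(index)
out[, parents := vapply(parents, paste, "", collapse = ";")]
fwrite(out, "results/peptide_index.tsv", sep = "\t")
message("theoretical peptide uniqueness partition:")
print(index[, .N, by = uniqueness])
saveRDS(list(db = db, dbd = dbd, index = index), "results/db.rds")
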