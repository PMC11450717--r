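.datatable.aware <- TRUE

# data.table / NSE column names used across the package
utils::globalVariables(c(
  ".", ".I", ".N", "..samples", "accession", "chrom", "decoy", "end",
  "gene_id", "included", "is_novel_orf", "is_unique_novel",
  "longest_reference", "missed", "n_novel", "n_ref", "origin", "ov",
  "p_adjusted", "parents", "peptide", "ppm_error", "probability",
  "protein_category", "relative_abundance", "sequence", "significant",
  "start", "strand", "subcategories", "total_count", "transcript_id",
  "uniqueness", "unindexed", "variant_id", "sv_id", "category",
  "matched_reference", "assigned_gene"))
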