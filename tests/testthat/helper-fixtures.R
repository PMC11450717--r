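# Hand-built fixtures shared across test files. All coordinates 0-based
# half-open, as in the package.

make_tx <- function(id, starts, ends, strand = "+", gene = "geneA",
                    chrom = "chr1", cds = NULL, attributes = character()) {
  transcript_model(id, gene, chrom, strand,
                   data.frame(start = starts, end = ends),
                   cds = cds, attributes = attributes)
}

# A reference gene with a 4-exon master isoform, a 5'-truncated isoform and
# a mono-exon gene next door. Exon boundaries of geneA master:
# (100,200) (300,400) (500,600) (700,800).
toy_reference <- function() {
  a1 <- make_tx("A1", c(100, 300, 500, 700), c(200, 400, 600, 800))
  a2 <- make_tx("A2", c(300, 500, 700), c(400, 600, 800))
  m1 <- make_tx("M1", 2000, 2600, gene = "geneM")
  gene_catalog(list(a1, a2, m1), source_tag = "toy")
}

toy_index <- function() build_reference_index(toy_reference())

# a genome with enough sequence for the toy reference coordinates
toy_genome_string <- function(n = 3000, seed = 99) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# brute-force cleavage-site predicate used as an independent digestion oracle
oracle_sites <- function(res, enzyme_name) {
  n <- length(res)
  if (n < 2) return(logical(0))
  after <- rep(FALSE, n - 1)
  for (i in seq_len(n - 1)) {
    after[i] <- switch(enzyme_name,
      stricttrypsin = res[i] %in% c("K", "R"),
      trypsin = res[i] %in% c("K", "R") && res[i + 1] != "P",
      chymotrypsin = res[i] %in% c("F", "W", "Y", "L") && res[i + 1] != "P",
      aspn = res[i + 1] == "D",
      `lysc-p` = res[i] == "K",
      `aspn+lysc` = res[i + 1] == "D" || res[i] == "K")
  }
  after
}

oracle_digest <- function(sequence, enzyme_name, max_missed, min_len) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  sites <- oracle_sites(res, enzyme_name)
  out <- character()
  for (i in 1:n) for (j in i:n) {
    if (j - i + 1 < min_len) next
    left_ok <- i == 1 || sites[i - 1]
    right_ok <- j == n || sites[j]
    if (!left_ok || !right_ok) next
    internal <- if (j > i) sum(sites[i:(j - 1)]) else 0
    if (internal > max_missed) next
    out <- c(out, paste(res[i:j], collapse = ""))
  }
  sort(unique(out))
}

random_protein <- function(len) {
  paste(sample(c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q",
                 "K", "E", "M", "H", "F", "R", "Y", "W"), len, TRUE),
        collapse = "")
}
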