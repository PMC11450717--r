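test_that("find_best_orf scans frames, prefers longest then 5'-most", {
  o <- find_best_orf("ATGAAATAA", min_aa = 1)
  expect_equal(o$protein, "MK")
  expect_true(o$has_stop)
  expect_equal(c(o$tx_start, o$tx_end), c(0, 9))
  # same ORF found at frame offset 2
  o2 <- find_best_orf("CCATGAAATGA", min_aa = 1)
  expect_equal(o2$protein, "MK")
  expect_equal(o2$tx_start, 2)
  # longest qualifying ORF wins over a shorter one
  long30 <- paste0("ATG", strrep("GCT", 29), "TAA")
  short12 <- paste0("ATG", strrep("GCT", 11), "TAA")
  seq <- paste0("CC", short12, "C", long30)
  o3 <- find_best_orf(seq, min_aa = 25)
  expect_equal(nchar(o3$protein), 30)
  # no stop codon: open ORF returned with has_stop FALSE
  o4 <- find_best_orf(paste0("ATG", strrep("GCT", 30)), min_aa = 25)
  expect_false(o4$has_stop)
  # codons containing N translate to X
  expect_match(find_best_orf("ATGANAGCTTAA", min_aa = 1)$protein, "X")
  expect_null(find_best_orf("CCCCCC"))
})

test_that("CDS projection is strand-aware and invertible", {
  tx <- make_tx("t", c(100, 300, 500), c(200, 400, 600))
  fake_orf <- function(s, e) structure(
    list(tx_start = s, tx_end = e, has_stop = TRUE, protein = ""),
    class = "open_reading_frame")
  # ORF spanning the first junction
  orf <- project_cds(fake_orf(90, 120), tx)
  expect_equal(nrow(orf$cds_blocks), 2)
  expect_equal(orf$cds_blocks,
               data.frame(start = c(190, 300), end = c(200, 320)))
  expect_equal(sum(orf$cds_blocks$end - orf$cds_blocks$start), 30)
  expect_equal(genomic_blocks_to_tx(tx, orf$cds_blocks), c(90, 120))
  # minus strand: transcript position 0 maps into the rightmost exon
  txm <- make_tx("tm", c(100, 300, 500), c(200, 400, 600), strand = "-")
  orfm <- project_cds(fake_orf(0, 30), txm)
  expect_equal(orfm$cds_blocks, data.frame(start = 570, end = 600))
  expect_equal(orfm$start_codon_genomic, 599)
  expect_equal(genomic_blocks_to_tx(txm, orfm$cds_blocks), c(0, 30))
  # full-transcript ORF projects to the exons themselves
  orff <- project_cds(fake_orf(0, tx_length(tx)), tx)
  expect_equal(orff$cds_blocks, tx$exons)
  expect_error(project_cds(fake_orf(10, 1000), tx), "outside")
})

test_that("UTR blocks complement the CDS exactly", {
  tx <- make_tx("t", c(100, 300, 500), c(200, 400, 600))
  orf <- list(tx_start = 150, tx_end = 210, has_stop = TRUE)
  utrs <- annotate_utrs(tx, orf)
  total <- function(df) sum(df$end - df$start)
  expect_equal(total(utrs$five_prime_utr), 150)
  expect_equal(total(utrs$three_prime_utr), tx_length(tx) - 210)
  expect_equal(total(utrs$five_prime_utr) + (210 - 150) +
                 total(utrs$three_prime_utr), tx_length(tx))
  # ORF at the very start / end
  expect_equal(nrow(annotate_utrs(tx, list(tx_start = 0, tx_end = 60))$five_prime_utr), 0)
  expect_equal(nrow(annotate_utrs(tx, list(tx_start = 240,
                                           tx_end = 300))$three_prime_utr), 0)
})

test_that("NMD 50-nt rule measures stop to last junction distance", {
  # two exons of 200 + 100; last junction at transcript position 200
  tx <- make_tx("t", c(0, 300), c(200, 400))
  orf60 <- list(tx_start = 0, tx_end = 140, has_stop = TRUE)   # 60 nt upstream
  orf20 <- list(tx_start = 0, tx_end = 180, has_stop = TRUE)   # 20 nt upstream
  orf_last <- list(tx_start = 0, tx_end = 260, has_stop = TRUE)
  expect_true(flag_nmd(orf60, tx))
  expect_false(flag_nmd(orf20, tx))
  expect_false(flag_nmd(orf_last, tx))
  mono <- make_tx("m", 0, 400)
  expect_false(flag_nmd(orf60, mono))
  expect_true(flag_nmd(orf20, tx, rule_nt = 10))
})

test_that("ORF filtering assigns nmd/truncated/unlikely/retained statuses", {
  tx2 <- make_tx("a", c(0, 300), c(200, 400))
  orfs <- list(a = structure(list(transcript_id = "a", tx_start = 0,
                                  tx_end = 140, protein = strrep("K", 45),
                                  has_stop = TRUE),
                             class = "open_reading_frame"))
  txs <- list(a = tx2)
  expect_equal(filter_orfs(orfs, txs)$a$status, "nmd")
  orfs$a$tx_end <- 260
  expect_equal(filter_orfs(orfs, txs)$a$status, "retained")
  orfs$a$has_stop <- FALSE
  expect_equal(filter_orfs(orfs, txs)$a$status, "truncated")
  orfs$a$has_stop <- TRUE
  orfs$a$protein <- "MKKK"
  expect_equal(filter_orfs(orfs, txs)$a$status, "unlikely")
})

test_that("frame property: 3n insertions preserve the C-terminus, others shift it", {
  set.seed(31)
  base_codons <- paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                                      c("TAA", "TAG", "TGA", "ATG")), 60,
                             TRUE), collapse = "")
  base <- paste0("CCCCC", "ATG", base_codons, "TAA", "CCCCC")
  o_base <- find_best_orf(base, min_aa = 10)
  insert_at <- 8 + 30 * 3                     # codon boundary inside the ORF
  ins3 <- paste0(substr(base, 1, insert_at), "GCTGCAGCC",
                 substr(base, insert_at + 1, nchar(base)))
  o3 <- find_best_orf(ins3, min_aa = 10)
  cterm <- function(o, k = 10) substr(o$protein, nchar(o$protein) - k + 1,
                                      nchar(o$protein))
  expect_equal(cterm(o3), cterm(o_base))
  expect_equal(nchar(o3$protein), nchar(o_base$protein) + 3)
  # a 17-nt insertion shifts the downstream frame
  ins17 <- paste0(substr(base, 1, insert_at), "GCTGCAGCCGCTGCAGC",
                  substr(base, insert_at + 1, nchar(base)))
  o17 <- find_best_orf(ins17, min_aa = 10)
  expect_false(identical(cterm(o17), cterm(o_base)))
  prefix <- substr(o_base$protein, 1, 30)
  expect_equal(substr(o17$protein, 1, 30), prefix)
})
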