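test_that("GTF coordinates convert to 0-based half-open and round-trip", {
  gtf <- c(
    'chr1\tsrc\tgene\t101\t400\t.\t+\t.\tgene_id "g1"; gene_biotype "protein_coding";',
    'chr1\tsrc\ttranscript\t101\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; tag "basic";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";')
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  cat <- read_gtf(f)
  tx <- cat$transcripts[["t1"]]
  expect_equal(tx$exons, data.frame(start = c(100L, 300L), end = c(200L, 400L)))
  expect_equal(unname(tx$attributes[["tag"]]), "basic")

  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(cat, f2)
  cat2 <- read_gtf(f2)
  expect_equal(cat2$transcripts[["t1"]]$exons, tx$exons)
  expect_equal(cat2$transcripts[["t1"]]$attributes[["tag"]], "basic")
  expect_equal(names(cat2$transcripts), names(cat$transcripts))
})

test_that("GTF errors name the offending line; invalid exons are rejected", {
  bad <- c('chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1";')
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(bad, f)
  expect_error(read_gtf(f), "line 1")
  expect_error(make_tx("t", c(100, 150), c(200, 250)), "overlap")
  expect_error(make_tx("t", 100, 100), "invalid exon")
})

test_that("minus-strand transcripts keep ascending exon order through GTF", {
  tx <- make_tx("tm", c(100, 300), c(200, 400), strand = "-")
  cat <- gene_catalog(list(tx))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(cat, f)
  back <- read_gtf(f)$transcripts[["tm"]]
  expect_false(is.unsorted(back$exons$start))
  expect_equal(back$strand, "-")
})

test_that("empty catalog writes an empty file", {
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(gene_catalog(list()), f)
  expect_length(readLines(f), 0)
})

test_that("spliced_sequence concatenates exons and reverse-complements on '-'", {
  genome <- c(c1 = "ATTGGGCCC")
  plus <- make_tx("p", c(0, 6), c(3, 9), chrom = "c1")
  expect_equal(spliced_sequence(plus, genome), "ATTCCC")
  minus <- make_tx("m", c(0, 6), c(3, 9), strand = "-", chrom = "c1")
  expect_equal(spliced_sequence(minus, genome), revcomp("ATTCCC"))
  expect_equal(spliced_sequence(minus, genome), "GGGAAT")
  whole <- make_tx("w", 0, 9, chrom = "c1")
  expect_equal(spliced_sequence(whole, genome), "ATTGGGCCC")
  oob <- make_tx("o", 0, 20, chrom = "c1")
  expect_error(spliced_sequence(oob, genome), "beyond")
})

test_that("spliced length equals the exon length sum (random transcripts)", {
  set.seed(4)
  genome <- c(chrR = toy_genome_string(5000))
  for (i in 1:20) {
    n <- sample(1:5, 1)
    starts <- sort(sample(seq(0, 4500, by = 50), n))
    ends <- starts + sample(10:40, n, TRUE)
    tx <- make_tx(paste0("r", i), starts, ends,
                  strand = sample(c("+", "-"), 1), chrom = "chrR")
    expect_equal(nchar(spliced_sequence(tx, genome)), tx_length(tx))
  }
})

test_that("FASTA round-trips and rejects duplicate identifiers", {
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(a = "ACGT", b = "GGGTTTAAA"), f)
  expect_equal(read_fasta(f), c(a = "ACGT", b = "GGGTTTAAA"))
  writeLines(c(">a", "ACGT", ">a", "TTTT"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">x", "ACGR"), f)
  expect_error(read_fasta(f, type = "DNA"), "ACGTN")
})

test_that("MGF-style peak lists parse with sorted peaks", {
  f <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=s1", "PEPMASS=500.25", "CHARGE=2+",
               "300.1 10", "100.2 5", "END IONS",
               "BEGIN IONS", "TITLE=s2", "PEPMASS=400.1", "CHARGE=1+",
               "150.5 3", "END IONS"), f)
  sp <- read_peaklist(f)
  expect_length(sp, 2)
  expect_equal(sp[[1]]$title, "s1")
  expect_equal(sp[[1]]$charge, 2L)
  expect_false(is.unsorted(sp[[1]]$peaks$mz))
  f2 <- withr::local_tempfile(fileext = ".mgf")
  write_peaklist(sp, f2)
  sp2 <- read_peaklist(f2)
  expect_equal(sp2[[2]]$peaks$mz, sp[[2]]$peaks$mz, tolerance = 1e-6)
})

test_that("count tables read as transcript keyed tables", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\ts1\ts2\ts3", "t1\t5\t0\t2", "t2\t1\t1\t1"), f)
  ct <- read_counts(f)
  expect_equal(ncol(ct), 4)
  expect_equal(ct[transcript_id == "t1", s3], 2L)
  writeLines("transcript_id", f)
  expect_error(read_counts(f), "sample")
})

test_that("BED12 blockStarts are relative and validated", {
  rec <- bed12_from_blocks("chr1", "+", data.frame(start = c(100, 180),
                                                   end = c(120, 200)), "pep1")
  expect_equal(rec$blockCount, 2)
  expect_equal(rec$blockStarts, "0,80")
  expect_equal(rec$blockSizes, "20,20")
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed12(rec, f)
  got <- strsplit(readLines(f), "\t")[[1]]
  expect_length(got, 12)
  bad <- rec
  bad$blockStarts <- "80,0"
  expect_error(write_bed12(bad, f), "sorted")
  bad2 <- rec
  bad2$end <- 150
  expect_error(write_bed12(bad2, f), "block")
})
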