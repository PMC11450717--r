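test_that("reference index counts junctions, sites and chains per gene", {
  idx <- toy_index()
  geneA <- idx$genes[["geneA"]]
  expect_length(geneA$junctions, 3)       # two isoforms share 2 junctions
  expect_length(geneA$donors, 3)
  expect_length(geneA$acceptors, 3)
  expect_length(geneA$chains, 2)
  expect_equal(nrow(idx$genes[["geneM"]]$mono), 1)
  expect_error(build_reference_index(gene_catalog(list())), "empty")
})

test_that("gene assignment follows junction votes, then exon overlap", {
  idx <- toy_index()
  q_junc <- make_tx("q1", c(120, 300, 500), c(200, 400, 620))
  expect_equal(assign_gene(q_junc, idx), "geneA")
  q_mono <- make_tx("q2", 2100, 2250)
  expect_equal(assign_gene(q_mono, idx), "geneM")
  q_far <- make_tx("q3", 9000, 9100)
  expect_match(assign_gene(q_far, idx), "^novelGene")
})

test_that("FSM requires exact chain match; NIC known sites; NNIC novel site", {
  idx <- toy_index()
  # same chain as A1, different ends
  fsm <- classify_transcript(make_tx("f", c(120, 300, 500, 700),
                                     c(200, 400, 600, 780)), idx)
  expect_equal(fsm$category, "FSM")
  expect_equal(fsm$matched_reference, "A1")
  # exon 3 skipped: junction (400, 700) is new, both sites known
  nic <- classify_transcript(make_tx("s", c(100, 300, 700),
                                     c(200, 400, 800)), idx)
  expect_equal(nic$category, "NIC")
  # donor of intron 1 shifted +9 nt to an unannotated site
  nnic <- classify_transcript(make_tx("n", c(100, 300, 500, 700),
                                      c(209, 400, 600, 800)), idx)
  expect_equal(nnic$category, "NNIC")
})

test_that("categories partition: exactly one of FSM/NIC/NNIC per query", {
  cfg <- sim_config(seed = 11, n_genes = 8, n_novel = 24)
  ref <- simulate_reference(cfg)
  pl <- plant_novel_isoforms(ref, cfg)
  idx <- build_reference_index(ref$catalog)
  calls <- classify_catalog(pl$catalog, idx)
  expect_true(all(calls$category %in% c("FSM", "NIC", "NNIC")))
  # NNIC iff at least one site is unannotated
  for (id in calls$transcript_id) {
    tx <- pl$catalog$transcripts[[id]]
    g <- calls[transcript_id == id, assigned_gene]
    ge <- idx$genes[[g]]
    has_novel_site <- !all(donor_sites(tx) %in% ge$donors) ||
      !all(acceptor_sites(tx) %in% ge$acceptors)
    expect_equal(calls[transcript_id == id, category] == "NNIC",
                 has_novel_site)
  }
})

test_that("mono-exon rules: FSM inside mono reference, NIC inside any exon", {
  idx <- toy_index()
  expect_equal(classify_transcript(make_tx("m1", 2100, 2400), idx)$category,
               "FSM")
  inside_exon <- classify_transcript(make_tx("m2", 320, 380), idx)
  expect_equal(inside_exon$category, "NIC")
  straddling <- classify_transcript(make_tx("m3", 150, 450), idx)
  expect_equal(straddling$category, "NNIC")
})

test_that("strand mirror: classification is invariant under coordinate mirroring", {
  L <- 10000L
  mirror_tx <- function(tx, id) {
    make_tx(id, L - rev(tx$exons$end), L - rev(tx$exons$start),
            strand = if (tx$strand == "+") "-" else "+",
            gene = tx$gene_id, chrom = tx$chrom)
  }
  ref <- toy_reference()
  mref <- gene_catalog(lapply(ref$transcripts, function(tx)
    mirror_tx(tx, tx$transcript_id)))
  midx <- build_reference_index(mref)
  idx <- toy_index()
  queries <- list(
    make_tx("q1", c(120, 300, 500, 700), c(200, 400, 600, 780)),
    make_tx("q2", c(100, 300, 700), c(200, 400, 800)),
    make_tx("q3", c(100, 300, 500, 700), c(209, 400, 600, 800)),
    make_tx("q4", c(100, 300), c(200, 650)))
  for (q in queries) {
    a <- classify_transcript(q, idx)
    b <- classify_transcript(mirror_tx(q, q$transcript_id), midx)
    expect_equal(a$category, b$category, info = q$transcript_id)
    expect_equal(sort(a$subcategories), sort(b$subcategories),
                 info = q$transcript_id)
  }
})

test_that("subcategory rules fire on canonical constructions", {
  idx <- toy_index()
  # intron retention: exon spanning intron 2 with both flanks overlapped
  ir <- classify_transcript(make_tx("ir", c(100, 300, 700), c(200, 600, 800)),
                            idx)
  expect_true("intron_retention" %in% ir$subcategories)
  # extra intron: novel intron inside reference exon 1
  ei <- classify_transcript(make_tx("ei", c(100, 160, 300, 500, 700),
                                    c(140, 200, 400, 600, 800)), idx)
  expect_true("extra_intron" %in% ei$subcategories)
  # alt polyA on an FSM: 3' end 600 bp beyond all TES
  ap <- classify_transcript(make_tx("ap", c(100, 300, 500, 700),
                                    c(200, 400, 600, 1400)), idx)
  expect_equal(ap$category, "FSM")
  expect_equal(ap$subcategories, "alt_polyA")
  # novel exon in intron 3 (novel sites -> NNIC)
  ne <- classify_transcript(make_tx("ne", c(100, 300, 500, 630, 700),
                                    c(200, 400, 600, 660, 800)), idx)
  expect_equal(ne$category, "NNIC")
  expect_true("novel_exon" %in% ne$subcategories)
})

test_that("CAGE support window arithmetic is strand-aware", {
  peaks <- data.frame(chrom = "chr1", start = c(960, 920), end = c(1010, 950))
  tx <- make_tx("t", 1000, 1500)
  expect_equal(cage_support(tx, peaks[1, ])$distance, 0)
  expect_true(cage_support(tx, peaks[1, ])$supported)
  r <- cage_support(tx, peaks[2, ], window = 50)
  expect_equal(r$distance, 50)
  expect_true(r$supported)
  peaks3 <- data.frame(chrom = "chr1", start = 920, end = 949)
  r3 <- cage_support(tx, peaks3, window = 50)
  expect_equal(r3$distance, 51)
  expect_false(r3$supported)
  # mirrored on '-': upstream means higher coordinates
  txm <- make_tx("tm", 500, 1001, strand = "-")
  pk <- data.frame(chrom = "chr1", start = 1051, end = 1080)
  rm_ <- cage_support(txm, pk, window = 50)
  expect_equal(rm_$distance, 50)
  expect_true(rm_$supported)
})

test_that("contained_features equals a brute-force containment scan", {
  set.seed(21)
  exons <- data.frame(chrom = "chr1",
                      start = sample(seq(0, 900, 10), 30),
                      end = NA)
  exons$end <- exons$start + sample(20:120, 30, TRUE)
  feats <- data.frame(chrom = "chr1",
                      start = sample(0:950, 60), end = NA)
  feats$end <- feats$start + sample(5:80, 60, TRUE)
  got <- contained_features(feats, exons)
  brute <- feats[vapply(seq_len(nrow(feats)), function(i)
    any(exons$start <= feats$start[i] & feats$end[i] <= exons$end),
    logical(1)), ]
  expect_equal(got, brute)
  # boundary case: feature exactly equal to an exon is retained
  eq <- data.frame(chrom = "chr1", start = exons$start[1], end = exons$end[1])
  expect_equal(nrow(contained_features(eq, exons)), 1)
})

test_that("sample overlap counts presence across sets", {
  r <- sample_overlap(list(c("a", "b"), c("b", "c"), "b"))
  expect_equal(unname(r$n_samples_per_transcript[c("a", "b", "c")]), c(1, 3, 1))
  expect_equal(r$fraction_in_ge2, 1 / 3)
  expect_equal(sample_overlap(list(c("x", "y"), c("x", "y")))$fraction_in_ge2, 1)
  expect_equal(sample_overlap(list("x", "y"))$fraction_in_ge2, 0)
  expect_error(sample_overlap(list("x")), "two")
})
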