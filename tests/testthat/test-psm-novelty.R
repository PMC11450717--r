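test_that("GG fragment masses match first principles", {
  theo <- theoretical_ions("GG", max_fragment_charge = 1)
  b1 <- theo$mz[theo$ion == "b" & theo$index == 1]
  y1 <- theo$mz[theo$ion == "y" & theo$index == 1]
  expect_equal(b1, 58.0287, tolerance = 5e-4)
  expect_equal(y1, 76.0393, tolerance = 5e-4)
  # carbamidomethyl on C is a fixed +57.02146
  tc <- theoretical_ions("CG", max_fragment_charge = 1)
  expect_equal(tc$mz[tc$ion == "b" & tc$index == 1],
               103.00919 + 57.02146 + 1.007276, tolerance = 1e-5)
})

test_that("b/y complementarity holds for random modified peptides", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(5:20, 1)
    pep <- random_protein(n)
    mods <- if (runif(1) < 0.3 && grepl("M", pep))
      paste0("Oxidation@", regexpr("M", pep)[[1]]) else ""
    if (runif(1) < 0.2) mods <- paste(c(mods[nzchar(mods)], "Acetyl@0"),
                                      collapse = ";")
    M <- peptide_mass(pep, mods)
    theo <- theoretical_ions(pep, max_fragment_charge = 1, mods = mods)
    b <- theo[theo$ion == "b", ]
    y <- theo[theo$ion == "y", ]
    for (k in seq_len(n - 1)) {
      expect_equal(b$mz[b$index == k] + y$mz[y$index == n - k],
                   M + 2 * 1.007276, tolerance = 1e-6)
    }
  }
  expect_error(theoretical_ions("GG", mods = "Phospho@1"), "unknown")
})

test_that("peak matching respects tolerance and one-to-one assignment", {
  theo <- data.table::data.table(ion = c("b", "y"), index = c(1L, 1L),
                                 charge = 1L, mz = c(500, 800))
  hit <- match_peaks(data.frame(mz = 500, intensity = 1), theo)
  expect_equal(hit$ppm_error, 0)
  off25 <- 800 * (1 + 25e-6)
  expect_equal(nrow(match_peaks(data.frame(mz = off25, intensity = 1), theo,
                                tolerance_ppm = 20)), 0)
  # two ions near one peak: only the closer one is matched
  theo2 <- data.table::data.table(ion = c("b", "y"), index = c(2L, 3L),
                                  charge = 1L,
                                  mz = c(600, 600 * (1 + 8e-6)))
  hit2 <- match_peaks(data.frame(mz = 600 * (1 + 2e-6), intensity = 1), theo2)
  expect_equal(nrow(hit2), 1)
  expect_equal(hit2$ion, "b")
})

test_that("validation criteria: ion count, b+y presence, strict probability", {
  pep <- "SAMPLEPTIDER"
  theo <- theoretical_ions(pep, max_fragment_charge = 1)
  full_peaks <- data.frame(mz = sort(theo$mz), intensity = 100)
  psm <- list(peptide = pep, mods = "", charge = 2, probability = 0.99,
              peaks = full_peaks)
  v <- validate_psm(psm)
  expect_true(v$passes)
  expect_true(v$has_b && v$has_y)
  # exactly 7 matched ions (with both series present) fail, 8 pass
  theo1 <- theo[theo$charge == 1]
  mk_peaks <- function(nb, ny) data.frame(
    mz = sort(c(theo1$mz[theo1$ion == "b"][seq_len(nb)],
                theo1$mz[theo1$ion == "y"][seq_len(ny)])), intensity = 100)
  p7 <- validate_psm(list(peptide = pep, mods = "", charge = 2,
                          probability = 0.99, peaks = mk_peaks(4, 3)))
  expect_false(p7$passes)
  expect_equal(p7$n_matched_ions, 7)
  expect_true(p7$has_b && p7$has_y)
  p8 <- validate_psm(list(peptide = pep, mods = "", charge = 2,
                          probability = 0.99, peaks = mk_peaks(4, 4)))
  expect_true(p8$passes)
  expect_equal(p8$n_matched_ions, 8)
  # probability exactly at the threshold fails (strict inequality)
  pb <- validate_psm(list(peptide = pep, mods = "", charge = 2,
                          probability = 0.95, peaks = full_peaks))
  expect_false(pb$passes)
  expect_false(pb$probability_ok)
  # missing peaks: verdict carries a reason
  p0 <- validate_psm(list(peptide = pep, mods = "", charge = 2,
                          probability = 0.99, peaks = NULL))
  expect_false(p0$passes)
  expect_equal(p0$reason, "no_peaks")
})

test_that("validation is monotone in matched ions", {
  pep <- "GLSDGEWQLVLNVWGK"
  theo <- theoretical_ions(pep, max_fragment_charge = 1)
  mixed <- theo[order(theo$index, theo$ion)]       # b1,y1,b2,y2,...
  v1 <- NULL
  for (k in c(6, 8, 12, 20)) {
    v2 <- validate_psm(list(peptide = pep, mods = "", charge = 2,
                            probability = 0.99,
                            peaks = data.frame(mz = sort(mixed$mz[1:k]),
                                               intensity = 1)))
    if (!is.null(v1)) {
      expect_gte(v2$n_matched_ions, v1$n_matched_ions)
      expect_true(!v1$passes || v2$passes)
    }
    v1 <- v2
  }
  expect_true(v1$passes)
})

test_that("the b/y index series maps peptides onto genome blocks", {
  tx <- make_tx("t", c(100, 300), c(200, 400))
  # CDS covers the whole transcript: 200 nt -> protein of 66 aa + stop
  orf <- structure(list(transcript_id = "t", tx_start = 0, tx_end = 200,
                        protein = paste0("MEVKWPTQ", strrep("G", 22), "WIN",
                                         strrep("G", 20)),
                        has_stop = TRUE),
                   class = "open_reading_frame")
  # peptide inside exon 1: residues 2..8 -> nt 3..24
  p1 <- map_peptide_to_genome("EVKWPTQ", orf, tx)
  expect_equal(p1$blockCount, 1)
  expect_equal(p1$end - p1$start, 21)
  # junction-spanning: residues 31..36 -> nt 90..108 crosses the junction at 100
  pj <- map_peptide_to_genome("WINGGG", orf, tx)
  expect_equal(pj$blockCount, 2)
  sizes <- as.integer(strsplit(pj$blockSizes, ",")[[1]])
  expect_equal(sum(sizes), 18)
  # all occurrences are reported
  multi <- map_peptide_to_genome("GGGGG", orf, tx)
  expect_gt(nrow(multi), 1)
  expect_error(map_peptide_to_genome("KRKRKR", orf, tx), "not found")
})

test_that("novel peptide detection joins index, calls and validation", {
  res <- run_synthetic_study(sim_config(seed = 6, n_genes = 8, n_novel = 20))
  rep <- res$novel_report
  truth <- unique(res$psms$truth[is_unique_novel == TRUE, peptide])
  got <- rep[uniqueness == "unique_novel" & included == TRUE, peptide]
  expect_setequal(got, truth)
  # shared peptides are never reported as novel
  shared <- res$peptide_index[uniqueness == "shared", peptide]
  expect_length(intersect(got, shared), 0)
  # decoy PSMs excluded, noise flagged unindexed
  cfg <- sim_config(seed = 6, n_genes = 8, n_novel = 20,
                    psm = list(peptides_per_orf = 2, n_reference_proteins = 10,
                               noise_peptide_rate = 0.2, decoy_hit_rate = 0.2,
                               peak_noise_rate = 0, true_prob = c(0.96, 0.999),
                               false_prob = c(0.2, 0.9)))
  res2 <- run_synthetic_study(cfg)
  rep2 <- res2$novel_report
  expect_false(any(grepl("rev_", rep2$parents)))
  noise_peps <- res2$psms$truth[class == "noise", peptide]
  expect_true(all(noise_peps %in% rep2[unindexed == TRUE, peptide]))
  got2 <- rep2[uniqueness == "unique_novel" & included == TRUE, peptide]
  truth2 <- unique(res2$psms$truth[is_unique_novel == TRUE, peptide])
  expect_setequal(got2, truth2)
})

test_that("override list force-includes a failing peptide", {
  db <- build_hybrid_db(c(t1 = "AAAKPEPTIDEK"), c(r1 = "GGGKWWSHRDPK"))
  idx <- build_peptide_index(db, enzymes = list("stricttrypsin"))
  psms <- data.frame(spectrum_id = "s1", peptide = "PEPTIDEK", mods = "",
                     charge = 2, probability = 0.5, proteins = "nov|t1")
  spectra <- list(s1 = list(title = "s1", pepmass = 500, charge = 2,
                            peaks = data.frame(mz = c(100, 200),
                                               intensity = c(1, 1))))
  plain <- detect_novel_peptides(psms, idx, db, spectra = spectra)
  expect_false(plain$included[plain$peptide == "PEPTIDEK"])
  forced <- detect_novel_peptides(psms, idx, db, spectra = spectra,
                                  override = "PEPTIDEK")
  row <- forced[forced$peptide == "PEPTIDEK", ]
  expect_true(row$included)
  expect_true(row$override)
  expect_false(row$passes_validation)
})
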