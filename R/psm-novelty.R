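# Peptide-spectrum-match ingestion, novel-peptide detection, and spectrum
# validation against theoretical b/y fragment ions.
#
# Only b and y ions at charge 1..max_fragment_charge are considered;
# monoisotopic masses throughout. Fixed carbamidomethylation of C is always
# applied; variable modifications are methionine oxidation and N-terminal
# acetylation, given as "Oxidation@<pos>" / "Acetyl@0" tokens.

PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565

AA_MONO <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
             V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
             I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
             K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
             F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

MOD_MASSES <- c(Carbamidomethyl = 57.02146, Oxidation = 15.9949,
                Acetyl = 42.01057)

parse_mods <- function(mods) {
  if (is.na(mods) || !nzchar(mods)) return(data.frame(name = character(),
                                                      pos = integer()))
  toks <- strsplit(mods, "[;,]")[[1L]]
  toks <- trimws(toks[nzchar(trimws(toks))])
  parts <- strsplit(toks, "@", fixed = TRUE)
  nm <- vapply(parts, `[[`, "", 1L)
  if (any(!nm %in% names(MOD_MASSES)))
    stop("unknown modification tag: ", nm[!nm %in% names(MOD_MASSES)][1L])
  data.frame(name = nm, pos = as.integer(vapply(parts, `[[`, "", 2L)))
}

residue_masses <- function(peptide, mods = "") {
  res <- strsplit(peptide, "")[[1L]]
  if (any(!res %in% names(AA_MONO)))
    stop("non-canonical residue in peptide: ", peptide)
  m <- unname(AA_MONO[res])
  m[res == "C"] <- m[res == "C"] + MOD_MASSES[["Carbamidomethyl"]]
  md <- parse_mods(mods)
  nterm <- 0
  for (i in seq_len(nrow(md))) {
    if (md$pos[i] == 0L) {
      if (md$name[i] != "Acetyl") stop("only Acetyl allowed at the N-terminus")
      nterm <- nterm + MOD_MASSES[["Acetyl"]]
    } else {
      if (md$pos[i] > length(res)) stop("modification position beyond peptide")
      m[md$pos[i]] <- m[md$pos[i]] + MOD_MASSES[[md$name[i]]]
    }
  }
  list(residues = m, nterm = nterm)
}

#' Monoisotopic neutral peptide mass
#' @param peptide Amino-acid string (canonical residues).
#' @param mods Modification tokens, e.g. `"Oxidation@5;Acetyl@0"`.
#' @export
peptide_mass <- function(peptide, mods = "") {
  rm <- residue_masses(peptide, mods)
  sum(rm$residues) + rm$nterm + WATER_MASS
}

#' Theoretical b/y fragment ions
#'
#' All b_i and y_i for 1 <= i < n at charges 1..`max_fragment_charge`, as
#' monoisotopic m/z (proton mass 1.007276).
#'
#' @inheritParams peptide_mass
#' @param max_fragment_charge Highest fragment charge considered (default 2).
#' @return data.table: ion ("b"/"y"), index, charge, mz.
#' @export
theoretical_ions <- function(peptide, max_fragment_charge = 2L, mods = "") {
  rm <- residue_masses(peptide, mods)
  n <- length(rm$residues)
  if (n < 2L) stop("peptide too short for fragmentation")
  b_neutral <- cumsum(rm$residues)[-n] + rm$nterm
  y_neutral <- cumsum(rev(rm$residues))[-n] + WATER_MASS   # y_i = last i residues
  rows <- list()
  for (z in seq_len(max_fragment_charge)) {
    rows[[length(rows) + 1L]] <- data.table::data.table(
      ion = "b", index = seq_len(n - 1L), charge = z,
      mz = (b_neutral + z * PROTON_MASS) / z)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      ion = "y", index = seq_len(n - 1L), charge = z,
      mz = (y_neutral + z * PROTON_MASS) / z)
  }
  data.table::rbindlist(rows)
}

#' Match observed peaks to theoretical ions
#'
#' Each theoretical ion is matched to the nearest peak within the ppm
#' tolerance; a peak may satisfy only one ion and vice versa (closest ppm
#' error wins, assigned greedily).
#'
#' @param peaks data.frame with `mz`, `intensity`, sorted by mz.
#' @param theoretical A [theoretical_ions()] table.
#' @param tolerance_ppm Fragment mass tolerance (default 20 ppm).
#' @return data.table: ion, index, charge, theoretical_mz, observed_mz,
#'   ppm_error, peak (row index into `peaks`).
#' @export
match_peaks <- function(peaks, theoretical, tolerance_ppm = 20) {
  if (!nrow(peaks) || !nrow(theoretical))
    return(data.table::data.table(ion = character(), index = integer(),
                                  charge = integer(), theoretical_mz = numeric(),
                                  observed_mz = numeric(), ppm_error = numeric(),
                                  peak = integer()))
  cand <- list()
  for (i in seq_len(nrow(theoretical))) {
    tm <- theoretical$mz[i]
    ppm <- (peaks$mz - tm) / tm * 1e6
    ok <- which(abs(ppm) <= tolerance_ppm)
    if (length(ok))
      cand[[length(cand) + 1L]] <- data.table::data.table(
        ti = i, peak = ok, ppm_error = ppm[ok])
  }
  if (!length(cand)) return(match_peaks(peaks[0, ], theoretical))
  cand <- data.table::rbindlist(cand)
  cand <- cand[order(abs(ppm_error))]
  used_t <- logical(nrow(theoretical))
  used_p <- logical(nrow(peaks))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    ti <- cand$ti[r]; pk <- cand$peak[r]
    if (!used_t[ti] && !used_p[pk]) {
      keep[r] <- TRUE
      used_t[ti] <- TRUE
      used_p[pk] <- TRUE
    }
  }
  cand <- cand[keep]
  data.table::data.table(
    ion = theoretical$ion[cand$ti], index = theoretical$index[cand$ti],
    charge = theoretical$charge[cand$ti],
    theoretical_mz = theoretical$mz[cand$ti],
    observed_mz = peaks$mz[cand$peak], ppm_error = cand$ppm_error,
    peak = cand$peak)
}

#' Validate a PSM against its spectrum
#'
#' The validation criteria: at least `min_ions` matched fragment ions
#' including at least one b- and one y-ion, identification probability
#' strictly greater than `min_probability`, and at least
#' `majority_threshold` of the `top_n_peaks` most intense peaks explained by
#' b/y ions.
#'
#' @param psm list/row with fields `peptide`, `mods`, `charge`,
#'   `probability`, `peaks` (data.frame mz/intensity, or NULL).
#' @param tolerance_ppm Fragment tolerance.
#' @param min_ions Minimum matched ions (default 8).
#' @param min_probability Probability threshold, strict (default 0.95).
#' @param majority_threshold Fraction of top peaks that must be explained.
#' @param top_n_peaks Number of most intense peaks considered.
#' @param max_fragment_charge Fragment charges considered.
#' @return list of class `validation_verdict`: n_matched_ions, has_b, has_y,
#'   probability_ok, fraction_peaks_explained, passes, reason.
#' @export
validate_psm <- function(psm, tolerance_ppm = 20, min_ions = 8L,
                         min_probability = 0.95, majority_threshold = 0.5,
                         top_n_peaks = 50L, max_fragment_charge = 2L) {
  verdict <- function(n = 0L, b = FALSE, y = FALSE, p = FALSE, f = 0,
                      passes = FALSE, reason = NA_character_) {
    structure(list(n_matched_ions = n, has_b = b, has_y = y,
                   probability_ok = p, fraction_peaks_explained = f,
                   passes = passes, reason = reason),
              class = "validation_verdict")
  }
  if (is.null(psm$peaks) || !nrow(psm$peaks))
    return(verdict(reason = "no_peaks"))
  mods <- if (is.null(psm$mods) || is.na(psm$mods)) "" else psm$mods
  theo <- theoretical_ions(psm$peptide, max_fragment_charge = max_fragment_charge,
                           mods = mods)
  matches <- match_peaks(psm$peaks, theo, tolerance_ppm = tolerance_ppm)
  n <- nrow(matches)
  has_b <- any(matches$ion == "b")
  has_y <- any(matches$ion == "y")
  prob_ok <- isTRUE(psm$probability > min_probability)
  top <- order(psm$peaks$intensity, decreasing = TRUE)[
    seq_len(min(top_n_peaks, nrow(psm$peaks)))]
  frac <- mean(top %in% matches$peak)
  passes <- n >= min_ions && has_b && has_y && prob_ok &&
    frac >= majority_threshold
  verdict(n, has_b, has_y, prob_ok, frac, passes,
          reason = if (passes) NA_character_ else "criteria_not_met")
}

#' Detect novel peptides among PSMs
#'
#' Joins PSM peptides to the peptide uniqueness index; peptides whose
#' uniqueness is `unique_novel` are reported with their parent novel
#' transcripts and the novel event labels of those transcripts' structural
#' calls. PSMs whose parents are all decoys are excluded; PSM peptides
#' absent from the index are flagged, not dropped. When spectra are
#' supplied, each reported peptide carries a validation verdict; peptides on
#' the override list are force-included with a flag even when validation
#' fails.
#'
#' @param psms data.frame: spectrum_id, peptide, mods, charge, probability,
#'   proteins (semicolon-joined accessions).
#' @param index A [build_peptide_index()].
#' @param db The `hybrid_db` (to map accessions to source transcripts).
#' @param calls Structural call table from [classify_catalog()] (optional).
#' @param spectra Named list of spectra keyed by spectrum_id (optional).
#' @param override Character vector of peptides to force-include.
#' @param ... Passed to [validate_psm()].
#' @return data.table report, one row per candidate novel peptide.
#' @export
detect_novel_peptides <- function(psms, index, db, calls = NULL,
                                  spectra = NULL, override = character(), ...) {
  psms <- data.table::as.data.table(psms)
  parents_list <- strsplit(psms$proteins, ";", fixed = TRUE)
  all_decoy <- vapply(parents_list, function(p)
    length(p) > 0L && all(startsWith(p, "rev_")), logical(1))
  psms <- psms[!all_decoy]
  if (!nrow(psms))
    return(data.table::data.table(peptide = character()))

  idx <- data.table::as.data.table(index)
  psms[, unindexed := !peptide %in% idx$peptide]
  merged <- merge(psms, idx[, .(peptide, parents, uniqueness)],
                  by = "peptide", all.x = TRUE)
  merged[is.na(uniqueness) & unindexed, uniqueness := "unindexed"]
  novel <- merged[uniqueness %in% c("unique_novel", "unindexed") |
                    peptide %in% override]
  if (!nrow(novel))
    return(data.table::data.table(peptide = character()))

  acc2tx <- stats::setNames(db$source_transcripts, db$accession)
  one_pep <- function(sub) {
    pep <- sub$peptide[1L]
    par <- unique(unlist(sub$parents))
    par <- as.character(par[!is.na(par)])
    ntx <- unique(unlist(acc2tx[par[startsWith(par, "nov|")]]))
    events <- NA_character_
    if (!is.null(calls) && length(ntx)) {
      ev <- calls$subcategories[calls$transcript_id %in% ntx]
      ev <- unique(unlist(strsplit(ev, ",")))
      if (length(ev)) events <- paste(sort(ev), collapse = ",")
    }
    validated <- NA
    n_ions <- NA_integer_
    if (!is.null(spectra)) {
      verdicts <- lapply(seq_len(nrow(sub)), function(i) {
        sp <- spectra[[sub$spectrum_id[i]]]
        validate_psm(list(peptide = pep, mods = sub$mods[i],
                          charge = sub$charge[i],
                          probability = sub$probability[i],
                          peaks = if (is.null(sp)) NULL else sp$peaks), ...)
      })
      validated <- any(vapply(verdicts, `[[`, logical(1), "passes"))
      n_ions <- max(vapply(verdicts, `[[`, 0L, "n_matched_ions"))
    }
    data.table::data.table(
      peptide = pep, uniqueness = sub$uniqueness[1L],
      parents = paste(par, collapse = ";"),
      novel_transcripts = paste(ntx, collapse = ";"),
      event = events, n_psms = nrow(sub),
      best_probability = max(sub$probability),
      n_matched_ions = n_ions, passes_validation = validated,
      override = pep %in% override,
      unindexed = any(sub$unindexed),
      included = isTRUE(validated) || is.na(validated) || pep %in% override)
  }
  out <- data.table::rbindlist(lapply(split(novel, by = "peptide"), one_pep))
  out[order(peptide)]
}

#' Project a peptide onto the genome as a BED12 record
#'
#' Every occurrence of the peptide in the ORF's protein is converted to its
#' CDS nucleotide span and projected through the exon structure;
#' junction-spanning peptides yield multi-block records.
#'
#' @param peptide Amino-acid string.
#' @param orf A projected `open_reading_frame`.
#' @param tx Its [transcript_model()].
#' @param name BED name (default `peptide|transcript`).
#' @return data.frame of BED12 rows (one per occurrence).
#' @export
map_peptide_to_genome <- function(peptide, orf, tx, name = NULL) {
  hits <- gregexpr(peptide, orf$protein, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L)
    stop("peptide ", peptide, " not found in protein of ", orf$transcript_id)
  rows <- lapply(as.integer(hits), function(p1) {
    s <- orf$tx_start + 3L * (p1 - 1L)
    e <- s + 3L * nchar(peptide)
    blocks <- tx_interval_to_genomic(tx, s, e)
    bed12_from_blocks(tx$chrom, tx$strand, blocks,
                      name = if (is.null(name))
                        paste0(peptide, "|", tx$transcript_id) else name)
  })
  do.call(rbind, rows)
}
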