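# Hybrid target-decoy protein database construction and multi-enzyme
# in-silico digestion with a peptide -> parent uniqueness index.

#' Built-in enzyme specifications
#'
#' Cleavage rules mirror the common search-engine enzyme identifiers:
#' `stricttrypsin` cuts after K/R including before P, `trypsin` after K/R but
#' not before P, `chymotrypsin` after F/W/Y/L but not before P, `aspn` before
#' D, `lysc-p` after K including before P, and `aspn+lysc` is the site union
#' of the last two.
#'
#' @param name One of the identifiers above, or a list of them (site union).
#' @param blocked_by_proline Override the proline-blocking default of the
#'   named enzyme (exposed because published in-silico digests differ here).
#' @return A list of class `enzyme_spec`, or a list of such for combinations.
#' @export
enzyme_spec <- function(name, blocked_by_proline = NULL) {
  if (length(name) > 1L) return(lapply(name, enzyme_spec,
                                       blocked_by_proline = blocked_by_proline))
  name <- tolower(name)
  if (name == "aspn+lysc")
    return(list(enzyme_spec("aspn"), enzyme_spec("lysc-p",
                                                 blocked_by_proline = blocked_by_proline)))
  spec <- switch(name,
    stricttrypsin = list(cleave_residues = c("K", "R"), terminus = "C",
                         blocked_by_proline = FALSE),
    trypsin = list(cleave_residues = c("K", "R"), terminus = "C",
                   blocked_by_proline = TRUE),
    chymotrypsin = list(cleave_residues = c("F", "W", "Y", "L"), terminus = "C",
                        blocked_by_proline = TRUE),
    aspn = list(cleave_residues = "D", terminus = "N",
                blocked_by_proline = FALSE),
    `lysc-p` = list(cleave_residues = "K", terminus = "C",
                    blocked_by_proline = FALSE),
    stop("unknown enzyme: ", name))
  if (!is.null(blocked_by_proline)) spec$blocked_by_proline <- blocked_by_proline
  structure(c(list(name = name), spec), class = "enzyme_spec")
}

#' Build the hybrid novel+reference protein database
#'
#' Novel proteins whose sequence exactly equals a reference protein are
#' dropped (the reference accession stands for them); the remaining novel
#' sequences are deduplicated to one entry each, listing all source
#' transcripts. Accessions are `nov|<first transcript_id>` and `ref|<name>`.
#'
#' @param novel_orfs Named (by transcript_id) list of retained
#'   `open_reading_frame`s, or a named character vector of protein sequences.
#' @param reference_proteins Named character vector (name -> sequence).
#' @return data.table of class `hybrid_db`: accession, sequence, origin,
#'   source_transcripts (list column), decoy.
#' @export
build_hybrid_db <- function(novel_orfs, reference_proteins) {
  if (is.list(novel_orfs)) {
    seqs <- vapply(novel_orfs, `[[`, "", "protein")
  } else seqs <- novel_orfs
  if (!length(reference_proteins)) stop("empty reference proteome")
  if (any(!nzchar(reference_proteins)) || any(!nzchar(seqs)))
    stop("empty protein sequence in input")
  ref <- data.table::data.table(
    accession = paste0("ref|", names(reference_proteins)),
    sequence = unname(reference_proteins), origin = "reference",
    source_transcripts = as.list(names(reference_proteins)), decoy = FALSE)
  keep <- !seqs %in% reference_proteins
  seqs <- seqs[keep]
  nov <- if (length(seqs)) {
    sp <- split(names(seqs), seqs)
    data.table::data.table(
      accession = paste0("nov|", vapply(sp, `[[`, "", 1L)),
      sequence = names(sp), origin = "novel",
      source_transcripts = unname(sp), decoy = FALSE)
  } else data.table::data.table(accession = character(), sequence = character(),
                                origin = character(),
                                source_transcripts = list(), decoy = logical())
  db <- data.table::rbindlist(list(ref, nov))
  if (anyDuplicated(db$accession)) stop("duplicate accession in hybrid database")
  data.table::setattr(db, "class", c("hybrid_db", class(db)))
  db[]
}

#' Add reversed-sequence decoys
#'
#' One full-sequence-reversal decoy per target, accession prefixed; the
#' output has exactly twice as many entries as targets.
#'
#' @param db A [build_hybrid_db()] result without decoys.
#' @param prefix Decoy accession prefix (default `"rev_"`).
#' @export
add_decoys <- function(db, prefix = "rev_") {
  if (any(db$decoy)) stop("database already contains decoys")
  dec <- data.table::copy(db)
  dec[, `:=`(accession = paste0(prefix, accession),
             sequence = vapply(sequence, function(s)
               paste(rev(strsplit(s, "")[[1L]]), collapse = ""), ""),
             decoy = TRUE)]
  out <- data.table::rbindlist(list(db, dec))
  data.table::setattr(out, "class", class(db))
  out[]
}

#' In-silico digestion of one protein
#'
#' Cleavage sites come from the enzyme rule (C-side after `cleave_residues`
#' or N-side before them, honouring proline blocking); for an enzyme
#' combination the sites are the union. Peptides are all runs spanning at
#' most `max_missed` internal sites, filtered by length; protein-terminal
#' peptides are included. Residues outside the 20 canonical letters are
#' treated as non-cleavable.
#'
#' @param sequence Amino-acid string.
#' @param enzyme An [enzyme_spec()], a name string, or a list of either.
#' @param max_missed Maximum internal missed cleavages (default 2).
#' @param min_len Minimum peptide length (default 7).
#' @param max_len Optional maximum peptide length.
#' @return data.table: peptide, missed (minimum missed-cleavage count).
#' @export
digest <- function(sequence, enzyme, max_missed = 2L, min_len = 7L,
                   max_len = NULL) {
  specs <- resolve_enzymes(enzyme)
  res <- strsplit(sequence, "")[[1L]]
  n <- length(res)
  sites <- logical(max(n - 1L, 0L))
  for (sp in specs) {
    if (sp$terminus == "C") {
      hit <- res[-n] %in% sp$cleave_residues
      if (sp$blocked_by_proline) hit <- hit & res[-1L] != "P"
    } else {
      hit <- res[-1L] %in% sp$cleave_residues
    }
    sites <- sites | hit
  }
  bounds <- c(0L, which(sites), n)
  nb <- length(bounds)
  out_pep <- character(); out_mis <- integer()
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + max_missed)) {
      L <- bounds[j] - bounds[i]
      if (L < min_len) next
      if (!is.null(max_len) && L > max_len) next
      out_pep <- c(out_pep, substr(sequence, bounds[i] + 1L, bounds[j]))
      out_mis <- c(out_mis, j - i - 1L)
    }
  }
  if (!length(out_pep))
    return(data.table::data.table(peptide = character(), missed = integer()))
  dt <- data.table::data.table(peptide = out_pep, missed = out_mis)
  dt[, .(missed = min(missed)), by = peptide]
}

resolve_enzymes <- function(enzyme) {
  if (inherits(enzyme, "enzyme_spec")) return(list(enzyme))
  if (is.character(enzyme)) {
    sp <- enzyme_spec(enzyme)
    return(if (inherits(sp, "enzyme_spec")) list(sp) else sp)
  }
  out <- list()
  for (e in enzyme) out <- c(out, resolve_enzymes(e))
  out
}

#' Collapse isoleucine to leucine
#'
#' I and L are mass-indistinguishable in standard MS; peptide novelty is
#' assessed on the collapsed alphabet by default.
#' @param peptides Character vector.
#' @export
collapse_il <- function(peptides) chartr("I", "L", peptides)

#' Build the peptide uniqueness index
#'
#' Digests every target entry with every enzyme scheme, unions the peptides,
#' and maps each peptide to its target parents. Uniqueness is `unique_novel`
#' (only novel parents), `unique_reference` (only reference parents) or
#' `shared`. With `il_collapse = TRUE` (default) a peptide is demoted from
#' `unique_novel` to `shared` when an I<->L variant of it occurs in a
#' reference protein. Decoy entries are never digested or listed as parents.
#'
#' @param db A [build_hybrid_db()] result (with or without decoys).
#' @param enzymes List of enzyme names/specs (each element one scheme).
#' @param max_missed,min_len,max_len Digestion parameters.
#' @param il_collapse Apply I/L equivalence to the novelty call.
#' @return data.table of class `peptide_index`: peptide, parents (list),
#'   uniqueness, missed.
#' @export
build_peptide_index <- function(db, enzymes = list("stricttrypsin",
                                                   "chymotrypsin", "aspn+lysc"),
                                max_missed = 2L, min_len = 7L, max_len = NULL,
                                il_collapse = TRUE) {
  targets <- db[decoy == FALSE]
  pieces <- vector("list", nrow(targets) * length(enzymes))
  k <- 0L
  for (i in seq_len(nrow(targets))) {
    for (enz in enzymes) {
      k <- k + 1L
      dg <- digest(targets$sequence[i], enz, max_missed = max_missed,
                   min_len = min_len, max_len = max_len)
      if (nrow(dg))
        pieces[[k]] <- dg[, .(peptide, missed, accession = targets$accession[i],
                              origin = targets$origin[i])]
    }
  }
  long <- data.table::rbindlist(pieces[!vapply(pieces, is.null, logical(1))])
  idx <- long[, .(parents = list(sort(unique(accession))),
                  missed = min(missed),
                  n_novel = sum(origin == "novel"),
                  n_ref = sum(origin == "reference")), by = peptide]
  idx[, uniqueness := data.table::fifelse(
    n_ref > 0L & n_novel > 0L, "shared",
    data.table::fifelse(n_novel > 0L, "unique_novel", "unique_reference"))]
  if (il_collapse) {
    ref_collapsed <- unique(collapse_il(long[origin == "reference", peptide]))
    demote <- idx$uniqueness == "unique_novel" &
      collapse_il(idx$peptide) %in% ref_collapsed
    idx[demote, uniqueness := "shared"]
  }
  idx[, c("n_novel", "n_ref") := NULL]
  data.table::setattr(idx, "class", c("peptide_index", class(idx)))
  idx[]
}

#' Write a hybrid database as FASTA
#' @param db A `hybrid_db`.
#' @param path Output path.
#' @export
write_db_fasta <- function(db, path) {
  seqs <- db$sequence
  names(seqs) <- db$accession
  write_fasta(seqs, path)
}
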