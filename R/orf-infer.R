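# Deterministic ORF calling on spliced transcript sequences, genomic CDS
# projection, UTR annotation and NMD/truncation filtering.
#
# The caller scans the three forward frames for ATG..stop runs and keeps the
# longest ORF (ties: 5'-most start). This replaces trained coding-potential
# models with a rule that is exact, testable and sufficient for the worked
# cases downstream.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a nucleotide string (frame 0)
#'
#' Codons containing N translate to `X`; translation does not stop at stop
#' codons (they appear as `*`). Trailing partial codons are dropped.
#'
#' @param seq ACGTN string whose length need not be a multiple of 3.
#' @export
translate_nt <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (!n) return("")
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Find the best open reading frame in a transcript sequence
#'
#' Scans the three forward frames for ATG-initiated ORFs. An ORF reaching an
#' in-frame stop codon is "closed" (the returned interval includes the stop
#' codon); an ATG run hitting the transcript end first is "open"
#' (`has_stop = FALSE`). The best ORF is the longest closed ORF with protein
#' length >= `min_aa`; if none exists, the longest candidate of any kind is
#' returned so downstream filtering can label it truncated/unlikely. Ties are
#' broken by the 5'-most start.
#'
#' @param sequence Nucleotide string over ACGTN.
#' @param min_aa Minimum protein length (aa) for a qualifying ORF.
#' @return A list of class `open_reading_frame` (fields `tx_start`, `tx_end`,
#'   `protein`, `has_stop`) or `NULL` when the sequence has no ATG.
#' @export
find_best_orf <- function(sequence, min_aa = 25L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 3L) return(NULL)
  starts <- gregexpr("(?=ATG)", sequence, perl = TRUE)[[1L]]
  if (starts[1L] == -1L) return(NULL)
  starts <- as.integer(starts) - 1L            # 0-based
  # stop codon start positions per frame (0-based)
  stop_pos <- sort(unlist(lapply(STOP_CODONS, function(sc) {
    p <- gregexpr(paste0("(?=", sc, ")"), sequence, perl = TRUE)[[1L]]
    if (p[1L] == -1L) integer() else as.integer(p) - 1L
  })))
  cand <- lapply(starts, function(p) {
    fr_stops <- stop_pos[stop_pos > p & (stop_pos - p) %% 3L == 0L]
    if (length(fr_stops)) {
      sp <- fr_stops[1L]
      list(tx_start = p, tx_end = sp + 3L, has_stop = TRUE,
           aa_len = (sp - p) %/% 3L)
    } else {
      aa_len <- (n - p) %/% 3L - 0L
      list(tx_start = p, tx_end = p + 3L * aa_len, has_stop = FALSE,
           aa_len = aa_len)
    }
  })
  qual <- vapply(cand, function(o) o$has_stop && o$aa_len >= min_aa, logical(1))
  pool <- if (any(qual)) cand[qual] else cand
  lens <- vapply(pool, `[[`, numeric(1), "aa_len")
  best <- pool[[which.max(lens)]]          # which.max returns first (5'-most)
  if (best$aa_len < 1L) return(NULL)
  prot <- translate_nt(substr(sequence, best$tx_start + 1L,
                              best$tx_start + 3L * best$aa_len))
  structure(list(transcript_id = NA_character_, tx_start = best$tx_start,
                 tx_end = best$tx_end, protein = prot,
                 has_stop = best$has_stop, cds_blocks = NULL,
                 start_codon_genomic = NA_integer_,
                 stop_codon_genomic = NA_integer_,
                 stop_to_last_junction = NA_integer_, nmd_flag = NA,
                 status = NA_character_),
            class = "open_reading_frame")
}

#' @export
print.open_reading_frame <- function(x, ...) {
  cat(sprintf("<ORF> tx %s [%d,%d) %d aa%s status=%s\n",
              x$transcript_id, x$tx_start, x$tx_end, nchar(x$protein),
              if (isTRUE(x$has_stop)) " (stop)" else " (no stop)",
              x$status))
  invisible(x)
}

#' Map a transcript-coordinate interval to genomic blocks
#'
#' Strand-aware: transcript position 0 is the 5' end. The returned blocks
#' are in ascending genomic order and their lengths sum to `e - s`.
#'
#' @param tx A [transcript_model()].
#' @param s,e Transcript coordinates, 0-based half-open.
#' @return data.frame of genomic blocks (`start`, `end`).
#' @export
tx_interval_to_genomic <- function(tx, s, e) {
  len <- tx_length(tx)
  if (s < 0L || e > len || s >= e) stop("interval outside transcript")
  ex <- tx$exons
  ord <- if (tx$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  off <- 0L
  blocks <- list()
  for (i in ord) {
    L <- ex$end[i] - ex$start[i]
    a <- max(s, off); b <- min(e, off + L)
    if (a < b) {
      if (tx$strand == "+") {
        blocks[[length(blocks) + 1L]] <- c(ex$start[i] + (a - off),
                                           ex$start[i] + (b - off))
      } else {
        blocks[[length(blocks) + 1L]] <- c(ex$end[i] - (b - off),
                                           ex$end[i] - (a - off))
      }
    }
    off <- off + L
  }
  m <- do.call(rbind, blocks)
  df <- data.frame(start = m[, 1L], end = m[, 2L])
  df[order(df$start), , drop = FALSE]
}

#' Map a genomic CDS block set back to transcript coordinates
#'
#' Inverse of [tx_interval_to_genomic()]; used as a projection sanity check.
#' @inheritParams tx_interval_to_genomic
#' @param blocks data.frame of genomic blocks.
#' @return c(tx_start, tx_end).
#' @export
genomic_blocks_to_tx <- function(tx, blocks) {
  ex <- tx$exons
  ord <- if (tx$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  off <- 0L
  pos <- integer()
  for (i in ord) {
    L <- ex$end[i] - ex$start[i]
    for (j in seq_len(nrow(blocks))) {
      bs <- blocks$start[j]; be <- blocks$end[j]
      if (bs >= ex$start[i] && be <= ex$end[i]) {
        if (tx$strand == "+") {
          pos <- c(pos, off + (bs - ex$start[i]), off + (be - ex$start[i]))
        } else {
          pos <- c(pos, off + (ex$end[i] - be), off + (ex$end[i] - bs))
        }
      }
    }
    off <- off + L
  }
  c(min(pos), max(pos))
}

#' Project an ORF's CDS to the genome
#'
#' Fills `cds_blocks` (ascending genomic blocks whose lengths sum to
#' `tx_end - tx_start`) and the genomic positions of the translation start
#' (first base of the start codon) and termination (last base of the stop
#' codon, or of the last complete codon for open ORFs), both in
#' transcription order.
#'
#' @param orf An `open_reading_frame`.
#' @param tx The [transcript_model()] it was called on.
#' @return The ORF with projection fields set.
#' @export
project_cds <- function(orf, tx) {
  blocks <- tx_interval_to_genomic(tx, orf$tx_start, orf$tx_end)
  orf$cds_blocks <- blocks
  orf$transcript_id <- tx$transcript_id
  tx_pos_genomic <- function(p) {
    b <- tx_interval_to_genomic(tx, p, p + 1L)
    b$start[1L]
  }
  orf$start_codon_genomic <- tx_pos_genomic(orf$tx_start)
  orf$stop_codon_genomic <- tx_pos_genomic(orf$tx_end - 1L)
  orf
}

#' Annotate UTRs
#'
#' Exonic regions upstream of the start codon become the 5' UTR, regions
#' downstream of the stop the 3' UTR, as genomic blocks.
#'
#' @inheritParams project_cds
#' @return list(five_prime_utr, three_prime_utr) of genomic block
#'   data.frames (possibly 0-row).
#' @export
annotate_utrs <- function(tx, orf) {
  len <- tx_length(tx)
  empty <- data.frame(start = integer(), end = integer())
  five <- if (orf$tx_start > 0L) tx_interval_to_genomic(tx, 0L, orf$tx_start) else empty
  three <- if (orf$tx_end < len) tx_interval_to_genomic(tx, orf$tx_end, len) else empty
  list(five_prime_utr = five, three_prime_utr = three)
}

#' Nonsense-mediated decay flag (50-nt rule)
#'
#' A closed ORF on a multi-exon transcript is flagged as a predicted NMD
#' substrate when its stop codon lies more than `rule_nt` nucleotides
#' upstream of the last exon-exon junction in transcript coordinates
#' (distance measured from the end of the stop codon). Mono-exon transcripts
#' are never flagged.
#'
#' @inheritParams project_cds
#' @param rule_nt The rule threshold in nucleotides (default 50).
#' @return TRUE/FALSE.
#' @export
flag_nmd <- function(orf, tx, rule_nt = 50L) {
  if (nrow(tx$exons) < 2L || !isTRUE(orf$has_stop)) return(FALSE)
  last_ex <- if (tx$strand == "+") nrow(tx$exons) else 1L
  last_len <- tx$exons$end[last_ex] - tx$exons$start[last_ex]
  junction_pos <- tx_length(tx) - last_len
  (junction_pos - orf$tx_end) > rule_nt
}

stop_to_last_junction <- function(orf, tx) {
  if (nrow(tx$exons) < 2L) return(NA_integer_)
  last_ex <- if (tx$strand == "+") nrow(tx$exons) else 1L
  last_len <- tx$exons$end[last_ex] - tx$exons$start[last_ex]
  as.integer(tx_length(tx) - last_len - orf$tx_end)
}

#' Filter called ORFs
#'
#' Sets status: `truncated` when the ORF has no stop codon within the
#' transcript, `nmd` when the 50-nt rule fires, `unlikely` when the protein
#' is shorter than `min_aa`, `retained` otherwise. Only retained ORFs go
#' into the search database.
#'
#' @param orfs Named list of projected `open_reading_frame`s.
#' @param txs Named list of the matching [transcript_model()]s.
#' @param min_aa Minimum protein length.
#' @param rule_nt NMD rule threshold.
#' @return The list with `status`, `nmd_flag`, `stop_to_last_junction` set.
#' @export
filter_orfs <- function(orfs, txs, min_aa = 25L, rule_nt = 50L) {
  for (id in names(orfs)) {
    orf <- orfs[[id]]
    tx <- txs[[id]]
    orf$nmd_flag <- flag_nmd(orf, tx, rule_nt)
    orf$stop_to_last_junction <- stop_to_last_junction(orf, tx)
    orf$status <- if (!isTRUE(orf$has_stop)) "truncated"
                  else if (orf$nmd_flag) "nmd"
                  else if (nchar(orf$protein) < min_aa) "unlikely"
                  else "retained"
    orfs[[id]] <- orf
  }
  orfs
}

#' Call, project and filter ORFs for a catalog
#'
#' @param catalog A [gene_catalog()].
#' @param genome Named chromosome sequence vector.
#' @param min_aa Minimum protein length (default 25 aa).
#' @param rule_nt NMD rule threshold (default 50 nt).
#' @return list(orfs = named list of `open_reading_frame`s,
#'   table = data.table summary with one row per transcript).
#' @export
call_orfs <- function(catalog, genome, min_aa = 25L, rule_nt = 50L) {
  orfs <- list()
  for (tx in catalog$transcripts) {
    orf <- find_best_orf(spliced_sequence(tx, genome), min_aa = min_aa)
    if (is.null(orf)) next
    orfs[[tx$transcript_id]] <- project_cds(orf, tx)
  }
  orfs <- filter_orfs(orfs, catalog$transcripts, min_aa = min_aa,
                      rule_nt = rule_nt)
  tab <- data.table::rbindlist(lapply(orfs, function(o) data.table::data.table(
    transcript_id = o$transcript_id, tx_start = o$tx_start, tx_end = o$tx_end,
    protein_length = nchar(o$protein), has_stop = o$has_stop,
    nmd_flag = o$nmd_flag, status = o$status)))
  list(orfs = orfs, table = tab)
}
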