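# A deterministic synthetic construction of a classic proteogenomic
# frameshift case: a reference-annotated 17-nt exon newly combined before
# the last exon of an otherwise reference-matching transcript. Because
# 17 is not a multiple of 3, the inclusion shifts the reading frame of the
# last exon, producing an alternative C-terminus detectable by a peptide
# unique to the novel ORF.
#
# The three isoforms read the last exon in three different frames (the
# internal exons sum to 1 mod 3, the cassette adds 2 mod 3), so the novel
# C-terminal peptide cannot occur in either reference protein. The last-exon
# sequence is found by a seeded constraint search; the resulting fixture is
# fixed and synthetic.

#' Synthetic 17-nt-exon frameshift case
#'
#' Builds a one-gene genome with reference isoforms R1 (full chain
#' e1-e2-e3-e4) and R2 (e1-X17-e4, annotating the 17-nt cassette exon X17)
#' plus the query Q (e1-e2-e3-X17-e4). Q combines only known splice sites in
#' a new order (NIC), its ORF is frameshifted downstream of X17, and its
#' C-terminal tryptic peptide occurs in neither reference protein.
#'
#' @param seed Seed for the constraint search (default 7).
#' @param min_aa Minimum protein length used by the ORF caller.
#' @return list: genome, ref_catalog, query_catalog, insertion_aa (0-based
#'   protein position where Q diverges from R1), unique_peptide (a
#'   C-terminal tryptic peptide unique to Q's ORF).
#' @export
frameshift_case <- function(seed = 7L, min_aa = 25L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  assemble <- function(e1, e2, e3, x17, e4) {
    introns <- list(intron_nt(150L), intron_nt(150L), intron_nt(120L),
                    intron_nt(120L))
    locus <- paste0(e1, introns[[1L]], e2, introns[[2L]], e3, introns[[3L]],
                    x17, introns[[4L]], e4)
    offs <- cumsum(c(0L, nchar(e1), 150L, nchar(e2), 150L, nchar(e3), 120L,
                     17L, 120L))
    names(offs) <- c("e1", "i1", "e2", "i2", "e3", "i3", "x17", "i4", "e4")
    genome <- c(chrFS = paste0(strrep("A", 100L), locus, strrep("A", 100L)))
    coord <- function(nm, len) c(100L + offs[[nm]], 100L + offs[[nm]] + len)
    blocks <- list(e1 = coord("e1", nchar(e1)), e2 = coord("e2", nchar(e2)),
                   e3 = coord("e3", nchar(e3)), x17 = coord("x17", 17L),
                   e4 = coord("e4", nchar(e4)))
    mk <- function(id, parts) {
      b <- do.call(rbind, blocks[parts])
      transcript_model(id, "GENEFS", "chrFS", "+",
                       data.frame(start = b[, 1L], end = b[, 2L]))
    }
    list(genome = genome,
         r1 = mk("GENEFS.R1", c("e1", "e2", "e3", "e4")),
         r2 = mk("GENEFS.R2", c("e1", "x17", "e4")),
         q = mk("GENEFS.Q", c("e1", "e2", "e3", "x17", "e4")))
  }

  for (attempt in 1:5000) {
    e1 <- paste0(utr_nt(12L), "ATG", codon_run(29L))   # 12 + 90
    e2 <- codon_run(30L)                               # 90
    e3 <- paste0(codon_run(30L), "A")                  # 91 -> e2+e3 = 1 mod 3
    x17 <- substr(codon_run(6L), 1L, 17L)              # 17 nt cassette
    e4 <- random_nt(240L)
    cs <- assemble(e1, e2, e3, x17, e4)
    orf_of <- function(tx) {
      o <- find_best_orf(spliced_sequence(tx, cs$genome), min_aa = min_aa)
      if (is.null(o)) return(NULL)
      project_cds(o, tx)
    }
    o1 <- orf_of(cs$r1); o2 <- orf_of(cs$r2); oq <- orf_of(cs$q)
    if (is.null(o1) || is.null(o2) || is.null(oq)) next
    if (!(o1$has_stop && o2$has_stop && oq$has_stop)) next
    if (o1$tx_start != 12L || oq$tx_start != 12L) next
    # stops must land in the last exon (no NMD), and Q's ORF must extend
    # into the frameshifted region
    len_before_e4 <- function(tx) tx_length(tx) -
      (tx$exons$end[nrow(tx$exons)] - tx$exons$start[nrow(tx$exons)])
    if (o1$tx_end <= len_before_e4(cs$r1)) next
    if (oq$tx_end <= len_before_e4(cs$q) + 30L) next
    if (flag_nmd(oq, cs$q) || flag_nmd(o1, cs$r1)) next
    # frameshift: shared prefix up to the insertion, divergent suffix
    ins_aa <- (90L + 90L + 91L - 3L) %/% 3L            # codons before X17
    if (nchar(oq$protein) < ins_aa + 12L) next
    if (substr(oq$protein, 1L, ins_aa) != substr(o1$protein, 1L, ins_aa)) next
    suffix_q <- substr(oq$protein, ins_aa + 1L, nchar(oq$protein))
    if (substr(o1$protein, ins_aa + 1L, nchar(o1$protein)) == suffix_q) next
    # a C-terminal tryptic peptide unique to Q
    dg <- digest(oq$protein, "trypsin", max_missed = 0L, min_len = 7L)
    if (!nrow(dg)) next
    ends_at <- vapply(dg$peptide, function(p) {
      h <- gregexpr(p, oq$protein, fixed = TRUE)[[1L]]
      any(h + nchar(p) - 1L == nchar(oq$protein))
    }, logical(1))
    cterm <- dg$peptide[ends_at]
    uniq <- cterm[!vapply(cterm, function(p) {
      pc <- collapse_il(p)
      grepl(pc, collapse_il(o1$protein), fixed = TRUE) ||
        grepl(pc, collapse_il(o2$protein), fixed = TRUE)
    }, logical(1))]
    if (!length(uniq)) next

    attach_cds <- function(tx, o) { tx$cds <- o$cds_blocks; tx }
    ref_catalog <- gene_catalog(list(attach_cds(cs$r1, o1),
                                     attach_cds(cs$r2, o2)),
                                source_tag = "frameshift_reference")
    query_catalog <- gene_catalog(list(cs$q), source_tag = "frameshift_query")
    return(list(genome = cs$genome, ref_catalog = ref_catalog,
                query_catalog = query_catalog, insertion_aa = ins_aa,
                unique_peptide = uniq[[1L]],
                proteins = c(GENEFS.R1 = o1$protein, GENEFS.R2 = o2$protein),
                query_orf = oq))
  }
  stop("frameshift construction search failed")
}
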