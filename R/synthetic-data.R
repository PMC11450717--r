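# Seeded synthetic-data generator: toy genomes, multi-isoform reference
# catalogs, query transcripts with planted structural events, expression
# counts and peptide-spectrum matches, each with machine-readable ground
# truth. The generator is first-class code: every pipeline stage is tested
# against what it plants.
#
# Construction guarantees that make planted labels unambiguous:
#  * reference isoforms of a gene are the full exon chain ("master") plus
#    5'-truncated chains, so reference intron intervals are disjoint except
#    around designated cassette exons;
#  * internal exon lengths are multiples of 3 and every exon starts with an
#    in-frame ATG, so every reference isoform carries a valid ORF and
#    exon-skipping preserves the reading frame;
#  * planted novel splice sites are checked against the whole gene's site
#    sets before acceptance, and ambiguous draws are resampled.

CODONS_NO_STOP <- setdiff(names(Biostrings::GENETIC_CODE),
                          c("TAA", "TAG", "TGA"))

#' Synthetic study configuration
#'
#' Defaults describe the desk-scale emulation of a three-replicate long-read
#' + proteomics study: a two-chromosome toy genome, multi-isoform protein
#' coding genes, a novel-isoform event mix dominated by end variation,
#' intron retention and alternative poly(A) (the most common events in real
#' long-read catalogs), log-normal expression over three samples, and PSMs
#' sampled from digests of the expressed ORFs.
#'
#' @param seed Master seed; stage seeds are derived from it by fixed offsets.
#' @param n_chroms,n_genes Genome shape.
#' @param isoforms_per_gene Range of reference isoforms per gene.
#' @param n_exons Range of exons of the master isoform (>= 4).
#' @param exon_codons Range of internal-exon length in codons.
#' @param intron_length,gene_gap Intron length range and intergenic gap (bp).
#' @param utr5_length,utr3_length UTR length ranges (bp).
#' @param cassette_gene_fraction Fraction of genes that additionally annotate
#'   a short in-frame cassette exon in a secondary isoform.
#' @param novel_event_mix Named proportions over the planted event types
#'   (must sum to 1).
#' @param n_novel Number of novel isoforms to plant.
#' @param n_samples,depth Expression sampling: samples and reads per sample.
#' @param expression_meanlog,expression_sdlog Log-normal abundance parameters.
#' @param n_dominant_novel Genes forced to have a novel-ORF dominant isoform.
#' @param psm PSM simulation knobs: peptides_per_orf, n_reference_proteins,
#'   noise_peptide_rate, decoy_hit_rate, peak_noise_rate, true_prob,
#'   false_prob ranges.
#' @param min_aa Minimum protein length used throughout.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, n_genes = 20L,
                       isoforms_per_gene = c(1L, 3L), n_exons = c(4L, 8L),
                       exon_codons = c(25L, 60L),
                       intron_length = c(200L, 600L), gene_gap = 2000L,
                       utr5_length = c(20L, 60L), utr3_length = c(60L, 120L),
                       cassette_gene_fraction = 0.25,
                       novel_event_mix = c(fsm_end_variation = 0.20,
                                           exon_skip_nic = 0.10,
                                           known_site_recombination_nic = 0.10,
                                           novel_site_nnic = 0.15,
                                           intron_retention = 0.15,
                                           terminal_elongation = 0.10,
                                           alt_polyA = 0.15,
                                           novel_exon = 0.05),
                       n_novel = 40L, n_samples = 3L, depth = 50000L,
                       expression_meanlog = 3, expression_sdlog = 1.2,
                       n_dominant_novel = 3L,
                       psm = list(peptides_per_orf = 3L,
                                  n_reference_proteins = 30L,
                                  noise_peptide_rate = 0, decoy_hit_rate = 0,
                                  peak_noise_rate = 0,
                                  true_prob = c(0.96, 0.999),
                                  false_prob = c(0.2, 0.9)),
                       min_aa = 25L) {
  if (abs(sum(novel_event_mix) - 1) > 1e-9)
    stop("novel_event_mix proportions must sum to 1")
  if (n_exons[1L] < 4L) stop("master isoforms need at least 4 exons")
  structure(as.list(environment()), class = "sim_config")
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

utr_nt <- function(n) {
  repeat {
    s <- random_nt(n)
    if (!grepl("ATG", s, fixed = TRUE)) return(s)
  }
}

codon_run <- function(n_codons, first_atg = FALSE) {
  cods <- sample(CODONS_NO_STOP, n_codons, TRUE)
  if (first_atg && n_codons > 0L) cods[1L] <- "ATG"
  paste(cods, collapse = "")
}

intron_nt <- function(n) paste0("GT", random_nt(n - 4L), "AG")

## Build one gene in transcription space, then place it on the genome.
build_gene <- function(gene_id, chrom, strand, cassette, cfg) {
  n_ex <- sample(cfg$n_exons[1L]:cfg$n_exons[2L], 1L)
  u5 <- sample(cfg$utr5_length[1L]:cfg$utr5_length[2L], 1L)
  u3 <- sample(cfg$utr3_length[1L]:cfg$utr3_length[2L], 1L)
  c1 <- 3L * sample(10L:30L, 1L)
  internal <- 3L * sample(cfg$exon_codons[1L]:cfg$exon_codons[2L],
                          n_ex - 2L, TRUE)
  ctail <- 3L * sample(30L:60L, 1L)

  exon_seq <- vector("list", n_ex)
  exon_seq[[1L]] <- paste0(utr_nt(u5), "ATG", codon_run(c1 %/% 3L - 1L))
  for (i in seq_len(n_ex - 2L))
    exon_seq[[i + 1L]] <- codon_run(internal[i] %/% 3L, first_atg = TRUE)
  exon_seq[[n_ex]] <- paste0(codon_run(ctail %/% 3L, first_atg = TRUE),
                             "TAA", utr_nt(u3))

  intr_len <- sample(cfg$intron_length[1L]:cfg$intron_length[2L], n_ex - 1L, TRUE)
  intron_seq <- lapply(intr_len, intron_nt)
  cassette_seq <- NULL
  if (cassette) {
    # host the cassette exon inside the intron before the last exon
    k <- n_ex - 1L
    sub <- sample(cfg$intron_length[1L]:cfg$intron_length[2L], 2L, TRUE)
    cassette_seq <- codon_run(6L)                      # 18 nt, in frame
    intron_seq[[k]] <- list(intron_nt(sub[1L]), intron_nt(sub[2L]))
    intr_len[k] <- sub[1L] + 18L + sub[2L]
  }

  # transcription-space offsets
  pieces <- character()
  exon_off <- integer(n_ex)
  cassette_off <- NA_integer_
  off <- 0L
  for (i in seq_len(n_ex)) {
    exon_off[i] <- off
    pieces <- c(pieces, exon_seq[[i]])
    off <- off + nchar(exon_seq[[i]])
    if (i < n_ex) {
      iseq <- intron_seq[[i]]
      if (is.list(iseq)) {
        pieces <- c(pieces, iseq[[1L]])
        off <- off + nchar(iseq[[1L]])
        cassette_off <- off
        pieces <- c(pieces, cassette_seq)
        off <- off + 18L
        pieces <- c(pieces, iseq[[2L]])
        off <- off + nchar(iseq[[2L]])
      } else {
        pieces <- c(pieces, iseq)
        off <- off + nchar(iseq)
      }
    }
  }
  locus <- paste(pieces, collapse = "")
  list(gene_id = gene_id, chrom = chrom, strand = strand, locus = locus,
       n_ex = n_ex, exon_off = exon_off,
       exon_len = vapply(exon_seq, nchar, integer(1)),
       cassette_off = cassette_off, cassette = cassette)
}

## transcription-space offsets -> ascending genomic intervals
place_blocks <- function(offs, lens, strand, locus_start, locus_len) {
  if (strand == "+") {
    df <- data.frame(start = locus_start + offs, end = locus_start + offs + lens)
  } else {
    df <- data.frame(start = locus_start + locus_len - offs - lens,
                     end = locus_start + locus_len - offs)
  }
  df[order(df$start), , drop = FALSE]
}

#' Simulate the reference genome and catalog
#'
#' Genes carry 1..k isoforms: the full exon chain plus 5'-truncated chains
#' starting at internal exons; designated cassette genes additionally
#' annotate a short in-frame cassette exon in a secondary isoform (first
#' exon + cassette + last exon). All introns are GT..AG, every isoform's
#' longest ORF is validated (ATG..stop, >= min_aa) and annotated as its CDS.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return list of class `sim_reference`: genome (named chromosome
#'   sequences), catalog ([gene_catalog()] with CDS), proteins (named by
#'   transcript_id), genes (per-gene construction metadata for planting).
#' @export
simulate_reference <- function(config) {
  cfg <- config
  set.seed(cfg$seed + 1L)
  per_chrom <- split(seq_len(cfg$n_genes),
                     rep(seq_len(cfg$n_chroms), length.out = cfg$n_genes))
  n_cassette <- max(1L, round(cfg$cassette_gene_fraction * cfg$n_genes))
  cassette_genes <- sort(sample(cfg$n_genes, n_cassette))

  genome <- character(cfg$n_chroms)
  names(genome) <- paste0("chr", seq_len(cfg$n_chroms))
  transcripts <- list()
  proteins <- character()
  gene_meta <- list()

  for (ci in seq_len(cfg$n_chroms)) {
    chrom <- names(genome)[ci]
    pieces <- character()
    cursor <- 0L
    for (gi in per_chrom[[ci]]) {
      gene_id <- sprintf("GENE%04d", gi)
      strand <- sample(c("+", "-"), 1L)
      ok <- FALSE
      locus_start <- cursor + cfg$gene_gap
      for (try in 1:25) {
        g <- build_gene(gene_id, chrom, strand, gi %in% cassette_genes, cfg)
        locus_len <- nchar(g$locus)
        # validate in locus-local coordinates, shift on success
        exons <- place_blocks(g$exon_off, g$exon_len, strand, 0L, locus_len)
        k <- sample(cfg$isoforms_per_gene[1L]:cfg$isoforms_per_gene[2L], 1L)
        iso_exons <- list(exons)                       # master
        trunc_from <- if (g$n_ex >= 5L) sample(2L:(g$n_ex - 2L)) else 2L
        trunc_from <- utils::head(trunc_from, k - 1L)
        for (j in trunc_from) {
          rows <- if (strand == "+") j:g$n_ex else 1L:(g$n_ex - j + 1L)
          iso_exons[[length(iso_exons) + 1L]] <- exons[rows, , drop = FALSE]
        }
        cassette_block <- NULL
        if (g$cassette) {
          cassette_block <- place_blocks(g$cassette_off, 18L, strand, 0L,
                                         locus_len)
          first_last <- exons[c(if (strand == "+") 1L else g$n_ex,
                                if (strand == "+") g$n_ex else 1L), ]
          cas_iso <- rbind(first_last, cassette_block)
          iso_exons[[length(iso_exons) + 1L]] <- cas_iso[order(cas_iso$start), ]
        }
        genomic_locus <- if (strand == "-") revcomp(g$locus) else g$locus
        local_genome <- stats::setNames(genomic_locus, chrom)
        models <- vector("list", length(iso_exons))
        valid <- TRUE
        for (m in seq_along(iso_exons)) {
          txid <- sprintf("%s.T%d", gene_id, m)
          tx <- transcript_model(txid, gene_id, chrom, strand, iso_exons[[m]])
          orf <- find_best_orf(spliced_sequence(tx, local_genome),
                               min_aa = cfg$min_aa)
          if (is.null(orf) || !orf$has_stop || nchar(orf$protein) < cfg$min_aa ||
              grepl("*", orf$protein, fixed = TRUE) ||
              grepl("X", orf$protein, fixed = TRUE)) {
            valid <- FALSE
            break
          }
          orf <- project_cds(orf, tx)
          tx$cds <- orf$cds_blocks
          models[[m]] <- list(tx = tx, protein = orf$protein)
        }
        if (valid) { ok <- TRUE; break }
      }
      if (!ok) stop("could not build a valid gene for ", gene_id)
      shift <- function(df) data.frame(start = df$start + locus_start,
                                       end = df$end + locus_start)
      for (m in models) {
        tx <- m$tx
        tx$exons <- shift(tx$exons)
        tx$cds <- shift(tx$cds)
        transcripts[[tx$transcript_id]] <- tx
        proteins[tx$transcript_id] <- m$protein
      }
      gene_meta[[gene_id]] <- list(
        gene_id = gene_id, chrom = chrom, strand = strand,
        master = transcripts[[sprintf("%s.T1", gene_id)]]$exons,
        n_ex = g$n_ex, cassette = g$cassette,
        cassette_block = if (is.null(cassette_block)) NULL else shift(cassette_block))
      pieces <- c(pieces, strrep("N", cfg$gene_gap), genomic_locus)
      cursor <- cursor + cfg$gene_gap + locus_len
    }
    pieces <- c(pieces, strrep("N", cfg$gene_gap))
    genome[chrom] <- paste(pieces, collapse = "")
  }
  # Ns only fill intergenic gaps; replace them with random background so the
  # genome is plain ACGT (exon/intron sequence is already placed)
  genome <- vapply(genome, function(s) {
    n_pos <- gregexpr("N+", s)[[1L]]
    if (n_pos[1L] == -1L) return(s)
    lens <- attr(n_pos, "match.length")
    for (i in rev(seq_along(n_pos)))
      substr(s, n_pos[i], n_pos[i] + lens[i] - 1L) <- random_nt(lens[i])
    s
  }, character(1))

  structure(list(genome = genome,
                 catalog = gene_catalog(transcripts, source_tag = "synthetic_reference"),
                 proteins = proteins, genes = gene_meta, config = cfg),
            class = "sim_reference")
}

## ---- planting -------------------------------------------------------------

# expected subcategory sets, given the construction guarantees
EVENT_TRUTH <- list(
  fsm_end_variation = list(category = "FSM"),
  exon_skip_nic = list(category = "NIC", subcats = "alternative_structure"),
  known_site_recombination_nic = list(category = "NIC",
                                      subcats = "alternative_structure"),
  novel_site_nnic = list(category = "NNIC", subcats = "intron_shift"),
  intron_retention = list(category = "NIC", subcats = "intron_retention"),
  terminal_elongation = list(category = "NIC", subcats = "exon_elongation"),
  alt_polyA = list(category = "NIC", subcats = "alt_polyA"),
  novel_exon = list(category = "NNIC",
                    subcats = c("intron_shift", "novel_exon")))

# transcription-order helpers on ascending genomic exon tables
last_row <- function(exons, strand) if (strand == "+") nrow(exons) else 1L
first_row <- function(exons, strand) if (strand == "+") 1L else nrow(exons)

#' Plant novel isoforms with ground truth
#'
#' Draws `config$n_novel` events from `config$novel_event_mix` and applies
#' each to a randomly chosen suitable gene so that the intended label is
#' unambiguous under the classifier's documented rules. Draws whose novel
#' sites would collide with annotated sites are rejected and resampled.
#'
#' @param reference A [simulate_reference()] result.
#' @param config The same [sim_config()].
#' @return list: catalog (query [gene_catalog()]), truth (data.table:
#'   transcript_id, source_gene, event, true_category, true_subcategories).
#' @export
plant_novel_isoforms <- function(reference, config) {
  cfg <- config
  set.seed(cfg$seed + 2L)
  meta <- reference$genes
  gene_ids <- names(meta)
  cassette_ids <- gene_ids[vapply(meta, `[[`, logical(1), "cassette")]
  plain_ids <- setdiff(gene_ids, cassette_ids)
  # annotated intron chains per gene: a planted "novel" chain must not
  # coincide with one of these (e.g. retaining intron 1 reproduces the
  # chain of a 5'-truncated reference isoform)
  gene_chains <- list()
  for (tx in reference$catalog$transcripts)
    gene_chains[[tx$gene_id]] <- c(gene_chains[[tx$gene_id]], chain_key(tx))

  transcripts <- list()
  truth <- list()
  events <- sample(names(cfg$novel_event_mix), cfg$n_novel, TRUE,
                   prob = cfg$novel_event_mix)

  for (i in seq_along(events)) {
    ev <- events[i]
    txid <- sprintf("NOVELTX%05d", i)
    made <- NULL
    for (attempt in 1:50) {
      g <- meta[[sample(switch(ev,
        known_site_recombination_nic = cassette_ids,
        novel_site_nnic = plain_ids,
        novel_exon = plain_ids,
        gene_ids), 1L)]]
      ex <- g$master
      s <- g$strand
      n <- nrow(ex)
      subcats <- EVENT_TRUTH[[ev]]$subcats
      if (ev == "fsm_end_variation") {
        delta <- sample(100:300, 1L)
        side <- sample(c("tss", "tes"), 1L)
        if ((side == "tes") == (s == "+")) ex$end[n] <- ex$end[n] + delta
        else ex$start[1L] <- max(0L, ex$start[1L] - delta)
        subcats <- if (side == "tes") "alt_polyA" else "alt_TSS"
      } else if (ev == "exon_skip_nic") {
        j <- sample(2:(n - 1L), 1L)
        ex <- ex[-j, , drop = FALSE]
      } else if (ev == "known_site_recombination_nic") {
        ex <- rbind(ex, g$cassette_block)
        ex <- ex[order(ex$start), , drop = FALSE]
      } else if (ev == "novel_site_nnic") {
        k <- sample(seq_len(n - 1L), 1L)
        if (s == "+") ex$end[k] <- ex$end[k] + 9L
        else ex$start[k + 1L] <- ex$start[k + 1L] - 9L
      } else if (ev == "intron_retention") {
        k <- sample(seq_len(n - 1L), 1L)
        if (g$cassette && k == (if (s == "+") n - 1L else 1L)) next
        ex$end[k] <- ex$end[k + 1L]
        ex <- ex[-(k + 1L), , drop = FALSE]
      } else if (ev == "terminal_elongation") {
        j <- sample(2:(n - 1L), 1L)
        ex <- ex[-j, , drop = FALSE]
        d <- sample(15:40, 1L)
        lr <- last_row(ex, s)
        if (s == "+") ex$end[lr] <- ex$end[lr] + d
        else ex$start[lr] <- ex$start[lr] - d
      } else if (ev == "alt_polyA") {
        j <- sample(2:(n - 1L), 1L)
        ex <- ex[-j, , drop = FALSE]
        lr <- last_row(ex, s)
        len_last <- ex$end[lr] - ex$start[lr]
        r <- sample(60:min(120L, len_last - 20L), 1L)
        if (s == "+") ex$end[lr] <- ex$end[lr] - r
        else ex$start[lr] <- ex$start[lr] + r
      } else if (ev == "novel_exon") {
        k <- sample(seq_len(n - 1L), 1L)
        istart <- ex$end[k]; iend <- ex$start[k + 1L]
        L <- sample(30:60, 1L)
        if (iend - istart < L + 80L) next
        o <- sample((istart + 40L):(iend - 40L - L), 1L)
        ex <- rbind(ex, data.frame(start = o, end = o + L))
        ex <- ex[order(ex$start), , drop = FALSE]
      }
      made <- transcript_model(txid, g$gene_id, g$chrom, s, ex)
      if (ev != "fsm_end_variation" &&
          chain_key(made) %in% gene_chains[[g$gene_id]]) {
        made <- NULL
        next
      }
      break
    }
    if (is.null(made)) stop("could not plant event ", ev)
    transcripts[[txid]] <- made
    truth[[i]] <- data.table::data.table(
      transcript_id = txid, source_gene = made$gene_id, event = ev,
      true_category = EVENT_TRUTH[[ev]]$category,
      true_subcategories = paste(sort(subcats), collapse = ","))
  }
  list(catalog = gene_catalog(transcripts, source_tag = "synthetic_query"),
       truth = data.table::rbindlist(truth))
}

## ---- expression -----------------------------------------------------------

#' Simulate full-length counts
#'
#' Independent log-normal abundances per transcript, multinomial read
#' sampling per sample. Transcripts named in `dominant` get an abundance of
#' 1.5x the rest of their gene so the novel isoform dominates.
#'
#' @param tx_gene data.frame: transcript_id, gene_id.
#' @param config A [sim_config()].
#' @param dominant Transcript ids to force dominant within their gene.
#' @return data.table: transcript_id + one count column per sample.
#' @export
simulate_expression <- function(tx_gene, config, dominant = character()) {
  cfg <- config
  set.seed(cfg$seed + 3L)
  tx_gene <- data.table::as.data.table(tx_gene)
  n <- nrow(tx_gene)
  ab <- stats::rlnorm(n, cfg$expression_meanlog, cfg$expression_sdlog)
  for (d in dominant) {
    di <- which(tx_gene$transcript_id == d)
    if (!length(di)) next
    same <- tx_gene$gene_id == tx_gene$gene_id[di]
    ab[di] <- 1.5 * sum(ab[same & tx_gene$transcript_id != d])
  }
  out <- data.table::data.table(transcript_id = tx_gene$transcript_id)
  for (si in seq_len(cfg$n_samples))
    out[[sprintf("sample%d", si)]] <-
      as.integer(stats::rmultinom(1L, cfg$depth, ab))
  out
}

## ---- PSMs -----------------------------------------------------------------

#' Simulate peptide-spectrum matches with spectra
#'
#' True PSMs sample tryptic peptides from novel entries and a subset of
#' reference entries of the hybrid database; their spectra are the complete
#' singly-charged b/y ion series (plus uniform noise peaks at
#' `peak_noise_rate`), probabilities drawn from the true-hit range. Noise
#' PSMs are random unindexed peptides and decoy PSMs sample decoy-entry
#' peptides, both with low probabilities. Ground truth marks each PSM and
#' whether its peptide is a planted unique-novel peptide (absent, I/L
#' collapsed, from the three-scheme digest of the reference proteins).
#'
#' @param db Hybrid database with decoys ([add_decoys()] output).
#' @param index The [build_peptide_index()] built from `db`.
#' @param config A [sim_config()].
#' @return list: psms (data.table), spectra (named list), truth (data.table).
#' @export
simulate_psms <- function(db, index, config) {
  cfg <- config
  set.seed(cfg$seed + 4L)
  p <- cfg$psm
  targets <- db[decoy == FALSE]
  novel <- targets[origin == "novel"]
  refs <- targets[origin == "reference"]
  refs <- refs[sample(nrow(refs), min(nrow(refs), p$n_reference_proteins))]
  chosen <- data.table::rbindlist(list(novel, refs))

  ref_pep_collapsed <- unique(collapse_il(unlist(lapply(
    db[decoy == FALSE & origin == "reference", sequence], function(sq)
      unlist(lapply(list("stricttrypsin", "chymotrypsin", "aspn+lysc"),
                    function(e) digest(sq, e, max_missed = 2L,
                                       min_len = 7L)$peptide))))))

  idx_env <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(index)))
    assign(index$peptide[r], index$parents[[r]], envir = idx_env)

  psm_rows <- list(); spectra <- list(); truth_rows <- list()
  sid <- 0L
  add_psm <- function(pep, prob, parents, class, origin) {
    sid <<- sid + 1L
    id <- sprintf("spec%05d", sid)
    theo <- theoretical_ions(pep, max_fragment_charge = 1L)
    peaks <- data.frame(mz = theo$mz,
                        intensity = round(stats::runif(nrow(theo), 2e3, 1e4), 2))
    n_noise <- round(p$peak_noise_rate * nrow(peaks))
    if (n_noise > 0L)
      peaks <- rbind(peaks, data.frame(
        mz = stats::runif(n_noise, 200, 1500),
        intensity = round(stats::runif(n_noise, 2e3, 1e4), 2)))
    peaks <- peaks[order(peaks$mz), ]
    psm_rows[[sid]] <<- data.table::data.table(
      spectrum_id = id, peptide = pep, mods = "", charge = 2L,
      probability = round(prob, 4), proteins = paste(parents, collapse = ";"))
    spectra[[id]] <<- list(title = id,
                           pepmass = (peptide_mass(pep) + 2 * PROTON_MASS) / 2,
                           charge = 2L, peaks = peaks)
    truth_rows[[sid]] <<- data.table::data.table(
      spectrum_id = id, peptide = pep, class = class, parent_origin = origin,
      is_unique_novel = class == "true" && origin == "novel" &&
        !collapse_il(pep) %in% ref_pep_collapsed)
  }

  for (i in seq_len(nrow(chosen))) {
    dg <- digest(chosen$sequence[i], "stricttrypsin", max_missed = 0L,
                 min_len = 7L, max_len = 25L)
    if (!nrow(dg)) next
    pick <- dg$peptide[sample(nrow(dg), min(nrow(dg), p$peptides_per_orf))]
    for (pep in pick) {
      parents <- if (exists(pep, idx_env)) get(pep, idx_env) else character()
      add_psm(pep, stats::runif(1L, p$true_prob[1L], p$true_prob[2L]),
              parents, "true", chosen$origin[i])
    }
  }
  n_true <- sid
  n_noise_psm <- round(p$noise_peptide_rate * n_true)
  for (i in seq_len(n_noise_psm)) {
    repeat {
      pep <- paste(sample(setdiff(names(AA_MONO), c("I")),
                          sample(8:14, 1L), TRUE), collapse = "")
      if (!exists(pep, idx_env)) break
    }
    add_psm(pep, stats::runif(1L, p$false_prob[1L], p$false_prob[2L]),
            character(), "noise", NA_character_)
  }
  n_decoy_psm <- round(p$decoy_hit_rate * n_true)
  decoys <- db[decoy == TRUE]
  for (i in seq_len(n_decoy_psm)) {
    dseq <- decoys$sequence[sample(nrow(decoys), 1L)]
    dg <- digest(dseq, "stricttrypsin", max_missed = 0L, min_len = 7L,
                 max_len = 25L)
    if (!nrow(dg)) next
    pep <- dg$peptide[sample(nrow(dg), 1L)]
    add_psm(pep, stats::runif(1L, p$false_prob[1L], p$false_prob[2L]),
            decoys$accession[sample(nrow(decoys), 1L)], "decoy", NA_character_)
  }
  list(psms = data.table::rbindlist(psm_rows), spectra = spectra,
       truth = data.table::rbindlist(truth_rows))
}
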