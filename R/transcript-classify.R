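# Structural classification of query transcripts against a reference catalog:
# FSM / NIC / NNIC with novel-element subcategories, CAGE TSS support, exon
# containment and cross-sample overlap summaries.
#
# The FSM/NIC/NNIC boundary follows the splice-SITE convention: a query is
# NIC when every donor and acceptor it uses is annotated for its gene (even
# if a junction, e.g. an exon-skipping junction, is new), and NNIC as soon as
# one site is unannotated.

NOVEL_GENE_PREFIX <- "novelGene"

SUBCATEGORIES <- c("intron_retention", "exon_elongation", "extra_intron",
                   "intron_shift", "alt_polyA", "alt_TSS", "novel_exon",
                   "alternative_structure")

## junction helpers; a junction is an intron interval. In transcription
## direction the donor is the intron's 5' boundary, the acceptor its 3'
## boundary: on '+' donor = intron start, acceptor = intron end; mirrored
## on '-'.

junction_keys <- function(tx) {
  intr <- tx_introns(tx)
  if (!nrow(intr)) return(character())
  sprintf("%s|%s|%d|%d", tx$chrom, tx$strand, intr$start, intr$end)
}

donor_sites <- function(tx) {
  intr <- tx_introns(tx)
  if (!nrow(intr)) return(integer())
  if (tx$strand == "+") intr$start else intr$end
}

acceptor_sites <- function(tx) {
  intr <- tx_introns(tx)
  if (!nrow(intr)) return(integer())
  if (tx$strand == "+") intr$end else intr$start
}

chain_key <- function(tx) {
  paste(junction_keys(tx), collapse = ";")
}

#' Build the reference index used for classification
#'
#' Indexes, per gene, the splice junctions, donor and acceptor sites, intron
#' chains (mapped to the transcript carrying them), exon intervals, intron
#' intervals with their flanking exons, TSS/TES positions and mono-exon
#' transcripts; plus a genome-wide junction-to-gene map and exon table for
#' gene assignment.
#'
#' @param catalog Reference [gene_catalog()].
#' @return An object of class `reference_index`.
#' @export
build_reference_index <- function(catalog) {
  if (!length(catalog$transcripts)) stop("empty catalog")
  genes <- list()
  jx2gene <- new.env(parent = emptyenv())
  exon_rows <- vector("list", length(catalog$transcripts))

  for (k in seq_along(catalog$transcripts)) {
    tx <- catalog$transcripts[[k]]
    g <- tx$gene_id
    ge <- genes[[g]]
    if (is.null(ge)) {
      ge <- list(gene_id = g, chrom = tx$chrom, strand = tx$strand,
                 junctions = character(), donors = integer(),
                 acceptors = integer(), chains = character(),
                 exons = list(), introns = list(), tss = integer(),
                 tes = integer(), mono = list(),
                 five_exons = list(), three_exons = list(),
                 transcript_ids = character())
    }
    if (ge$chrom != tx$chrom || ge$strand != tx$strand)
      stop("gene ", g, ": transcripts disagree on chrom/strand")
    jk <- junction_keys(tx)
    ge$junctions <- union(ge$junctions, jk)
    ge$donors <- union(ge$donors, donor_sites(tx))
    ge$acceptors <- union(ge$acceptors, acceptor_sites(tx))
    ge$tss <- union(ge$tss, tx_tss(tx))
    ge$tes <- union(ge$tes, tx_tes(tx))
    ge$transcript_ids <- c(ge$transcript_ids, tx$transcript_id)
    ex <- tx$exons
    ge$exons[[length(ge$exons) + 1L]] <- ex
    if (nrow(ex) >= 2L) {
      ck <- chain_key(tx)
      if (!ck %in% names(ge$chains)) {
        ge$chains[ck] <- tx$transcript_id
      }
      intr <- tx_introns(tx)
      ge$introns[[length(ge$introns) + 1L]] <- data.frame(
        start = intr$start, end = intr$end,
        lf_start = ex$start[-nrow(ex)], lf_end = ex$end[-nrow(ex)],
        rf_start = ex$start[-1L], rf_end = ex$end[-1L])
      i5 <- if (tx$strand == "+") 1L else nrow(ex)
      i3 <- if (tx$strand == "+") nrow(ex) else 1L
      ge$five_exons[[length(ge$five_exons) + 1L]] <- c(ex$start[i5], ex$end[i5])
      ge$three_exons[[length(ge$three_exons) + 1L]] <- c(ex$start[i3], ex$end[i3])
    } else {
      ge$mono[[length(ge$mono) + 1L]] <- c(tx$transcript_id, ex$start, ex$end)
    }
    genes[[g]] <- ge
    for (key in jk) {
      assign(key, union(if (exists(key, jx2gene)) get(key, jx2gene) else character(), g),
             envir = jx2gene)
    }
    exon_rows[[k]] <- data.table::data.table(
      chrom = tx$chrom, strand = tx$strand, start = ex$start, end = ex$end,
      gene_id = g)
  }

  # consolidate per-gene tables
  for (g in names(genes)) {
    ge <- genes[[g]]
    exdt <- unique(data.table::rbindlist(
      lapply(ge$exons, function(e) data.table::data.table(start = e$start, end = e$end))))
    ge$exons <- as.data.frame(exdt[order(start, end)])
    if (length(ge$introns)) {
      idt <- unique(data.table::rbindlist(ge$introns))
      ge$intron_flanks <- as.data.frame(idt[order(start, end)])
      ge$intron_intervals <- unique(ge$intron_flanks[, c("start", "end")])
    } else {
      ge$intron_flanks <- data.frame(start = integer(), end = integer(),
                                     lf_start = integer(), lf_end = integer(),
                                     rf_start = integer(), rf_end = integer())
      ge$intron_intervals <- data.frame(start = integer(), end = integer())
    }
    ge$introns <- NULL
    ge$five_exons <- unique(do.call(rbind, ge$five_exons))
    ge$three_exons <- unique(do.call(rbind, ge$three_exons))
    ge$mono <- if (length(ge$mono)) {
      m <- do.call(rbind, ge$mono)
      data.frame(transcript_id = m[, 1L], start = as.integer(m[, 2L]),
                 end = as.integer(m[, 3L]), stringsAsFactors = FALSE)
    } else data.frame(transcript_id = character(), start = integer(),
                      end = integer())
    genes[[g]] <- ge
  }

  exon_table <- data.table::rbindlist(exon_rows)
  data.table::setkeyv(exon_table, c("chrom", "strand", "start", "end"))
  structure(list(genes = genes, jx2gene = jx2gene, exon_table = exon_table,
                 catalog = catalog),
            class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("<reference_index> %d gene(s), %d transcript(s)\n",
              length(x$genes), length(x$catalog$transcripts)))
  invisible(x)
}

novel_gene_id <- function(query) {
  sprintf("%s.%s.%s.%d", NOVEL_GENE_PREFIX, query$chrom, query$strand,
          tx_tss(query))
}

#' Assign a query transcript to a reference gene
#'
#' The gene sharing the most splice junctions wins; ties are broken by exonic
#' overlap bases, then lexicographic gene_id. A query sharing no junction and
#' no same-strand exonic overlap with any gene gets a stable novel-gene
#' sentinel id (prefix `novelGene`).
#'
#' @param query A [transcript_model()].
#' @param index A [build_reference_index()] result.
#' @return A gene_id string.
#' @export
assign_gene <- function(query, index) {
  jk <- junction_keys(query)
  votes <- character()
  for (key in jk)
    if (exists(key, index$jx2gene)) votes <- c(votes, get(key, index$jx2gene))
  cand <- if (length(votes)) {
    tb <- table(votes)
    names(tb)[tb == max(tb)]
  } else character()
  if (length(cand) == 1L) return(cand)

  # exonic overlap (same chrom+strand), restricted to tied candidates if any
  et <- index$exon_table[chrom == query$chrom & strand == query$strand]
  if (length(cand)) et <- et[gene_id %in% cand]
  if (!nrow(et)) {
    if (length(cand)) return(sort(cand)[1L])
    return(novel_gene_id(query))
  }
  qe <- query$exons
  ov <- vapply(seq_len(nrow(et)), function(i) {
    sum(pmax(0L, pmin(qe$end, et$end[i]) - pmax(qe$start, et$start[i])))
  }, numeric(1))
  et$ov <- ov
  per_gene <- et[, .(ov = sum(ov)), by = gene_id][ov > 0L]
  if (!nrow(per_gene)) {
    if (length(cand)) return(sort(cand)[1L])
    return(novel_gene_id(query))
  }
  best <- per_gene[ov == max(ov), gene_id]
  sort(best)[1L]
}

#' Classify one query transcript as FSM / NIC / NNIC
#'
#' FSM: the query's intron chain equals a reference transcript's chain
#' exactly (transcript ends may differ). NIC: every donor and acceptor site
#' is annotated for the assigned gene, but the chain is new. NNIC: at least
#' one splice site is unannotated. Mono-exon queries are FSM when fully
#' contained in a mono-exon reference transcript of the gene, NIC when
#' contained in any reference exon, else NNIC. Queries assigned to no gene
#' are NNIC with subcategory `novel_exon`.
#'
#' @param query A [transcript_model()].
#' @param index A [build_reference_index()] result.
#' @param elong_bp Terminal exon elongation threshold (bp).
#' @param w_tss,w_tes Windows (bp) beyond which the 5'/3' end counts as an
#'   alternative TSS / poly(A) site.
#' @return A list of class `structural_call` with fields `transcript_id`,
#'   `assigned_gene`, `category`, `matched_reference`, `subcategories`.
#' @export
classify_transcript <- function(query, index, elong_bp = 10L,
                                w_tss = 50L, w_tes = 50L) {
  g <- assign_gene(query, index)
  if (startsWith(g, NOVEL_GENE_PREFIX)) {
    return(structure(list(transcript_id = query$transcript_id,
                          assigned_gene = g, category = "NNIC",
                          matched_reference = NA_character_,
                          subcategories = "novel_exon"),
                     class = "structural_call"))
  }
  ge <- index$genes[[g]]
  n_ex <- nrow(query$exons)
  matched <- NA_character_
  if (n_ex == 1L) {
    qs <- query$exons$start[1L]; qe <- query$exons$end[1L]
    m <- ge$mono
    hit <- which(m$start <= qs & qe <= m$end)
    if (length(hit)) {
      category <- "FSM"
      matched <- sort(m$transcript_id[hit])[1L]
    } else if (any(ge$exons$start <= qs & qe <= ge$exons$end)) {
      category <- "NIC"
    } else {
      category <- "NNIC"
    }
  } else {
    ck <- chain_key(query)
    if (ck %in% names(ge$chains)) {
      category <- "FSM"
      matched <- unname(ge$chains[ck])
    } else {
      d_known <- all(donor_sites(query) %in% ge$donors)
      a_known <- all(acceptor_sites(query) %in% ge$acceptors)
      category <- if (d_known && a_known) "NIC" else "NNIC"
    }
  }
  call <- structure(list(transcript_id = query$transcript_id, assigned_gene = g,
                         category = category, matched_reference = matched,
                         subcategories = character()),
                    class = "structural_call")
  call$subcategories <- subcategorize(query, call, index, elong_bp = elong_bp,
                                      w_tss = w_tss, w_tes = w_tes)
  call
}

#' Subcategorize a structural call
#'
#' Applies the operational novel-element rules (intron retention, extra
#' intron, intron shift, terminal exon elongation, alternative poly(A)/TSS,
#' novel exon) and falls back to `alternative_structure` when the chain is
#' novel but no specific label fires. FSM calls only receive the end labels.
#'
#' @inheritParams classify_transcript
#' @param call A `structural_call`.
#' @return Character vector of subcategory labels.
#' @export
subcategorize <- function(query, call, index, elong_bp = 10L,
                          w_tss = 50L, w_tes = 50L) {
  if (startsWith(call$assigned_gene, NOVEL_GENE_PREFIX)) return("novel_exon")
  ge <- index$genes[[call$assigned_gene]]
  labels <- character()

  # end variation (evaluated for every category)
  if (length(ge$tes) && all(abs(tx_tes(query) - ge$tes) > w_tes))
    labels <- c(labels, "alt_polyA")
  if (length(ge$tss) && all(abs(tx_tss(query) - ge$tss) > w_tss))
    labels <- c(labels, "alt_TSS")
  if (call$category == "FSM")
    return(intersect(SUBCATEGORIES, labels))

  qex <- query$exons
  qintr <- tx_introns(query)
  known_jx <- junction_keys(query) %in% ge$junctions
  ri <- ge$intron_flanks
  rint <- ge$intron_intervals

  # intron_retention: a query exon fully spans a reference intron whose
  # flanking reference exons both overlap that query exon
  if (nrow(ri)) {
    for (i in seq_len(nrow(qex))) {
      sp <- which(ri$start >= qex$start[i] & ri$end <= qex$end[i] &
                    ri$lf_end > qex$start[i] & ri$lf_start < qex$end[i] &
                    ri$rf_end > qex$start[i] & ri$rf_start < qex$end[i])
      if (length(sp)) { labels <- c(labels, "intron_retention"); break }
    }
  }

  if (nrow(qintr)) {
    for (i in seq_len(nrow(qintr))) {
      if (known_jx[i]) next
      # extra_intron: novel query intron fully inside a reference exon
      if (any(ge$exons$start <= qintr$start[i] & qintr$end[i] <= ge$exons$end))
        labels <- c(labels, "extra_intron")
      # intron_shift: novel query intron overlapping exactly one distinct
      # reference intron interval
      if (nrow(rint)) {
        n_ov <- sum(rint$start < qintr$end[i] & qintr$start[i] < rint$end)
        if (n_ov == 1L) labels <- c(labels, "intron_shift")
      }
    }
  }

  # novel_exon: a query exon overlapping no reference exon of the gene
  for (i in seq_len(nrow(qex))) {
    if (!any(ge$exons$start < qex$end[i] & qex$start[i] < ge$exons$end)) {
      labels <- c(labels, "novel_exon")
      break
    }
  }

  # exon_elongation: a terminal query exon extending beyond every matched
  # (overlapping) reference terminal exon boundary by > elong_bp, outward
  term <- function(side) {
    ref <- if (side == "five") ge$five_exons else ge$three_exons
    if (is.null(ref) || !nrow(ref)) return(FALSE)
    i <- if ((side == "five") == (query$strand == "+")) 1L else nrow(qex)
    qs <- qex$start[i]; qe <- qex$end[i]
    ov <- ref[ref[, 1L] < qe & qs < ref[, 2L], , drop = FALSE]
    if (!nrow(ov)) return(FALSE)
    outward_plus_left <- (side == "five") == (query$strand == "+")
    ext <- if (outward_plus_left) ov[, 1L] - qs else qe - ov[, 2L]
    min(ext) > elong_bp
  }
  if (term("five") || term("three")) labels <- c(labels, "exon_elongation")

  labels <- unique(labels)
  if (!length(labels)) labels <- "alternative_structure"
  intersect(SUBCATEGORIES, labels)
}

#' Classify a whole query catalog
#'
#' @param query_catalog Query [gene_catalog()].
#' @param index Reference index.
#' @inheritParams classify_transcript
#' @return data.table with columns transcript_id, assigned_gene, category,
#'   matched_reference, subcategories (comma-joined).
#' @export
classify_catalog <- function(query_catalog, index, elong_bp = 10L,
                             w_tss = 50L, w_tes = 50L) {
  calls <- lapply(query_catalog$transcripts, classify_transcript, index = index,
                  elong_bp = elong_bp, w_tss = w_tss, w_tes = w_tes)
  data.table::rbindlist(lapply(calls, function(cl) {
    data.table::data.table(
      transcript_id = cl$transcript_id, assigned_gene = cl$assigned_gene,
      category = cl$category, matched_reference = cl$matched_reference,
      subcategories = paste(cl$subcategories, collapse = ","))
  }))
}

#' CAGE support of a transcript's TSS
#'
#' A TSS is supported when it lies inside a CAGE peak (distance 0) or when a
#' peak ends within `window` bp upstream of it (strand-aware upstream). The
#' reported distance is 0 (inside), the upstream gap (positive), or the
#' negative downstream gap of the nearest peak.
#'
#' @param tx A [transcript_model()].
#' @param peaks data.frame with columns chrom, start, end (0-based half-open).
#' @param window Upstream search window in bp (default 50).
#' @return list(transcript_id, distance, supported).
#' @export
cage_support <- function(tx, peaks, window = 50L) {
  pos <- tx_tss(tx)
  pk <- peaks[peaks$chrom == tx$chrom, , drop = FALSE]
  if (!nrow(pk))
    return(list(transcript_id = tx$transcript_id, distance = NA_integer_,
                supported = FALSE))
  inside <- pk$start <= pos & pos < pk$end
  if (any(inside))
    return(list(transcript_id = tx$transcript_id, distance = 0L,
                supported = TRUE))
  # positive = peak upstream of the TSS (strand-aware), negative = downstream
  gap <- if (tx$strand == "+") {
    ifelse(pk$end <= pos, pos - pk$end, -(pk$start - pos))
  } else {
    ifelse(pk$start > pos, pk$start - pos - 1L, -(pos + 1L - pk$end))
  }
  d <- gap[which.min(abs(gap))]
  list(transcript_id = tx$transcript_id, distance = as.integer(d),
       supported = d >= 0L && d <= window)
}

#' Features fully contained in catalog exons
#'
#' Returns the subset of `features` 100% covered by at least one exon of the
#' catalog (fraction-of-feature = 1, each feature reported once).
#'
#' @param features data.frame with chrom, start, end (0-based half-open).
#' @param catalog A [gene_catalog()] or an exon data.frame with
#'   chrom/start/end columns.
#' @return The retained subset of `features`.
#' @export
contained_features <- function(features, catalog) {
  exons <- if (inherits(catalog, "gene_catalog")) {
    data.table::rbindlist(lapply(catalog$transcripts, function(tx)
      data.table::data.table(chrom = tx$chrom, start = tx$exons$start,
                             end = tx$exons$end)))
  } else data.table::as.data.table(catalog[, c("chrom", "start", "end")])
  keep <- logical(nrow(features))
  for (ch in unique(features$chrom)) {
    fi <- which(features$chrom == ch)
    ex <- exons[chrom == ch]
    if (!nrow(ex)) next
    fr <- IRanges::IRanges(features$start[fi] + 1L, features$end[fi])
    er <- IRanges::IRanges(ex$start + 1L, ex$end)
    hits <- IRanges::findOverlaps(fr, er, type = "within")
    keep[fi[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  features[keep, , drop = FALSE]
}

#' Cross-sample transcript overlap
#'
#' @param per_sample_ids List (length >= 2) of transcript-id character sets.
#' @return list(n_samples_per_transcript = named integer vector,
#'   fraction_in_ge2 = proportion of transcripts present in at least two sets).
#' @export
sample_overlap <- function(per_sample_ids) {
  if (length(per_sample_ids) < 2L) stop("need at least two sample sets")
  all_ids <- unlist(lapply(per_sample_ids, unique))
  tb <- table(all_ids)
  counts <- as.integer(tb)
  names(counts) <- names(tb)
  list(n_samples_per_transcript = counts,
       fraction_in_ge2 = mean(counts >= 2L))
}
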