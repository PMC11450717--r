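# Transcript data model and I/O for the standard formats (GTF, FASTA, BED12,
# MGF-style peak lists, TSV count tables).
#
# All coordinates are 0-based half-open internally; GTF conversion happens at
# the file boundary only. Exons are stored in ascending genomic order
# regardless of strand; transcription order is derived from the strand.

#' Construct a transcript model
#'
#' The unit of classification: a strand-aware exon structure with an optional
#' CDS and a free-form attribute map.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons A data.frame with integer columns `start`, `end`
#'   (0-based half-open), ascending and non-overlapping.
#' @param cds Optional data.frame of CDS blocks, same convention; every block
#'   must be contained in an exon.
#' @param attributes Named character vector of extra GTF attributes.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL, attributes = character()) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  tx <- structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, cds = cds, attributes = attributes),
    class = "transcript_model")
  validate_transcript_model(tx)
  tx
}

validate_transcript_model <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 1L) stop("transcript ", tx$transcript_id, ": no exons")
  if (any(ex$start < 0L) || any(ex$end <= ex$start))
    stop("transcript ", tx$transcript_id, ": invalid exon interval")
  if (!tx$strand %in% c("+", "-"))
    stop("transcript ", tx$transcript_id, ": strand must be '+' or '-'")
  if (nrow(ex) > 1L) {
    if (is.unsorted(ex$start, strictly = TRUE))
      stop("transcript ", tx$transcript_id, ": exons not in ascending order")
    if (any(ex$start[-1L] <= ex$end[-nrow(ex)] - 1L))
      stop("transcript ", tx$transcript_id, ": overlapping exons")
    if (any(ex$start[-1L] - ex$end[-nrow(ex)] < 1L))
      stop("transcript ", tx$transcript_id, ": intron of length < 1")
  }
  if (!is.null(tx$cds)) {
    cd <- tx$cds
    contained <- vapply(seq_len(nrow(cd)), function(i) {
      any(ex$start <= cd$start[i] & cd$end[i] <= ex$end)
    }, logical(1))
    if (!all(contained))
      stop("transcript ", tx$transcript_id, ": CDS block outside exons")
  }
  invisible(tx)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exon(s), %d nt%s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), tx_length(x),
              if (is.null(x$cds)) "" else ", CDS"))
  invisible(x)
}

#' Construct a gene catalog
#'
#' @param transcripts Named (by transcript_id) list of [transcript_model()]s,
#'   or an unnamed list (names are taken from the models).
#' @param genes Optional data.frame with columns `gene_id`, `biotype`.
#' @param source_tag Free label recording where the catalog came from.
#' @return An object of class `gene_catalog`.
#' @export
gene_catalog <- function(transcripts, genes = NULL, source_tag = "") {
  if (is.null(names(transcripts)) && length(transcripts))
    names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(names(transcripts)))
    stop("duplicate transcript_id in catalog")
  gids <- unique(vapply(transcripts, `[[`, "", "gene_id"))
  if (is.null(genes)) {
    genes <- data.frame(gene_id = gids, biotype = rep("protein_coding", length(gids)),
                        stringsAsFactors = FALSE)
  } else {
    if (!all(gids %in% genes$gene_id))
      stop("transcript refers to a gene_id missing from the gene table")
  }
  structure(list(transcripts = transcripts, genes = genes,
                 source_tag = source_tag),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("<gene_catalog> %d gene(s), %d transcript(s)%s\n",
              nrow(x$genes), length(x$transcripts),
              if (nzchar(x$source_tag)) paste0(" [", x$source_tag, "]") else ""))
  invisible(x)
}

#' @export
length.gene_catalog <- function(x) length(x$transcripts)

## ---- small transcript accessors -------------------------------------------

#' Transcript length and exon arithmetic
#'
#' `tx_length()` is the spliced length; `tx_introns()` returns the intron
#' intervals in ascending genomic order; `tx_tss()`/`tx_tes()` return the
#' 0-based genomic coordinate of the first/last transcribed base.
#'
#' @param tx A [transcript_model()].
#' @export
tx_length <- function(tx) sum(tx$exons$end - tx$exons$start)

#' @rdname tx_length
#' @export
tx_introns <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 2L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1L])
}

#' @rdname tx_length
#' @export
tx_tss <- function(tx) {
  if (tx$strand == "+") tx$exons$start[1L] else tx$exons$end[nrow(tx$exons)] - 1L
}

#' @rdname tx_length
#' @export
tx_tes <- function(tx) {
  if (tx$strand == "+") tx$exons$end[nrow(tx$exons)] - 1L else tx$exons$start[1L]
}

## ---- GTF ------------------------------------------------------------------

#' Read a GENCODE-dialect GTF into a gene catalog
#'
#' 1-based inclusive GTF coordinates are converted to the internal 0-based
#' half-open convention. Exon rows are grouped per transcript and sorted;
#' CDS rows become CDS blocks; feature types other than
#' gene/transcript/exon/CDS are ignored (their count is reported via
#' `message()`). Exon or CDS rows missing `gene_id` or `transcript_id` raise
#' an error naming the offending line.
#'
#' @param path GTF file.
#' @param source_tag Stored on the returned catalog.
#' @return A [gene_catalog()].
#' @export
read_gtf <- function(path, source_tag = basename(path)) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  feat <- sub("^[^\t]*\t[^\t]*\t([^\t]*)\t.*$", "\\1", lines[body])
  need <- body[feat %in% c("exon", "CDS")]
  bad <- need[!grepl("transcript_id \"", lines[need], fixed = TRUE) |
                !grepl("gene_id \"", lines[need], fixed = TRUE)]
  if (length(bad))
    stop("GTF line ", bad[1L], " lacks a gene_id/transcript_id attribute: ",
         substr(lines[bad[1L]], 1, 80))

  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(S4Vectors::mcols(gr))
  type <- as.character(md$type)
  known <- type %in% c("gene", "transcript", "exon", "CDS")
  if (any(!known))
    message(sum(!known), " GTF row(s) with unhandled feature types ignored: ",
            paste(unique(type[!known]), collapse = ", "))

  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(BiocGenerics::strand(gr))

  attr_cols <- setdiff(names(md), c("type", "source", "score", "phase"))
  ex_idx <- which(type == "exon")
  cds_idx <- which(type == "CDS")
  tr_idx <- which(type == "transcript")

  build_one <- function(txid) {
    i <- ex_idx[md$transcript_id[ex_idx] == txid]
    j <- cds_idx[md$transcript_id[cds_idx] == txid]
    o <- order(start0[i])
    i <- i[o]
    cds <- NULL
    if (length(j)) {
      j <- j[order(start0[j])]
      cds <- data.frame(start = start0[j], end = end0[j])
    }
    # transcript-level attributes: from the transcript row if present,
    # else from the first exon row
    src <- tr_idx[md$transcript_id[tr_idx] == txid]
    src <- if (length(src)) src[1L] else i[1L]
    at <- unlist(md[src, setdiff(attr_cols, c("gene_id", "transcript_id")),
                    drop = FALSE])
    at <- at[!is.na(at)]
    transcript_model(txid, md$gene_id[i[1L]], chrom[i[1L]], strand[i[1L]],
                     data.frame(start = start0[i], end = end0[i]),
                     cds = cds, attributes = at)
  }
  txids <- unique(md$transcript_id[ex_idx])
  transcripts <- lapply(txids, build_one)
  names(transcripts) <- txids

  gene_rows <- which(type == "gene")
  genes <- NULL
  if (length(gene_rows) && "gene_biotype" %in% names(md)) {
    genes <- data.frame(gene_id = md$gene_id[gene_rows],
                        biotype = md$gene_biotype[gene_rows],
                        stringsAsFactors = FALSE)
    genes <- genes[!duplicated(genes$gene_id), ]
    extra <- setdiff(unique(vapply(transcripts, `[[`, "", "gene_id")),
                     genes$gene_id)
    if (length(extra))
      genes <- rbind(genes, data.frame(gene_id = extra, biotype = "protein_coding"))
  }
  gene_catalog(transcripts, genes = genes, source_tag = source_tag)
}

#' Write a gene catalog as GENCODE-dialect GTF
#'
#' Emits gene, transcript, exon and (where present) CDS rows with 1-based
#' inclusive coordinates; exon rows stay in ascending genomic order on both
#' strands. Attributes round-trip.
#'
#' @param catalog A [gene_catalog()].
#' @param path Output file.
#' @export
write_gtf <- function(catalog, path) {
  txs <- catalog$transcripts
  if (!length(txs)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  rows <- list()
  n <- 0L
  add <- function(chrom, feat, s0, e0, strand, attrs) {
    n <<- n + 1L
    rows[[n]] <<- sprintf("%s\tlrproteo\t%s\t%d\t%d\t.\t%s\t.\t%s",
                          chrom, feat, s0 + 1L, e0, strand, attrs)
  }
  fmt_attr <- function(keys, vals) {
    paste0(sprintf('%s "%s";', keys, vals), collapse = " ")
  }
  gene_span <- list()
  for (tx in txs) {
    g <- tx$gene_id
    sp <- gene_span[[g]]
    rng <- c(tx$exons$start[1L], tx$exons$end[nrow(tx$exons)])
    gene_span[[g]] <- if (is.null(sp)) list(chrom = tx$chrom, strand = tx$strand,
                                            start = rng[1L], end = rng[2L])
                      else modifyList(sp, list(start = min(sp$start, rng[1L]),
                                               end = max(sp$end, rng[2L])))
  }
  done_gene <- character()
  for (tx in txs) {
    g <- tx$gene_id
    if (!g %in% done_gene) {
      sp <- gene_span[[g]]
      bt <- catalog$genes$biotype[match(g, catalog$genes$gene_id)]
      add(sp$chrom, "gene", sp$start, sp$end, sp$strand,
          fmt_attr(c("gene_id", "gene_biotype"), c(g, bt)))
      done_gene <- c(done_gene, g)
    }
    base_keys <- c("gene_id", "transcript_id")
    base_vals <- c(g, tx$transcript_id)
    if (length(tx$attributes)) {
      base_keys <- c(base_keys, names(tx$attributes))
      base_vals <- c(base_vals, unname(tx$attributes))
    }
    add(tx$chrom, "transcript", tx$exons$start[1L], tx$exons$end[nrow(tx$exons)],
        tx$strand, fmt_attr(base_keys, base_vals))
    for (i in seq_len(nrow(tx$exons)))
      add(tx$chrom, "exon", tx$exons$start[i], tx$exons$end[i], tx$strand,
          fmt_attr(c(base_keys, "exon_number"), c(base_vals, i)))
    if (!is.null(tx$cds))
      for (i in seq_len(nrow(tx$cds)))
        add(tx$chrom, "CDS", tx$cds$start[i], tx$cds$end[i], tx$strand,
            fmt_attr(base_keys, base_vals))
  }
  writeLines(unlist(rows), path)
  invisible(path)
}

## ---- sequence -------------------------------------------------------------

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of an ACGTN string
#' @param s Nucleotide string.
#' @export
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences in transcript order; on the minus strand
#' the result is reverse-complemented so that position 0 is the 5' end.
#'
#' @param tx A [transcript_model()].
#' @param genome Named character vector (chrom -> uppercase ACGTN sequence).
#' @return A nucleotide string.
#' @export
spliced_sequence <- function(tx, genome) {
  if (!tx$chrom %in% names(genome))
    stop("chromosome ", tx$chrom, " not in genome")
  chromseq <- genome[[tx$chrom]]
  if (any(tx$exons$end > nchar(chromseq)))
    stop("transcript ", tx$transcript_id, ": exon beyond chromosome end")
  parts <- substring(chromseq, tx$exons$start + 1L, tx$exons$end)
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") revcomp(s) else s
}

## ---- FASTA ----------------------------------------------------------------

#' Read / write FASTA
#'
#' Sequences are uppercased on read. Duplicate identifiers are an error.
#' `type = "DNA"` additionally rejects non-ACGTN characters (the genome used
#' for ORF calling must be plain ACGTN).
#'
#' @param path File path.
#' @param type `"auto"`, `"DNA"` or `"AA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("auto", "DNA", "AA")) {
  type <- match.arg(type)
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) stop("duplicate FASTA identifiers: ",
                              nm[duplicated(nm)][1L])
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  if (type == "DNA" && any(grepl("[^ACGTN]", seqs)))
    stop("non-ACGTN characters in DNA FASTA")
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

## ---- MGF-style peak lists -------------------------------------------------

#' Read an MGF-style peak list
#'
#' Minimal BEGIN IONS/END IONS dialect: TITLE, PEPMASS, CHARGE headers and
#' one `m/z intensity` pair per line. Peaks are returned sorted by m/z.
#'
#' @param path File path.
#' @return A list of spectra: `list(title, pepmass, charge, peaks)` where
#'   `peaks` is a data.frame with columns `mz`, `intensity`.
#' @export
read_peaklist <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (ln == "BEGIN IONS") {
      cur <- list(title = NA_character_, pepmass = NA_real_,
                  charge = NA_integer_, mz = numeric(), int = numeric())
    } else if (ln == "END IONS") {
      o <- order(cur$mz)
      out[[length(out) + 1L]] <- list(
        title = cur$title, pepmass = cur$pepmass, charge = cur$charge,
        peaks = data.frame(mz = cur$mz[o], intensity = cur$int[o]))
      cur <- NULL
    } else if (is.null(cur)) {
      next
    } else if (startsWith(ln, "TITLE=")) {
      cur$title <- sub("^TITLE=", "", ln)
    } else if (startsWith(ln, "PEPMASS=")) {
      cur$pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1L]][1L])
    } else if (startsWith(ln, "CHARGE=")) {
      cur$charge <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", ln)))
    } else if (grepl("^[0-9]", ln)) {
      xy <- as.numeric(strsplit(ln, "\\s+")[[1L]])
      cur$mz <- c(cur$mz, xy[1L])
      cur$int <- c(cur$int, if (length(xy) > 1L) xy[2L] else 1)
    }
  }
  out
}

#' @rdname read_peaklist
#' @param spectra List of spectra as returned by `read_peaklist()`.
#' @export
write_peaklist <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.na(sp$title)) writeLines(paste0("TITLE=", sp$title), con)
    if (!is.na(sp$pepmass)) writeLines(sprintf("PEPMASS=%.6f", sp$pepmass), con)
    if (!is.na(sp$charge)) writeLines(sprintf("CHARGE=%d+", sp$charge), con)
    writeLines(sprintf("%.6f %.2f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

## ---- counts ---------------------------------------------------------------

#' Read a full-length count table
#'
#' TSV with a `transcript_id` column and one integer column per sample.
#'
#' @param path File path.
#' @return A data.table keyed by `transcript_id`.
#' @export
read_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  if (!"transcript_id" %in% names(dt))
    stop("counts table lacks a transcript_id column")
  if (ncol(dt) < 2L) stop("counts table has no sample columns")
  data.table::setkeyv(dt, "transcript_id")
  dt[]
}

#' @rdname read_counts
#' @param counts data.frame with `transcript_id` plus sample columns.
#' @export
write_counts <- function(counts, path) {
  data.table::fwrite(counts, path, sep = "\t")
  invisible(path)
}

## ---- BED ------------------------------------------------------------------

#' Write BED12 records
#'
#' `records` is a data.frame with the 12 BED columns (`chrom`, `start`, `end`,
#' `name`, `score`, `strand`, `thickStart`, `thickEnd`, `rgb`, `blockCount`,
#' `blockSizes`, `blockStarts`); blockSizes/blockStarts are comma-joined
#' strings, blockStarts relative to `start`. Blocks must be sorted, start at
#' 0 and end at `end - start`.
#'
#' @param records BED12 data.frame.
#' @param path Output file.
#' @export
write_bed12 <- function(records, path) {
  records <- as.data.frame(records)
  for (i in seq_len(nrow(records))) {
    sizes <- as.integer(strsplit(records$blockSizes[i], ",")[[1L]])
    starts <- as.integer(strsplit(records$blockStarts[i], ",")[[1L]])
    if (length(sizes) != records$blockCount[i] ||
        length(starts) != records$blockCount[i])
      stop("BED12 row ", i, ": blockCount does not match block lists")
    if (is.unsorted(starts, strictly = TRUE))
      stop("BED12 row ", i, ": blocks not sorted")
    if (starts[1L] != 0L)
      stop("BED12 row ", i, ": first blockStart must be 0")
    span <- records$end[i] - records$start[i]
    if (utils::tail(starts + sizes, 1L) != span)
      stop("BED12 row ", i, ": last block must end at end")
    if (any(starts + sizes > span) || any(starts < 0L))
      stop("BED12 row ", i, ": block outside [start, end)")
  }
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "thickStart", "thickEnd", "rgb", "blockCount",
            "blockSizes", "blockStarts")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Turn genomic blocks into one BED12 record
#'
#' @param chrom,strand Location.
#' @param blocks data.frame of 0-based half-open blocks, ascending.
#' @param name,score BED name/score fields.
#' @keywords internal
bed12_from_blocks <- function(chrom, strand, blocks, name, score = 0L) {
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  s <- blocks$start[1L]
  e <- blocks$end[nrow(blocks)]
  data.frame(chrom = chrom, start = s, end = e, name = name, score = score,
             strand = strand, thickStart = s, thickEnd = e, rgb = "0,0,0",
             blockCount = nrow(blocks),
             blockSizes = paste(blocks$end - blocks$start, collapse = ","),
             blockStarts = paste(blocks$start - s, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Read a BED file of peaks/intervals (first 6 columns honoured)
#'
#' @param path BED file (0-based half-open, as BED natively is).
#' @return data.frame with chrom/start/end (+ name/score/strand when present).
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, seq_len(min(ncol(dt), 6L)), nm[seq_len(min(ncol(dt), 6L))])
  as.data.frame(dt)
}
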