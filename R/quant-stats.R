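# Quantification (TPM on full-length counts, per-gene isoform fractions,
# novel-dominant gene detection) and the accompanying statistical tests.
# The tests are thin wrappers over the standard stats:: machinery returning
# a uniform result shape.

test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = unname(statistic), df = df,
                 p_value = unname(p_value), method = method),
            class = "lrp_test")
}

#' @export
print.lrp_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.3g\n", x$method, x$statistic,
              if (!is.null(x$df) && !is.na(x$df)) paste0(", df = ", x$df) else "",
              x$p_value))
  invisible(x)
}

#' Transcripts-per-million from full-length counts
#'
#' `tpm_i = count_i / sum(counts) * 1e6` per sample, with no length
#' normalization: full-length read counts already count molecules.
#'
#' @param counts data.frame with `transcript_id` plus one integer column per
#'   sample.
#' @return list of class `expression_table`: `counts` and `tpm` data.tables
#'   with the same shape.
#' @export
compute_tpm <- function(counts) {
  dt <- data.table::as.data.table(counts)
  samples <- setdiff(names(dt), "transcript_id")
  if (any(vapply(samples, function(s) any(dt[[s]] < 0), logical(1))))
    stop("negative counts")
  tpm <- data.table::copy(dt)
  for (s in samples) {
    tot <- sum(dt[[s]])
    if (tot == 0) {
      warning("sample ", s, " has all-zero counts")
      tpm[[s]] <- as.numeric(dt[[s]])
    } else {
      tpm[[s]] <- dt[[s]] / tot * 1e6
    }
  }
  structure(list(counts = dt, tpm = tpm, samples = samples),
            class = "expression_table")
}

#' Per-gene relative isoform abundance
#'
#' Counts are summed across samples before computing per-gene fractions, so
#' each isoform gets a single relative abundance.
#'
#' @param expr An [compute_tpm()] result or raw counts data.frame.
#' @param gene_assignment Named character vector transcript_id -> gene_id.
#' @param novel_orf_ids Transcript ids whose ORF is novel (non-pFSM).
#' @return data.table: gene_id, transcript_id, total_count,
#'   relative_abundance, is_novel_orf.
#' @export
isoform_abundance <- function(expr, gene_assignment, novel_orf_ids = character()) {
  counts <- if (inherits(expr, "expression_table")) expr$counts
            else data.table::as.data.table(expr)
  samples <- setdiff(names(counts), "transcript_id")
  dt <- data.table::data.table(
    transcript_id = counts$transcript_id,
    total_count = rowSums(as.matrix(counts[, ..samples])))
  dt[, gene_id := gene_assignment[transcript_id]]
  dt[is.na(gene_id), gene_id := paste0(NOVEL_GENE_PREFIX, ".unassigned")]
  dt[, relative_abundance := {
    tot <- sum(total_count)
    if (tot > 0) total_count / tot else rep(0, .N)
  }, by = gene_id]
  dt[, is_novel_orf := transcript_id %in% novel_orf_ids]
  dt[order(gene_id, -relative_abundance)]
}

#' Genes whose most abundant isoform carries a novel ORF
#'
#' Genes whose longest reference transcript exceeds `length_cutoff` are
#' excluded (incomplete long-transcript coverage) and listed separately.
#'
#' @param records An [isoform_abundance()] table.
#' @param ref_catalog Reference [gene_catalog()] (for transcript lengths).
#' @param gene_list Optional restriction to a gene panel.
#' @param length_cutoff Longest-reference-transcript exclusion (default 8000 nt).
#' @return list(flagged, excluded): data.tables of genes.
#' @export
flag_novel_dominant <- function(records, ref_catalog, gene_list = NULL,
                                length_cutoff = 8000L) {
  dt <- data.table::as.data.table(records)
  if (!is.null(gene_list)) dt <- dt[gene_id %in% gene_list]
  top <- dt[dt[, .I[which.max(relative_abundance)], by = gene_id]$V1]
  ref_len <- vapply(ref_catalog$transcripts, tx_length, integer(1))
  ref_gene <- vapply(ref_catalog$transcripts, `[[`, "", "gene_id")
  longest <- tapply(ref_len, ref_gene, max)
  top[, longest_reference := as.integer(longest[gene_id])]
  excluded <- top[!is.na(longest_reference) & longest_reference > length_cutoff]
  kept <- top[is.na(longest_reference) | longest_reference <= length_cutoff]
  list(flagged = kept[is_novel_orf == TRUE], excluded = excluded)
}

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction; df = (r-1)(c-1).
#' @param table Matrix of non-negative counts.
#' @export
chi_squared <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table")
  ht <- stats::chisq.test(table, correct = FALSE)
  test_result(ht$statistic, unname(ht$parameter), ht$p.value,
              "Pearson chi-squared")
}

#' Mann-Whitney U test
#'
#' U counts pairs where x exceeds y (ties 1/2). Exact enumeration is used
#' when `length(x)*length(y) <= 1e4` and there are no ties; otherwise the
#' normal approximation with tie correction.
#'
#' @param x,y Numeric samples.
#' @export
mann_whitney <- function(x, y) {
  exact <- length(x) * length(y) <= 1e4 && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = FALSE))
  test_result(ht$statistic, NA_integer_, ht$p.value,
              paste0("Mann-Whitney U (", if (exact) "exact" else "normal approx.", ")"))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; p from the t approximation.
#' @param x,y Numeric vectors (length >= 3).
#' @export
spearman <- function(x, y) {
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for constant input")
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  test_result(ht$estimate, NA_integer_, ht$p.value, "Spearman rank correlation")
}

#' Benjamini-Hochberg adjustment
#' @param p_values Raw p-values in [0, 1].
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values outside [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis
#'
#' One-sided hypergeometric tail per term against the background, BH across
#' terms; terms with no background overlap are skipped with a message.
#'
#' @param study_genes Character vector (subset of background).
#' @param background_genes Character vector.
#' @param term_to_genes Named list term -> gene ids.
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @return data.table: term, overlap, term_size, p, p_adjusted, significant.
#' @export
overrepresentation <- function(study_genes, background_genes, term_to_genes,
                               alpha = 0.05) {
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  if (!all(study_genes %in% background_genes))
    stop("study genes must be a subset of the background")
  N <- length(background_genes)
  n <- length(study_genes)
  rows <- list()
  for (term in names(term_to_genes)) {
    tg <- intersect(term_to_genes[[term]], background_genes)
    K <- length(tg)
    if (K == 0L) {
      message("term ", term, " has no background overlap; skipped")
      next
    }
    k <- length(intersect(study_genes, tg))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      term = term, overlap = k, term_size = K, p = p)
  }
  if (!length(rows))
    return(data.table::data.table(term = character(), overlap = integer(),
                                  term_size = integer(), p = numeric(),
                                  p_adjusted = numeric(), significant = logical()))
  out <- data.table::rbindlist(rows)
  out[, p_adjusted := bh_adjust(p)]
  out[, significant := p_adjusted < alpha]
  out[order(p_adjusted, term)]
}
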