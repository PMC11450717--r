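# Rule-based prioritization of annotated SNVs/indels and SVs/CNVs in a gene
# panel. The SNV frequency gate is strict (af > cutoff discarded) while the
# SV gate is inclusive (af <= cutoff kept), following the asymmetric wording
# of the underlying criteria.

SNV_DIRECT_CONSEQUENCES <- c("stop_gain", "stop_loss", "start_gain",
                             "start_loss", "frameshift", "inframe_indel",
                             "canonical_splice", "near_splice_missense",
                             "noncanonical_splice")
SNV_SPLICEAI_CONSEQUENCES <- c("deep_intronic", "exonic_splice_region")

#' Prioritize SNVs/indels
#'
#' Rules, applied to each row independently (order-independent):
#' variants with population allele frequency above `af_cutoff` are discarded
#' regardless of scores; protein-disrupting and splice-site consequences are
#' prioritized directly; deep-intronic and exonic splice-region variants
#' require SpliceAI >= `spliceai_min`; missense requires phyloP >=
#' `phylop_min` OR CADD_PHRED >= `cadd_min` OR Grantham >= `grantham_min`;
#' silent requires phyloP or CADD_PHRED above threshold. A variant whose
#' applicable rule needs a score that is missing (and no available score
#' passes) is marked indeterminate (`prioritized = NA`).
#'
#' @param variants data.frame with columns `variant_id` (optional),
#'   `population_af`, `consequence`, and score columns `spliceai`, `phylop`,
#'   `cadd_phred`, `grantham` (NA allowed).
#' @param af_cutoff Allele-frequency gate (default 0.005; strict `>` discards).
#' @param spliceai_min,phylop_min,cadd_min,grantham_min Rule thresholds.
#' @return data.table: variant_id, prioritized (TRUE/FALSE/NA), rules_fired,
#'   discard_reason.
#' @export
prioritize_snv <- function(variants, af_cutoff = 0.005, spliceai_min = 0.2,
                           phylop_min = 2.7, cadd_min = 15, grantham_min = 80) {
  v <- data.table::as.data.table(variants)
  if (!"variant_id" %in% names(v))
    v[, variant_id := sprintf("snv_%d", .I)]
  for (col in c("spliceai", "phylop", "cadd_phred", "grantham"))
    if (!col %in% names(v)) v[[col]] <- NA_real_

  score_rule <- function(scores, thresholds, label) {
    # OR over the available scores; indeterminate when undecidable
    pass <- mapply(function(s, t) !is.na(s) && s >= t, scores, thresholds)
    if (any(pass))
      list(p = TRUE, rules = paste0(label, ":", paste(names(scores)[pass],
                                                      collapse = "+")))
    else if (any(is.na(unlist(scores))))
      list(p = NA, rules = "")
    else list(p = FALSE, rules = "")
  }

  out <- lapply(seq_len(nrow(v)), function(i) {
    af <- v$population_af[i]
    cons <- v$consequence[i]
    if (!is.na(af) && af > af_cutoff)
      return(data.table::data.table(variant_id = v$variant_id[i],
                                    prioritized = FALSE, rules_fired = "",
                                    discard_reason = "allele_frequency"))
    if (cons %in% SNV_DIRECT_CONSEQUENCES) {
      res <- list(p = TRUE, rules = paste0("effect:", cons))
    } else if (cons %in% SNV_SPLICEAI_CONSEQUENCES) {
      s <- v$spliceai[i]
      res <- if (is.na(s)) list(p = NA, rules = "")
             else if (s >= spliceai_min) list(p = TRUE, rules = "spliceai")
             else list(p = FALSE, rules = "")
    } else if (cons == "missense") {
      res <- score_rule(list(phylop = v$phylop[i], cadd_phred = v$cadd_phred[i],
                             grantham = v$grantham[i]),
                        c(phylop_min, cadd_min, grantham_min), "missense")
    } else if (cons == "silent") {
      res <- score_rule(list(phylop = v$phylop[i], cadd_phred = v$cadd_phred[i]),
                        c(phylop_min, cadd_min), "silent")
    } else {
      res <- list(p = FALSE, rules = "")
    }
    data.table::data.table(
      variant_id = v$variant_id[i], prioritized = res$p,
      rules_fired = res$rules,
      discard_reason = if (isFALSE(res$p)) "no_rule_fired"
                       else if (is.na(res$p)) "missing_score" else NA_character_)
  })
  data.table::rbindlist(out)
}

#' Prioritize SVs/CNVs against a gene panel
#'
#' A non-inversion SV is prioritized when its in-house allele frequency is
#' at most `af_cutoff` and it fully spans at least one panel exon; an
#' inversion additionally requires at least one breakpoint inside a panel
#' gene body.
#'
#' @param svs data.frame: sv_id (optional), type
#'   (deletion/duplication/inversion/other), chrom, start, end, inhouse_af.
#' @param panel list with `exons` (data.frame chrom/start/end/gene) and
#'   `genes` (data.frame chrom/start/end/gene gene bodies).
#' @param af_cutoff Frequency gate (inclusive `<=` keeps).
#' @return data.table: sv_id, prioritized, rules_fired, discard_reason.
#' @export
prioritize_sv <- function(svs, panel, af_cutoff = 0.005) {
  v <- data.table::as.data.table(svs)
  if (!"sv_id" %in% names(v)) v[, sv_id := sprintf("sv_%d", .I)]
  ex <- panel$exons
  gb <- panel$genes
  out <- lapply(seq_len(nrow(v)), function(i) {
    if (v$inhouse_af[i] > af_cutoff)
      return(data.table::data.table(sv_id = v$sv_id[i], prioritized = FALSE,
                                    rules_fired = "",
                                    discard_reason = "allele_frequency"))
    if (v$type[i] == "inversion") {
      bp_in <- any(gb$chrom == v$chrom[i] &
                     ((gb$start <= v$start[i] & v$start[i] < gb$end) |
                        (gb$start <= v$end[i] & v$end[i] < gb$end)))
      if (bp_in)
        return(data.table::data.table(sv_id = v$sv_id[i], prioritized = TRUE,
                                      rules_fired = "inversion_breakpoint",
                                      discard_reason = NA_character_))
      return(data.table::data.table(sv_id = v$sv_id[i], prioritized = FALSE,
                                    rules_fired = "",
                                    discard_reason = "no_panel_breakpoint"))
    }
    spans <- any(ex$chrom == v$chrom[i] & v$start[i] <= ex$start &
                   ex$end <= v$end[i])
    if (spans)
      data.table::data.table(sv_id = v$sv_id[i], prioritized = TRUE,
                             rules_fired = "spans_panel_exon",
                             discard_reason = NA_character_)
    else
      data.table::data.table(sv_id = v$sv_id[i], prioritized = FALSE,
                             rules_fired = "",
                             discard_reason = "no_panel_exon_spanned")
  })
  data.table::rbindlist(out)
}
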