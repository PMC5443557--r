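#' Normalize effect sizes to the [-1, 1] interval
#'
#' Within one study, positive median-ratio fold changes are divided by the
#' study's largest positive value and negative ones by the absolute value
#' of the most negative, so upregulated genes land in `[0, 1]` and
#' downregulated genes in `[-1, 0]`.  This removes expression-ratio scale
#' bias between platforms before scores are compared across studies.
#'
#' @param logfc_m numeric vector of per-feature `logFC_m` values for one
#'   study.
#' @return Vector of the same length in `[-1, 1]`; zeros stay zero.
#' @export
normalize_effect_sizes <- function(logfc_m) {
  if (length(logfc_m) == 0L) stop("empty effect-size vector")
  out <- logfc_m
  pos <- logfc_m > 0
  neg <- logfc_m < 0
  if (any(pos)) out[pos] <- logfc_m[pos] / max(logfc_m[pos])
  if (any(neg)) out[neg] <- logfc_m[neg] / abs(min(logfc_m[neg]))
  out
}

#' Raw per-feature study score
#'
#' The gated score `s = n * r * gate`: the normalized effect size `n` is
#' weighted by the reliability ratio
#' `r = |logFC_m| / (|logFC_m| + c * MAD)`, which shrinks towards zero as
#' replicate scatter (MAD) grows relative to the effect, and zeroed
#' unless the feature passes both significance gates, `adj_p <= alpha`
#' and `B > 0`.  A feature with `logFC_m = 0` scores 0.
#'
#' @param n normalized effect size(s) from [normalize_effect_sizes()].
#' @param logfc_m median-ratio log2 fold change(s).
#' @param mad MAD reproducibility penalty input(s).
#' @param adj_p BH-adjusted p-value(s).
#' @param B empirical-Bayes log-odds of differential expression.
#' @param alpha significance gate on the adjusted p-value.
#' @param c weight of the MAD penalty in the reliability ratio.
#' @return Numeric score(s) in `[-1, 1]`, sharing the sign of `logfc_m`
#'   when non-zero.
#' @export
probe_score <- function(n, logfc_m, mad, adj_p, B, alpha = 0.05, c = 1) {
  stopifnot(is.finite(alpha), is.finite(c), c >= 0)
  r <- ifelse(logfc_m == 0, 0,
              abs(logfc_m) / (abs(logfc_m) + c * mad))
  gate <- as.numeric(adj_p <= alpha & B > 0)
  n * r * gate
}

#' Attach normalized effects, gates and raw scores to a probe table
#'
#' @param stats probe statistics table from [probe_stats()].
#' @inheritParams probe_score
#' @return `stats` with added columns `n`, `gate`, `s_raw`.
#' @export
score_probes <- function(stats, alpha = 0.05, c = 1) {
  stats$n <- normalize_effect_sizes(stats$logFC_m)
  stats$gate <- as.numeric(stats$adj_p <= alpha & stats$B > 0)
  stats$s_raw <- probe_score(stats$n, stats$logFC_m, stats$MAD,
                             stats$adj_p, stats$B, alpha = alpha, c = c)
  stats
}

#' Collapse probe-level rows to one row per gene
#'
#' When several probes map to the same gene the row of the probe with the
#' largest variance of normalized expression across all samples of both
#' phenotypes is kept.  Variance ties are broken by the lexicographically
#' smallest probe ID so results are platform- and order-independent.
#' Probes without a map entry are dropped (a message reports how many).
#'
#' @param stats probe-level table containing at least `probe_id` and
#'   `variance` columns.
#' @param probe_map data frame with columns `probe_id`, `gene_id`.
#' @return The table with one row per gene, `gene_id` first.
#' @export
collapse_probes_to_genes <- function(stats, probe_map) {
  merged <- merge(stats, probe_map[, c("probe_id", "gene_id")],
                  by = "probe_id")
  n_drop <- nrow(stats) - nrow(merged)
  if (n_drop > 0)
    message(n_drop, " probe(s) without a gene map entry dropped")
  if (nrow(merged) == 0L)
    stop("no probes in common between statistics table and probe map")
  merged <- merged[order(merged$gene_id, -merged$variance,
                         merged$probe_id), ]
  out <- merged[!duplicated(merged$gene_id), ]
  rownames(out) <- NULL
  out[, c("gene_id", setdiff(names(out), "gene_id"))]
}

#' Standardize raw scores within a study
#'
#' Divides every raw score by the study's maximum absolute raw score, so
#' each study contributes at most 1 in magnitude to the summed final
#' score.  Range standardization (rather than z-scoring) keeps zeroed
#' (gated) genes at exactly zero.  An all-zero vector is returned
#' unchanged.
#'
#' @param s_raw numeric vector of raw scores for one study.
#' @return Vector with `max(abs(.)) == 1` unless all zero.
#' @export
standardize_scores <- function(s_raw) {
  if (length(s_raw) == 0L) stop("empty score vector")
  m <- max(abs(s_raw))
  if (m == 0) return(s_raw)
  s_raw / m
}

#' Score one study end to end
#'
#' Convenience chain for a single study: optional ANOVA FDR prefilter,
#' per-probe statistics, effect-size normalization and gated scoring,
#' probe-to-gene collapse by maximal variance, and within-study score
#' standardization.
#'
#' @param study an [expression_study()].
#' @param alpha significance gate on the adjusted p-value.
#' @param c MAD penalty weight.
#' @param prefilter apply [anova_prefilter()] first?
#' @param fdr prefilter FDR threshold.
#' @param ... passed to [moderated_stats()] via [probe_stats()].
#' @return Per-gene study score table (`StudyScoreTable`): columns
#'   `gene_id`, `probe_id`, `logFC`, `logFC_m`, `MAD`, `t`, `p`, `adj_p`,
#'   `B`, `variance`, `n`, `gate`, `s_raw`, `s_std`; the study ID,
#'   species and filter counts are attached as attributes.
#' @export
score_study <- function(study, alpha = 0.05, c = 1, prefilter = TRUE,
                        fdr = 0.05, ...) {
  n_probes <- nrow(study$matrix)
  removed <- 0L
  if (prefilter) {
    study <- anova_prefilter(study, fdr = fdr)
    removed <- attr(study, "prefilter_removed")
    if (nrow(study$matrix) == 0L)
      stop("prefilter removed every probe in study '", study$study_id, "'")
  }
  st <- score_probes(probe_stats(study, ...), alpha = alpha, c = c)
  gt <- collapse_probes_to_genes(st, study$probe_map)
  gt$s_std <- standardize_scores(gt$s_raw)
  attr(gt, "study_id") <- study$study_id
  attr(gt, "species") <- study$species
  attr(gt, "n_probes") <- n_probes
  attr(gt, "prefilter_removed") <- removed
  gt
}
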