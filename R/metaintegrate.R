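#' Re-key a mouse study score table to human gene IDs
#'
#' Mouse gene IDs are translated to their human orthologs through a
#' user-supplied map.  Mouse genes without a map entry are dropped (a
#' message reports how many).  When several mouse genes map to the same
#' human gene the row whose underlying probe had the largest expression
#' variance is kept, mirroring the probe-collapse rule; variance ties
#' fall back to the smallest mouse gene ID.
#'
#' @param mouse_table per-gene study score table from [score_study()] for
#'   the mouse study.
#' @param ortholog_map data frame with columns `mouse_gene_id`,
#'   `human_gene_id`.
#' @return The score table keyed by human gene IDs.
#' @export
map_orthologs <- function(mouse_table, ortholog_map) {
  if (is.null(ortholog_map) || nrow(ortholog_map) == 0L)
    stop("empty ortholog map")
  if (!all(c("mouse_gene_id", "human_gene_id") %in% names(ortholog_map)))
    stop("ortholog map needs columns mouse_gene_id and human_gene_id")
  at <- attributes(mouse_table)
  merged <- merge(mouse_table, ortholog_map, by.x = "gene_id",
                  by.y = "mouse_gene_id")
  n_drop <- nrow(mouse_table) - nrow(merged)
  if (n_drop > 0)
    message(n_drop, " mouse gene(s) without a human ortholog dropped")
  merged <- merged[order(merged$human_gene_id, -merged$variance,
                         merged$gene_id), ]
  merged <- merged[!duplicated(merged$human_gene_id), ]
  merged$gene_id <- merged$human_gene_id
  merged$human_gene_id <- NULL
  rownames(merged) <- NULL
  for (a in c("study_id", "species", "n_probes", "prefilter_removed"))
    attr(merged, a) <- at[[a]]
  merged
}

#' Combine standardized per-study scores into final gene scores
#'
#' The final human score of a gene is the sum of its standardized scores
#' over the human studies in which it is represented.  Mouse data enter
#' only for genes whose final human score is non-null and shares the sign
#' of the mouse score; the mouse term is weighted by `mouse_weight`.
#' Genes observed exclusively in mouse are ignored.
#'
#' @param human_tables list of per-gene study score tables (human).
#' @param mouse_table optional mouse score table already keyed by human
#'   gene IDs (see [map_orthologs()]).
#' @param mouse_weight weight applied to the mouse score when included.
#' @return Data frame with columns `gene_id`, `score`, `studies` (number
#'   of contributing studies, mouse counted when included) and `mouse`
#'   (0/1 inclusion flag).  The per-study contribution matrix (genes x
#'   studies, `NA` where a gene is absent) is attached as attribute
#'   `contributions` for downstream bias statistics.
#' @export
combine_scores <- function(human_tables, mouse_table = NULL,
                           mouse_weight = 1) {
  if (length(human_tables) == 0L)
    stop("at least one human study score table required")
  genes <- sort(unique(unlist(lapply(human_tables, `[[`, "gene_id"))))
  contrib <- matrix(NA_real_, nrow = length(genes),
                    ncol = length(human_tables),
                    dimnames = list(genes, vapply(seq_along(human_tables),
                      function(j) {
                        id <- attr(human_tables[[j]], "study_id")
                        if (is.null(id)) paste0("human", j) else id
                      }, character(1))))
  for (j in seq_along(human_tables)) {
    tab <- human_tables[[j]]
    contrib[tab$gene_id, j] <- tab$s_std
  }
  s_human <- rowSums(contrib, na.rm = TRUE)
  n_human <- rowSums(!is.na(contrib))
  mouse_flag <- integer(length(genes))
  mouse_term <- numeric(length(genes))
  if (!is.null(mouse_table)) {
    ms <- mouse_table$s_std[match(genes, mouse_table$gene_id)]
    include <- !is.na(ms) & s_human != 0 & ms != 0 &
      sign(ms) == sign(s_human)
    mouse_flag[include] <- 1L
    mouse_term[include] <- mouse_weight * ms[include]
    mid <- attr(mouse_table, "study_id")
    contrib <- cbind(contrib, ifelse(mouse_flag == 1L, mouse_term, NA))
    colnames(contrib)[ncol(contrib)] <-
      if (is.null(mid)) "mouse" else mid
  }
  out <- data.frame(gene_id = genes, score = s_human + mouse_term,
                    studies = n_human + mouse_flag, mouse = mouse_flag,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contributions") <- contrib
  out
}

#' Cross-study median effect sizes with the mouse sign rule
#'
#' The final effect size of a gene is the median of its per-study values.
#' The mouse value joins the median only when its sign equals the sign of
#' the human median; otherwise it is ignored and the human median stands.
#'
#' @param human_values numeric vector of per-study human effect sizes
#'   (`logFC` or `logFC_m`) for one gene.
#' @param mouse_value optional mouse effect size for the gene.
#' @return The combined median.
#' @export
median_effect_size <- function(human_values, mouse_value = NA) {
  if (length(human_values) == 0L || all(is.na(human_values)))
    stop("at least one human effect size required")
  hv <- human_values[!is.na(human_values)]
  hmed <- stats::median(hv)
  if (!is.na(mouse_value) && sign(mouse_value) == sign(hmed) &&
      mouse_value != 0 && hmed != 0)
    stats::median(c(hv, mouse_value))
  else
    hmed
}

#' Bhattacharyya-distance ratio of study contributions
#'
#' Measures how unevenly the studies contribute to a gene's final score.
#' Absolute per-study scores are converted to a discrete distribution
#' `p_j = |s_j| / sum |s_j|` and compared with the uniform distribution
#' `q_j = 1/n` through the Bhattacharyya distance
#' `BD = -ln(sum_j sqrt(p_j q_j))`; the ratio divides by the maximum
#' attainable distance for `n` studies, `BD_max = ln(n)/2` (all mass on
#' one study).  Equal contributions give 0, a single dominating study
#' gives 1.  Genes represented in a single study are assigned 0 by
#' convention, distinguishing them from multi-study genes whose mass
#' happens to sit in one study (ratio 1); an all-zero vector also returns
#' 0.
#'
#' @param scores numeric vector of per-study scores for one gene, over
#'   the studies in which the gene is represented.
#' @return Ratio in `[0, 1]`.
#' @export
bd_ratio <- function(scores) {
  n <- length(scores)
  if (n == 0L) stop("no study scores supplied")
  if (n == 1L) return(0)
  tot <- sum(abs(scores))
  if (tot == 0) return(0)
  p <- abs(scores) / tot
  bc <- sum(sqrt(p / n))
  bd <- -log(min(bc, 1))
  min(max(bd / (log(n) / 2), 0), 1)
}

#' Build the unfiltered meta-analysis gene table
#'
#' Runs the cross-study integration for scored study tables: combines
#' standardized scores ([combine_scores()]), computes cross-study median
#' `logFC` and `logFC_m` with the mouse sign rule, and attaches the
#' Bhattacharyya-distance ratio of study contributions per gene.
#'
#' @inheritParams combine_scores
#' @return Data frame (one row per gene present in at least one human
#'   study) with columns `gene_id`, `score`, `logFC`, `logFC_m`,
#'   `studies`, `mouse`, `bd_ratio`.
#' @export
integrate_studies <- function(human_tables, mouse_table = NULL,
                              mouse_weight = 1) {
  comb <- combine_scores(human_tables, mouse_table,
                         mouse_weight = mouse_weight)
  contrib <- attr(comb, "contributions")
  genes <- comb$gene_id
  eff <- matrix(NA_real_, length(genes), length(human_tables))
  eff_m <- eff
  for (j in seq_along(human_tables)) {
    tab <- human_tables[[j]]
    idx <- match(genes, tab$gene_id)
    eff[, j] <- tab$logFC[idx]
    eff_m[, j] <- tab$logFC_m[idx]
  }
  mouse_eff <- mouse_eff_m <- rep(NA_real_, length(genes))
  if (!is.null(mouse_table)) {
    idx <- match(genes, mouse_table$gene_id)
    mouse_eff <- mouse_table$logFC[idx]
    mouse_eff_m <- mouse_table$logFC_m[idx]
  }
  comb$logFC <- vapply(seq_along(genes), function(i)
    median_effect_size(eff[i, ], mouse_eff[i]), numeric(1))
  comb$logFC_m <- vapply(seq_along(genes), function(i)
    median_effect_size(eff_m[i, ], mouse_eff_m[i]), numeric(1))
  comb$bd_ratio <- vapply(seq_along(genes), function(i) {
    s <- contrib[i, ]
    bd_ratio(s[!is.na(s)])
  }, numeric(1))
  out <- comb[, c("gene_id", "score", "logFC", "logFC_m", "studies",
                  "mouse", "bd_ratio")]
  attr(out, "contributions") <- contrib
  out
}

#' Sign-consistency screen (third filter)
#'
#' Removes genes whose final score sign disagrees with the sign of the
#' cross-study median `logFC`, and drops null-score genes from signature
#' candidacy.
#'
#' @param records meta table from [integrate_studies()].
#' @return The screened table.
#' @export
consistency_screen <- function(records) {
  stopifnot(all(c("score", "logFC") %in% names(records)))
  keep <- records$score != 0 & records$logFC != 0 &
    sign(records$score) == sign(records$logFC)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-percentile signature filter (fourth filter)
#'
#' From the sign-consistent candidate list, takes the top
#' `floor(top_frac * N)` positive-score genes by score and, symmetrically,
#' the bottom `floor(top_frac * N)` negative-score genes, then retains
#' only members with `|logFC| > min_abs_logfc`.  Rank ties are broken by
#' larger `|logFC|`, then by gene ID, so the cut is deterministic.
#'
#' @param records candidate table, already passed through
#'   [consistency_screen()].
#' @param top_frac fraction of each score sign taken before the fold
#'   change condition.
#' @param min_abs_logfc strict lower bound on `|logFC|` for signature
#'   membership.
#' @return `Signature`: the retained records sorted by decreasing score,
#'   with a `direction` column (`"up"`/`"down"`).
#' @export
final_signature_filter <- function(records, top_frac = 0.10,
                                   min_abs_logfc = 0.99) {
  stopifnot(top_frac > 0, top_frac <= 1)
  take_side <- function(side) {
    sub <- records[sign(records$score) == side, , drop = FALSE]
    k <- floor(top_frac * nrow(sub))
    if (k == 0L) return(sub[0, , drop = FALSE])
    ord <- order(-side * sub$score, -abs(sub$logFC), sub$gene_id)
    sub <- sub[ord[seq_len(k)], , drop = FALSE]
    sub[abs(sub$logFC) > min_abs_logfc, , drop = FALSE]
  }
  up <- take_side(1)
  down <- take_side(-1)
  out <- rbind(up, down)
  if (nrow(out) == 0L)
    warning("no genes satisfy the signature conditions: empty signature")
  out$direction <- ifelse(out$score > 0, "up", "down")
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("Signature", "data.frame")
  out
}

#' @export
print.Signature <- function(x, ...) {
  cat("Gene signature: ", nrow(x), " genes (",
      sum(x$direction == "up"), " up, ",
      sum(x$direction == "down"), " down)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Format a meta table the way the published signature tables print
#'
#' Rounds score and effect-size columns to two decimals and reports the
#' Bhattacharyya-distance ratio on the 0-100 scale.
#'
#' @param records meta table or signature.
#' @param bd_percent multiply `bd_ratio` by 100?
#' @param digits decimal places for score and fold-change columns.
#' @return A data frame ready for printing/export.
#' @export
format_meta_table <- function(records, bd_percent = TRUE, digits = 2) {
  out <- as.data.frame(records)
  for (col in intersect(c("score", "logFC", "logFC_m"), names(out)))
    out[[col]] <- round(out[[col]], digits)
  if ("bd_ratio" %in% names(out)) {
    if (bd_percent) out$bd_ratio <- out$bd_ratio * 100
    out$bd_ratio <- round(out$bd_ratio, digits)
  }
  out
}
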