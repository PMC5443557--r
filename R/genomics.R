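#' Chromosome arm/band enrichment by exact binomial tails
#'
#' For each chromosomal region (arm such as `17q`, or cytogenetic band
#' such as `17q25.1`), compares the number of signature genes observed in
#' the region with the expectation under the genome-wide frequency of the
#' region in the annotated universe, using the exact upper-tail binomial
#' probability `P(X >= x)` with `n` = signature size and `p` = universe
#' frequency of the region.  Expected frequencies are genome-wide at both
#' levels.  Genes lacking a band label still take part in arm-level tests
#' when the arm is known.
#'
#' @param signature_genes character vector of gene IDs.
#' @param annotation data frame with columns `gene_id`, `chromosome`,
#'   `arm`, `band` (band labels include the arm, e.g. `"q25.1"`).
#' @param level `"arm"` or `"band"`.
#' @return Data frame sorted by tail probability with columns `region`,
#'   `observed`, `expected_freq`, `n`, `p_tail`, `stars`.
#' @export
region_enrichment <- function(signature_genes, annotation,
                              level = c("arm", "band")) {
  level <- match.arg(level)
  if (is.null(annotation) || nrow(annotation) == 0L)
    stop("empty genome annotation universe")
  need <- c("gene_id", "chromosome", "arm", "band")
  if (!all(need %in% names(annotation)))
    stop("annotation needs columns ", paste(need, collapse = ", "))
  ann <- annotation
  ann <- ann[!is.na(if (level == "arm") ann$arm else ann$band), ,
             drop = FALSE]
  if (nrow(ann) == 0L) stop("empty genome annotation universe")
  ann$region <- if (level == "arm")
    paste0(ann$chromosome, ann$arm) else paste0(ann$chromosome, ann$band)
  sig <- unique(signature_genes)
  missing <- setdiff(sig, ann$gene_id)
  if (length(missing))
    message(length(missing), " signature gene(s) without ", level,
            " annotation dropped")
  sig <- setdiff(sig, missing)
  n <- length(sig)
  universe_n <- nrow(ann)
  region_total <- table(ann$region)
  region_obs <- table(factor(ann$region[ann$gene_id %in% sig],
                             levels = names(region_total)))
  p <- as.numeric(region_total) / universe_n
  x <- as.numeric(region_obs)
  p_tail <- stats::pbinom(x - 1, size = n, prob = p, lower.tail = FALSE)
  out <- data.frame(region = names(region_total), observed = x,
                    expected_freq = p, n = n, p_tail = p_tail,
                    stars = significance_stars(p_tail),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_tail, out$region), ]
}

#' Star labels for binomial tail probabilities
#'
#' Maps `P(X >= x)` to the conventional star annotation:
#' `****` below 1e-4, `***` below 1e-3, `**` below 0.01, `*` below 0.05,
#' empty otherwise.  The intervals are open, so a probability exactly on
#' a boundary falls into the less significant bin.
#'
#' @param p numeric vector of tail probabilities in `[0, 1]`.
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("tail probabilities must lie in [0, 1]")
  out <- character(length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 0.0001] <- "****"
  out
}

#' Promoter-hypermethylation silencing filter
#'
#' Selects candidate genes whose downregulation in the malignant tissue
#' could plausibly be driven by promoter hypermethylation: the gene must
#' have a negative malignant-vs-benign (MPNST vs. NF) score, expression
#' `logFC` strictly below `expr_logfc_below` in both the
#' malignant-vs-benign and malignant-vs-control comparisons, and a
#' promoter methylation log fold change strictly above `meth_logfc_above`
#' at adjusted p strictly below `meth_adjp_below`.  By default the
#' methylation condition must hold in both the `MPNST_vs_NF` and
#' `MPNST_vs_control` methylome comparisons; `require_both = FALSE`
#' relaxes this to either.
#'
#' @param meta_mpnst_nf meta table (columns `gene_id`, `score`, `logFC`)
#'   for the malignant-vs-benign expression comparison.
#' @param meta_mpnst_control meta table for the malignant-vs-control
#'   expression comparison.
#' @param methylation data frame with columns `gene_id`, `comparison`
#'   (values among `MPNST_vs_NF`, `MPNST_vs_control`, `NF_vs_control`),
#'   `meth_logfc`, `meth_adj_p`.
#' @param expr_logfc_below strict upper bound on expression `logFC`.
#' @param meth_logfc_above strict lower bound on methylation log fold
#'   change.
#' @param meth_adjp_below strict upper bound on methylation adjusted p.
#' @param require_both require the methylation condition in both tumor
#'   methylome comparisons (default) or in at least one.
#' @return Data frame of candidate genes (ordered by ascending score)
#'   with the expression and methylation statistics that qualified them.
#' @export
methylation_silencing_filter <- function(meta_mpnst_nf,
                                         meta_mpnst_control,
                                         methylation,
                                         expr_logfc_below = -0.5,
                                         meth_logfc_above = 1.5,
                                         meth_adjp_below = 0.1,
                                         require_both = TRUE) {
  for (nm in c("meta_mpnst_nf", "meta_mpnst_control")) {
    tab <- get(nm)
    if (is.null(tab) || !all(c("gene_id", "logFC") %in% names(tab)))
      stop("expression meta table '", nm, "' missing or malformed")
  }
  if (!all(c("gene_id", "comparison", "meth_logfc", "meth_adj_p") %in%
           names(methylation)))
    stop("methylation table needs columns gene_id, comparison, ",
         "meth_logfc, meth_adj_p")
  need_cmp <- c("MPNST_vs_NF", "MPNST_vs_control")
  absent <- setdiff(need_cmp, unique(methylation$comparison))
  if (length(absent) && (require_both || length(absent) == 2L))
    stop("methylation table lacks comparison(s): ",
         paste(absent, collapse = ", "))
  meth_pass <- function(cmp) {
    sub <- methylation[methylation$comparison == cmp &
                         !is.na(methylation$meth_logfc) &
                         !is.na(methylation$meth_adj_p) &
                         methylation$meth_logfc > meth_logfc_above &
                         methylation$meth_adj_p < meth_adjp_below, ]
    unique(sub$gene_id)
  }
  pass_nf <- meth_pass("MPNST_vs_NF")
  pass_ctrl <- meth_pass("MPNST_vs_control")
  meth_ok <- if (require_both) intersect(pass_nf, pass_ctrl) else
    union(pass_nf, pass_ctrl)
  expr_nf <- meta_mpnst_nf[meta_mpnst_nf$score < 0 &
                             meta_mpnst_nf$logFC < expr_logfc_below, ]
  ctrl_ok <- meta_mpnst_control$gene_id[
    meta_mpnst_control$logFC < expr_logfc_below]
  cand <- expr_nf[expr_nf$gene_id %in% intersect(meth_ok, ctrl_ok), ,
                  drop = FALSE]
  if (nrow(cand) == 0L) {
    out <- cand
    out$meth_logfc_mpnst_nf <- numeric(0)
    out$meth_adjp_mpnst_nf <- numeric(0)
    out$meth_logfc_mpnst_control <- numeric(0)
    out$meth_adjp_mpnst_control <- numeric(0)
    rownames(out) <- NULL
    return(out)
  }
  add_cmp <- function(df, cmp, suffix) {
    sub <- methylation[methylation$comparison == cmp, ]
    idx <- match(df$gene_id, sub$gene_id)
    df[[paste0("meth_logfc_", suffix)]] <- sub$meth_logfc[idx]
    df[[paste0("meth_adjp_", suffix)]] <- sub$meth_adj_p[idx]
    df
  }
  cand <- add_cmp(cand, "MPNST_vs_NF", "mpnst_nf")
  cand <- add_cmp(cand, "MPNST_vs_control", "mpnst_control")
  cand <- cand[order(cand$score, cand$gene_id), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}
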