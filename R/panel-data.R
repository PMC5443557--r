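#' Published MPNST promoter-hypermethylation panel
#'
#' Ships the published statistics of a 10-gene panel of malignant
#' peripheral nerve sheath tumor (MPNST) signature genes potentially
#' silenced by promoter hypermethylation: the RASSF1 tumor suppressor
#' (whose promoter hypermethylation in MPNST is an established control)
#' plus nine downregulated signature genes.  Per gene: the nerve-tumor
#' expression score and median logFC of the MPNST vs. NF (benign
#' neurofibroma) and MPNST vs. control comparisons, and the promoter
#' methylation log fold change and adjusted p-value of the MPNST vs. NF
#' and MPNST vs. control methylome comparisons (GEO series GSE21714).
#'
#' @param as in `"wide"` the table is returned as shipped; in `"filter"`
#'   it is reshaped into the three inputs of
#'   [methylation_silencing_filter()]: `meta_mpnst_nf`,
#'   `meta_mpnst_control` and a long `methylation` table.
#' @return A data frame (`"wide"`) or a list of three data frames
#'   (`"filter"`).
#' @export
hypermethylation_panel <- function(as = c("wide", "filter")) {
  as <- match.arg(as)
  path <- system.file("extdata", "mpnst_hypermethylation_panel.tsv",
                      package = "scoremeta", mustWork = TRUE)
  wide <- .read_tsv(path)
  if (as == "wide") return(wide)
  meta_nf <- data.frame(gene_id = wide$gene_id, symbol = wide$symbol,
                        score = wide$score_mpnst_nf,
                        logFC = wide$logfc_mpnst_nf,
                        stringsAsFactors = FALSE)
  meta_ctrl <- data.frame(gene_id = wide$gene_id, symbol = wide$symbol,
                          score = wide$score_mpnst_control,
                          logFC = wide$logfc_mpnst_control,
                          stringsAsFactors = FALSE)
  methylation <- rbind(
    data.frame(gene_id = wide$gene_id, comparison = "MPNST_vs_NF",
               meth_logfc = wide$meth_logfc_mpnst_nf,
               meth_adj_p = wide$meth_adjp_mpnst_nf,
               stringsAsFactors = FALSE),
    data.frame(gene_id = wide$gene_id, comparison = "MPNST_vs_control",
               meth_logfc = wide$meth_logfc_mpnst_control,
               meth_adj_p = wide$meth_adjp_mpnst_control,
               stringsAsFactors = FALSE))
  list(meta_mpnst_nf = meta_nf, meta_mpnst_control = meta_ctrl,
       methylation = methylation)
}
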