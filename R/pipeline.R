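#' Run the meta-analysis on in-memory studies
#'
#' Executes the full chain: per-study ANOVA FDR prefilter, per-probe
#' statistics, effect normalization and gated scoring, probe-to-gene
#' collapse, within-study standardization, ortholog mapping of the mouse
#' study, cross-study score combination with the mouse sign rule, median
#' effect sizes, Bhattacharyya-distance ratios, the sign-consistency
#' screen and the top-percentile signature filter; then, when an
#' annotation is supplied, arm- and band-level enrichment of the up- and
#' downregulated signature halves, and, when a methylation table is
#' supplied, the promoter-hypermethylation silencing filter.
#'
#' With a methylation table but no `meta_control` table the pipeline
#' applies the malignant-vs-control expression condition to the same
#' comparison's meta table (single-comparison mode) and says so in the
#' run log.
#'
#' @param studies list of [expression_study()] objects (at most one
#'   mouse study).
#' @param ortholog_map data frame (`mouse_gene_id`, `human_gene_id`);
#'   required when a mouse study is present.
#' @param annotation optional genome annotation data frame.
#' @param methylation optional methylation statistics data frame.
#' @param meta_control optional meta table of the malignant-vs-control
#'   expression comparison, used by the methylation filter.
#' @param alpha significance gate on adjusted p-values in the score.
#' @param c_penalty MAD penalty weight in the reliability ratio.
#' @param prefilter apply the ANOVA FDR prefilter per study?
#' @param fdr prefilter FDR threshold.
#' @param top_frac signature percentile per score sign.
#' @param min_abs_logfc strict `|logFC|` bound for signature membership.
#' @param mouse_weight weight of the included mouse score.
#' @param meth_args named list of overrides for
#'   [methylation_silencing_filter()] thresholds.
#' @return List with elements `study_tables`, `meta` (unfiltered gene
#'   table), `screened`, `signature`, `enrichment` (list of arm/band
#'   tables for up and down, or `NULL`), `methylation_candidates` (or
#'   `NULL`) and `log` (named list of stage counts and notes).
#' @export
run_meta_analysis <- function(studies, ortholog_map = NULL,
                              annotation = NULL, methylation = NULL,
                              meta_control = NULL,
                              alpha = 0.05, c_penalty = 1,
                              prefilter = TRUE, fdr = 0.05,
                              top_frac = 0.10, min_abs_logfc = 0.99,
                              mouse_weight = 1, meth_args = list()) {
  stopifnot(length(studies) >= 1)
  species <- vapply(studies, `[[`, character(1), "species")
  if (sum(species == "mouse") > 1L)
    stop("at most one mouse study is supported")
  if (!any(species == "human"))
    stop("at least one human study is required")
  log <- list(notes = character(0))
  tables <- lapply(studies, score_study, alpha = alpha, c = c_penalty,
                   prefilter = prefilter, fdr = fdr)
  names(tables) <- vapply(studies, `[[`, character(1), "study_id")
  log$probes_read <- sum(vapply(tables, attr, numeric(1), "n_probes"))
  log$probes_removed_prefilter <-
    sum(vapply(tables, attr, numeric(1), "prefilter_removed"))
  log$genes_after_collapse <- sum(vapply(tables, nrow, integer(1)))
  human_tables <- tables[species == "human"]
  mouse_table <- NULL
  if (any(species == "mouse")) {
    if (is.null(ortholog_map))
      stop("a mouse study requires an ortholog map")
    mouse_table <- map_orthologs(tables[[which(species == "mouse")]],
                                 ortholog_map)
  }
  meta <- integrate_studies(human_tables, mouse_table,
                            mouse_weight = mouse_weight)
  log$genes_meta <- nrow(meta)
  log$genes_nonnull_score <- sum(meta$score != 0)
  screened <- consistency_screen(meta)
  log$genes_after_consistency <- nrow(screened)
  signature <- final_signature_filter(screened, top_frac = top_frac,
                                      min_abs_logfc = min_abs_logfc)
  log$signature_up <- sum(signature$direction == "up")
  log$signature_down <- sum(signature$direction == "down")
  enrichment <- NULL
  if (!is.null(annotation)) {
    enrichment <- list()
    for (dirn in c("up", "down")) {
      genes <- signature$gene_id[signature$direction == dirn]
      for (lvl in c("arm", "band")) {
        enrichment[[paste(dirn, lvl, sep = "_")]] <-
          if (length(genes)) region_enrichment(genes, annotation, lvl)
      }
    }
  }
  meth_cand <- NULL
  if (!is.null(methylation)) {
    ctrl <- meta_control
    if (is.null(ctrl)) {
      ctrl <- meta
      log$notes <- c(log$notes,
        "single-comparison mode: malignant-vs-control expression condition applied to the same meta table")
    }
    meth_cand <- do.call(methylation_silencing_filter,
                         c(list(meta_mpnst_nf = meta,
                                meta_mpnst_control = ctrl,
                                methylation = methylation), meth_args))
    log$methylation_candidates <- nrow(meth_cand)
  }
  list(study_tables = tables, meta = meta, screened = screened,
       signature = signature, enrichment = enrichment,
       methylation_candidates = meth_cand, log = log)
}

#' Run the pipeline from a configuration file or object
#'
#' Reads every input table named in the configuration, calls
#' [run_meta_analysis()] and writes the per-study statistics and score
#' tables, the unfiltered meta table, the signature, the enrichment
#' tables, the methylation candidates and a run log under the
#' configured output directory.  With a fixed configuration the outputs
#' are bit-identical between runs.
#'
#' @param config a `PipelineConfig` from [read_pipeline_config()] or a
#'   path to a YAML configuration file.
#' @return The [run_meta_analysis()] result list, invisibly, with the
#'   output directory attached as attribute `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  studies <- lapply(config$studies, function(s)
    read_expression_study(s$matrix, s$samples, s$probe_map,
                          species = if (is.null(s$species)) "human"
                                    else s$species,
                          study_id = s$study_id, case = s$case))
  ortho <- if (!is.null(config$ortholog_map))
    read_ortholog_map(config$ortholog_map)
  ann <- if (!is.null(config$annotation))
    read_genome_annotation(config$annotation)
  meth <- if (!is.null(config$methylation))
    read_methylation_table(config$methylation)
  ctrl <- if (!is.null(config$meta_control))
    .read_tsv(config$meta_control)
  get_par <- function(name, default)
    if (is.null(config[[name]])) default else config[[name]]
  res <- run_meta_analysis(
    studies, ortholog_map = ortho, annotation = ann, methylation = meth,
    meta_control = ctrl,
    alpha = get_par("alpha", 0.05),
    c_penalty = get_par("c_penalty", 1),
    prefilter = get_par("prefilter", TRUE),
    fdr = get_par("fdr", 0.05),
    top_frac = get_par("top_frac", 0.10),
    min_abs_logfc = get_par("min_abs_logfc", 0.99),
    mouse_weight = get_par("mouse_weight", 1))
  outdir <- get_par("outdir", "scoremeta_out")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  for (nm in names(res$study_tables))
    write_tsv(res$study_tables[[nm]],
              file.path(outdir, paste0(nm, "_gene_scores.tsv")))
  write_tsv(res$meta, file.path(outdir, "meta_table.tsv"))
  write_tsv(as.data.frame(res$signature),
            file.path(outdir, "signature.tsv"))
  write_tsv(format_meta_table(res$signature,
                              bd_percent = get_par("report_bd_percent",
                                                   TRUE)),
            file.path(outdir, "signature_report.tsv"))
  if (!is.null(res$enrichment))
    for (nm in names(res$enrichment))
      if (!is.null(res$enrichment[[nm]]))
        write_tsv(res$enrichment[[nm]],
                  file.path(outdir, paste0("enrichment_", nm, ".tsv")))
  if (!is.null(res$methylation_candidates))
    write_tsv(res$methylation_candidates,
              file.path(outdir, "methylation_candidates.tsv"))
  log_lines <- c(
    vapply(setdiff(names(res$log), "notes"),
           function(k) paste0(k, "\t", res$log[[k]]), character(1)),
    res$log$notes)
  writeLines(log_lines, file.path(outdir, "run_log.tsv"))
  attr(res, "outdir") <- outdir
  invisible(res)
}
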