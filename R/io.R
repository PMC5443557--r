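# All tables are tab-separated with a single header row; missing values
# are written as "NA".

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a table in the package's TSV convention
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an expression study from TSV files
#'
#' The matrix file has probe IDs in the first column and one column per
#' sample; the sample sheet has columns `sample_id` and `group`; the
#' probe map has columns `probe_id` and `gene_id`.  Validation errors
#' name the offending probe or sample.
#'
#' @param matrix_path,samples_path,probe_map_path file paths.
#' @param species `"human"` or `"mouse"`.
#' @param study_id study identifier.
#' @param case optional case phenotype name (defaults to the first group
#'   in the sample sheet).
#' @return An [expression_study()].
#' @export
read_expression_study <- function(matrix_path, samples_path,
                                  probe_map_path,
                                  species = c("human", "mouse"),
                                  study_id = "study", case = NULL) {
  species <- match.arg(species)
  raw <- .read_tsv(matrix_path)
  probes <- as.character(raw[[1]])
  dup <- unique(probes[duplicated(probes)])
  if (length(dup))
    stop("duplicated probe row(s) in ", matrix_path, ": ",
         paste(dup, collapse = ", "))
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat))
    stop("non-numeric expression values in ", matrix_path)
  rownames(mat) <- probes
  sheet <- .read_tsv(samples_path)
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop("sample sheet needs columns sample_id and group")
  absent <- setdiff(sheet$sample_id, colnames(mat))
  if (length(absent))
    stop("sample(s) in sheet but not in matrix: ",
         paste(absent, collapse = ", "))
  mat <- mat[, as.character(sheet$sample_id), drop = FALSE]
  pm <- .read_tsv(probe_map_path)
  if (is.null(case)) case <- as.character(sheet$group[1])
  expression_study(mat, groups = sheet$group, probe_map = pm,
                   species = species, study_id = study_id, case = case)
}

#' Write an expression study to TSV files
#'
#' Creates `<study_id>_matrix.tsv`, `<study_id>_samples.tsv` and
#' `<study_id>_probe_map.tsv` under `dir`, in the formats
#' [read_expression_study()] reads.
#'
#' @param study an [expression_study()].
#' @param dir output directory (created if absent).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_expression_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, study$study_id)
  mat <- data.frame(probe_id = rownames(study$matrix),
                    study$matrix, check.names = FALSE,
                    stringsAsFactors = FALSE)
  paths <- c(matrix = paste0(base, "_matrix.tsv"),
             samples = paste0(base, "_samples.tsv"),
             probe_map = paste0(base, "_probe_map.tsv"))
  write_tsv(mat, paths["matrix"])
  write_tsv(data.frame(sample_id = colnames(study$matrix),
                       group = as.character(study$groups)),
            paths["samples"])
  write_tsv(study$probe_map, paths["probe_map"])
  invisible(paths)
}

#' Read a genome annotation table
#' @param path TSV with columns `gene_id`, `chromosome`, `arm`, `band`.
#' @return Data frame.
#' @export
read_genome_annotation <- function(path) {
  ann <- .read_tsv(path)
  need <- c("gene_id", "chromosome", "arm", "band")
  if (!all(need %in% names(ann)))
    stop("annotation file needs columns ", paste(need, collapse = ", "))
  ann$chromosome <- as.character(ann$chromosome)
  ann
}

#' Read a promoter methylation statistics table
#' @param path TSV with columns `gene_id`, `comparison`, `meth_logfc`,
#'   `meth_adj_p`.
#' @return Data frame.
#' @export
read_methylation_table <- function(path) {
  meth <- .read_tsv(path)
  need <- c("gene_id", "comparison", "meth_logfc", "meth_adj_p")
  if (!all(need %in% names(meth)))
    stop("methylation file needs columns ", paste(need, collapse = ", "))
  meth
}

#' Read a mouse-to-human ortholog map
#' @param path TSV with columns `mouse_gene_id`, `human_gene_id`.
#' @return Data frame.
#' @export
read_ortholog_map <- function(path) {
  map <- .read_tsv(path)
  if (!all(c("mouse_gene_id", "human_gene_id") %in% names(map)))
    stop("ortholog map needs columns mouse_gene_id and human_gene_id")
  map
}

#' Read a pipeline configuration file
#'
#' YAML key-value format.  Top-level keys: `studies` (list of entries
#' with `study_id`, `species`, `matrix`, `samples`, `probe_map`,
#' optional `case`), optional `ortholog_map`, `annotation`,
#' `methylation`, `meta_control` paths, an `outdir`, a `seed`, and any
#' of the threshold parameters accepted by [run_meta_analysis()]
#' (`alpha`, `c_penalty`, `fdr`, `prefilter`, `top_frac`,
#' `min_abs_logfc`, `mouse_weight`, `report_bd_percent`).  Relative
#' paths are resolved against the config file's directory.
#'
#' @param path YAML file.
#' @return A `PipelineConfig` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$studies) || length(cfg$studies) == 0L)
    stop("config must list at least one study")
  base <- dirname(normalizePath(path))
  resolve <- function(p)
    if (is.null(p) || file.exists(p)) p else file.path(base, p)
  cfg$studies <- lapply(cfg$studies, function(s) {
    for (k in c("matrix", "samples", "probe_map")) {
      if (is.null(s[[k]])) stop("study entry missing '", k, "' path")
      s[[k]] <- resolve(s[[k]])
    }
    s
  })
  for (k in c("ortholog_map", "annotation", "methylation", "meta_control"))
    cfg[[k]] <- resolve(cfg[[k]])
  n_mouse <- sum(vapply(cfg$studies,
                        function(s) identical(s$species, "mouse"),
                        logical(1)))
  if (n_mouse > 1L) stop("at most one mouse study is supported")
  class(cfg) <- "PipelineConfig"
  cfg
}
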