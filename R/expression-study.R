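#' Construct an expression study
#'
#' Bundles one study of a two-phenotype comparison: a normalized log2
#' intensity matrix (probes in rows, samples in columns), the phenotype
#' label of each sample, the species and a probe-to-gene map.  The first
#' level of the group factor is treated as the case (numerator) phenotype
#' throughout: positive log fold changes mean higher expression in the
#' case group.
#'
#' @param matrix numeric matrix of log2 intensities with unique row names
#'   (probe IDs) and column names (sample IDs).
#' @param groups character or factor of length `ncol(matrix)` assigning
#'   each sample to one of exactly two phenotypes.
#' @param probe_map data frame with columns `probe_id` and `gene_id`.
#' @param species `"human"` or `"mouse"`.
#' @param study_id short identifier for the study.
#' @param case optional name of the case phenotype; defaults to the first
#'   level of `groups` in order of appearance.
#' @return An object of class `ExpressionStudy`.
#' @export
expression_study <- function(matrix, groups, probe_map,
                             species = c("human", "mouse"),
                             study_id = "study", case = NULL) {
  species <- match.arg(species)
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("'matrix' must be a numeric matrix of log2 intensities")
  if (is.null(rownames(matrix)))
    stop("'matrix' must have probe IDs as row names")
  dup <- rownames(matrix)[duplicated(rownames(matrix))]
  if (length(dup))
    stop("duplicated probe ID(s) in study '", study_id, "': ",
         paste(unique(dup), collapse = ", "))
  if (anyNA(matrix))
    stop("expression matrix contains missing values")
  if (length(groups) != ncol(matrix))
    stop("'groups' must assign a phenotype to every sample column")
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L)
    stop("exactly two phenotype groups required, found ", length(lev),
         ": ", paste(lev, collapse = ", "))
  if (!is.null(case)) {
    if (!case %in% lev) stop("case group '", case, "' not among groups")
    lev <- c(case, setdiff(lev, case))
  }
  groups <- factor(groups, levels = lev)
  if (any(table(groups) == 0L)) stop("both phenotype groups must be non-empty")
  if (!is.data.frame(probe_map) ||
      !all(c("probe_id", "gene_id") %in% names(probe_map)))
    stop("'probe_map' needs columns probe_id and gene_id")
  probe_map <- data.frame(probe_id = as.character(probe_map$probe_id),
                          gene_id = as.character(probe_map$gene_id),
                          stringsAsFactors = FALSE)
  structure(list(study_id = study_id, species = species,
                 matrix = matrix, groups = groups, probe_map = probe_map),
            class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  tab <- table(x$groups)
  cat("ExpressionStudy '", x$study_id, "' (", x$species, ")\n", sep = "")
  cat("  ", nrow(x$matrix), " probes x ", ncol(x$matrix), " samples; groups: ",
      paste(names(tab), tab, sep = "=", collapse = ", "),
      " (case = ", levels(x$groups)[1], ")\n", sep = "")
  invisible(x)
}

# split the matrix into case (A) and reference (B) sample blocks
.study_blocks <- function(study) {
  g <- study$groups
  list(A = study$matrix[, g == levels(g)[1], drop = FALSE],
       B = study$matrix[, g == levels(g)[2], drop = FALSE])
}
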