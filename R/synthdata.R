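#' Configuration for the synthetic multi-study generator
#'
#' Defaults describe the emulated study design: four human studies plus
#' one mouse study on different platforms, 1000 genes of which 10% are
#' planted as differential with log2 effects between 2 and 4, five
#' replicates per phenotype group and per-replicate Gaussian noise of
#' 0.5 on the log2 scale.
#'
#' @param n_genes size of the gene universe.
#' @param n_studies_human number of human studies.
#' @param include_mouse add a mouse study connected via an ortholog map?
#' @param probes_per_gene_range integer interval for the number of probes
#'   per gene on each platform.
#' @param platform_coverage fraction of the gene universe present on each
#'   study's platform.
#' @param n_replicates_per_group samples per phenotype group per study.
#' @param frac_de fraction of genes planted as differentially expressed.
#' @param effect_size_range interval of planted absolute log2 effects.
#' @param noise_sd per-replicate standard deviation on the log2 scale.
#' @param mouse_signflip_frac fraction of planted genes whose mouse
#'   effect sign is flipped relative to human.
#' @param seed integer seed; identical seeds give bit-identical outputs.
#' @return A validated `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_genes = 1000, n_studies_human = 4,
                             include_mouse = TRUE,
                             probes_per_gene_range = c(1, 3),
                             platform_coverage = 0.8,
                             n_replicates_per_group = 5,
                             frac_de = 0.1,
                             effect_size_range = c(2, 4),
                             noise_sd = 0.5,
                             mouse_signflip_frac = 0.1,
                             seed = 1) {
  stopifnot(n_genes >= 1, n_studies_human >= 1,
            n_replicates_per_group >= 1,
            length(probes_per_gene_range) == 2,
            probes_per_gene_range[1] >= 1,
            probes_per_gene_range[2] >= probes_per_gene_range[1],
            platform_coverage > 0, platform_coverage <= 1,
            frac_de >= 0, frac_de <= 1,
            length(effect_size_range) == 2, effect_size_range[1] > 0,
            effect_size_range[2] >= effect_size_range[1],
            noise_sd >= 0,
            mouse_signflip_frac >= 0, mouse_signflip_frac <= 1)
  structure(list(n_genes = n_genes, n_studies_human = n_studies_human,
                 include_mouse = include_mouse,
                 probes_per_gene_range = as.integer(probes_per_gene_range),
                 platform_coverage = platform_coverage,
                 n_replicates_per_group = n_replicates_per_group,
                 frac_de = frac_de,
                 effect_size_range = effect_size_range,
                 noise_sd = noise_sd,
                 mouse_signflip_frac = mouse_signflip_frac,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Generate a synthetic multi-study, multi-species study set
#'
#' Emulates the statistical structure the meta-analysis assumes: each
#' study has its own probe universe covering roughly
#' `platform_coverage` of the genes, one to several probes per gene
#' (probe-specific baseline offsets make the max-variance collapse
#' meaningful), two phenotype groups whose means differ by the planted
#' log2 effect for differential genes and by zero otherwise, and i.i.d.
#' Gaussian replicate noise.  The optional mouse study carries the same
#' effect magnitudes under mouse gene IDs linked by a 1:1 ortholog map,
#' with a configurable fraction of planted genes flipped in sign.
#' Expression is generated on the log2 scale with gene baselines drawn
#' uniformly in `[5, 10]`.
#'
#' @param config a [synthetic_config()].
#' @return List with elements `studies` (list of [expression_study()];
#'   the mouse study last when present), `truth` (the planted ledger:
#'   `gene_id`, `status` in up/down/null, `human_effect`, `mouse_effect`,
#'   `mouse_flipped`) and `ortholog_map` (`mouse_gene_id`,
#'   `human_gene_id`; `NULL` without a mouse study).
#' @export
generate_study_set <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  n_de <- round(config$frac_de * config$n_genes)
  if (config$frac_de > 0 && n_de == 0)
    stop("frac_de > 0 but no gene qualifies: increase n_genes or frac_de")
  status <- rep("null", config$n_genes)
  de_idx <- sample.int(config$n_genes, n_de)
  dir <- sample(c(1, -1), n_de, replace = TRUE)
  status[de_idx] <- ifelse(dir > 0, "up", "down")
  effect <- numeric(config$n_genes)
  effect[de_idx] <- dir * stats::runif(n_de, config$effect_size_range[1],
                                       config$effect_size_range[2])
  flipped <- rep(FALSE, config$n_genes)
  n_flip <- round(config$mouse_signflip_frac * n_de)
  if (n_flip > 0) flipped[sample(de_idx, n_flip)] <- TRUE
  mouse_effect <- ifelse(flipped, -effect, effect)
  truth <- data.frame(gene_id = genes, status = status,
                      human_effect = effect, mouse_effect = mouse_effect,
                      mouse_flipped = flipped,
                      stringsAsFactors = FALSE)
  ortho <- NULL
  mouse_genes <- paste0("m", genes)
  if (config$include_mouse)
    ortho <- data.frame(mouse_gene_id = mouse_genes,
                        human_gene_id = genes, stringsAsFactors = FALSE)
  n_total <- config$n_studies_human + as.integer(config$include_mouse)
  studies <- vector("list", n_total)
  for (j in seq_len(n_total)) {
    is_mouse <- config$include_mouse && j == n_total
    sid <- if (is_mouse) "mouse1" else sprintf("human%d", j)
    covered <- sort(sample.int(config$n_genes,
                               max(1, round(config$platform_coverage *
                                              config$n_genes))))
    npro <- sample(seq(config$probes_per_gene_range[1],
                       config$probes_per_gene_range[2]),
                   length(covered), replace = TRUE)
    gene_of_probe <- rep(covered, npro)
    probe_ids <- sprintf("%s_P%05d", sid, seq_along(gene_of_probe))
    ids <- if (is_mouse) mouse_genes else genes
    probe_map <- data.frame(probe_id = probe_ids,
                            gene_id = ids[gene_of_probe],
                            stringsAsFactors = FALSE)
    eff <- if (is_mouse) mouse_effect else effect
    baseline <- stats::runif(config$n_genes, 5, 10)
    probe_offset <- stats::rnorm(length(probe_ids), 0, 0.3)
    nrep <- config$n_replicates_per_group
    mu_case <- baseline[gene_of_probe] + probe_offset + eff[gene_of_probe]
    mu_ref <- baseline[gene_of_probe] + probe_offset
    mat <- cbind(
      matrix(rep(mu_case, nrep), ncol = nrep),
      matrix(rep(mu_ref, nrep), ncol = nrep))
    if (config$noise_sd > 0)
      mat <- mat + matrix(stats::rnorm(length(mat), 0, config$noise_sd),
                          nrow = nrow(mat))
    rownames(mat) <- probe_ids
    colnames(mat) <- paste0(sid, "_", rep(c("MPNST", "NF"), each = nrep),
                            seq_len(2 * nrep))
    studies[[j]] <- expression_study(
      mat, groups = rep(c("MPNST", "NF"), each = nrep),
      probe_map = probe_map,
      species = if (is_mouse) "mouse" else "human",
      study_id = sid, case = "MPNST")
  }
  list(studies = studies, truth = truth, ortholog_map = ortho)
}

#' Generate a synthetic genome annotation table
#'
#' Assigns every gene a chromosome, an arm (p/q) and a cytogenetic band
#' label, reproducibly from the seed.  Useful for exercising the
#' chromosome-region enrichment test.
#'
#' @param genes character vector of unique gene IDs.
#' @param n_chromosomes number of chromosomes to draw from.
#' @param seed integer seed.
#' @return Data frame with columns `gene_id`, `chromosome`, `arm`,
#'   `band`.
#' @export
generate_genome_annotation <- function(genes, n_chromosomes = 23,
                                       seed = 1) {
  if (length(genes) == 0L) stop("empty gene list")
  if (anyDuplicated(genes))
    stop("duplicate gene IDs in annotation input")
  set.seed(as.integer(seed))
  n <- length(genes)
  chrom <- sample.int(n_chromosomes, n, replace = TRUE)
  arm <- sample(c("p", "q"), n, replace = TRUE)
  band <- paste0(arm, sample(1:3, n, replace = TRUE), ".",
                 sample(1:3, n, replace = TRUE))
  data.frame(gene_id = genes, chromosome = as.character(chrom),
             arm = arm, band = band, stringsAsFactors = FALSE)
}

#' Generate a synthetic promoter-methylation statistics table
#'
#' Emulates the pre-computed methylome comparison statistics the
#' silencing filter consumes: a stated fraction of the planted
#' downregulated genes receive a hypermethylated promoter (methylation
#' log fold change above 1.5 at adjusted p below 0.1) in both the
#' `MPNST_vs_NF` and `MPNST_vs_control` comparisons; all other entries
#' get null-like values, and the `NF_vs_control` comparison is null
#' throughout.
#'
#' @param truth planted-truth ledger from [generate_study_set()].
#' @param frac_hypermethylated_of_down fraction of planted-down genes
#'   given a hypermethylated promoter.
#' @param seed integer seed.
#' @return Data frame with columns `gene_id`, `comparison`,
#'   `meth_logfc`, `meth_adj_p`.
#' @export
generate_methylation_table <- function(truth,
                                       frac_hypermethylated_of_down = 0.5,
                                       seed = 1) {
  stopifnot(is.data.frame(truth), "status" %in% names(truth),
            frac_hypermethylated_of_down >= 0,
            frac_hypermethylated_of_down <= 1)
  set.seed(as.integer(seed))
  down <- truth$gene_id[truth$status == "down"]
  n_hyper <- round(frac_hypermethylated_of_down * length(down))
  hyper <- if (n_hyper > 0) sample(down, n_hyper) else character(0)
  one_cmp <- function(cmp, hyper_set) {
    n <- nrow(truth)
    is_h <- truth$gene_id %in% hyper_set
    data.frame(gene_id = truth$gene_id, comparison = cmp,
               meth_logfc = ifelse(is_h, stats::runif(n, 2, 4),
                                   stats::rnorm(n, 0, 0.3)),
               meth_adj_p = ifelse(is_h, stats::runif(n, 1e-6, 0.05),
                                   stats::runif(n, 0.2, 1)),
               stringsAsFactors = FALSE)
  }
  rbind(one_cmp("MPNST_vs_NF", hyper),
        one_cmp("MPNST_vs_control", hyper),
        one_cmp("NF_vs_control", character(0)))
}
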