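test_that("configuration validation rejects out-of-range settings", {
  expect_s3_class(synthetic_config(), "SyntheticConfig")
  expect_error(synthetic_config(frac_de = 1.5))
  expect_error(synthetic_config(platform_coverage = 0))
  expect_error(synthetic_config(effect_size_range = c(0, 2)))
  expect_error(synthetic_config(n_genes = 0))
  # frac_de > 0 that rounds to zero planted genes is a config error
  expect_error(generate_study_set(synthetic_config(n_genes = 4,
                                                   frac_de = 0.1)),
               "no gene qualifies")
})

test_that("identical seeds give bit-identical study sets", {
  cfg <- synthetic_config(n_genes = 60, n_studies_human = 2,
                          n_replicates_per_group = 3, seed = 19)
  a <- generate_study_set(cfg)
  b <- generate_study_set(cfg)
  expect_identical(a$truth, b$truth)
  for (j in seq_along(a$studies))
    expect_identical(a$studies[[j]]$matrix, b$studies[[j]]$matrix)
  expect_identical(a$ortholog_map, b$ortholog_map)
})

test_that("zero-noise generation reproduces planted effects exactly through the effect-size chain", {
  cfg <- synthetic_config(n_genes = 40, n_studies_human = 1,
                          include_mouse = FALSE, platform_coverage = 1,
                          n_replicates_per_group = 3, frac_de = 0.25,
                          effect_size_range = c(1, 4), noise_sd = 0,
                          seed = 23)
  gen <- generate_study_set(cfg)
  st <- gen$studies[[1]]
  g <- st$groups
  for (k in seq_len(nrow(st$matrix))) {
    gene <- st$probe_map$gene_id[match(rownames(st$matrix)[k],
                                       st$probe_map$probe_id)]
    planted <- gen$truth$human_effect[gen$truth$gene_id == gene]
    a <- st$matrix[k, g == "MPNST"]; b <- st$matrix[k, g == "NF"]
    expect_equal(compute_logfc(a, b), planted, tolerance = 1e-12)
    expect_equal(compute_logfc_m(a, b), planted, tolerance = 1e-12)
    expect_equal(compute_mad(a, b), 0, tolerance = 1e-12)
  }
})

test_that("the planted-truth ledger counts and covers every mapped gene", {
  cfg <- synthetic_config(n_genes = 1000, frac_de = 0.1, seed = 7,
                          n_studies_human = 2,
                          n_replicates_per_group = 2)
  gen <- generate_study_set(cfg)
  expect_equal(sum(gen$truth$status != "null"), 100)
  # every gene of every study's probe map appears in the ledger
  ledger_ids <- c(gen$truth$gene_id, paste0("m", gen$truth$gene_id))
  for (st in gen$studies)
    expect_true(all(st$probe_map$gene_id %in% ledger_ids))
  # mouse study is linked through the ortholog map
  mouse <- gen$studies[[length(gen$studies)]]
  expect_equal(mouse$species, "mouse")
  expect_true(all(mouse$probe_map$gene_id %in%
                    gen$ortholog_map$mouse_gene_id))
  # sign flips only affect planted genes
  expect_true(all(gen$truth$status[gen$truth$mouse_flipped] != "null"))
  expect_equal(gen$truth$mouse_effect[!gen$truth$mouse_flipped],
               gen$truth$human_effect[!gen$truth$mouse_flipped])
  expect_equal(gen$truth$mouse_effect[gen$truth$mouse_flipped],
               -gen$truth$human_effect[gen$truth$mouse_flipped])
})

test_that("genome annotation generation is reproducible and validates input", {
  genes <- sprintf("g%02d", 1:10)
  ann1 <- generate_genome_annotation(genes, n_chromosomes = 1, seed = 3)
  expect_equal(unique(ann1$chromosome), "1")
  expect_identical(ann1, generate_genome_annotation(genes, 1, seed = 3))
  expect_true(all(ann1$arm %in% c("p", "q")))
  expect_true(all(substr(ann1$band, 1, 1) == ann1$arm))
  expect_error(generate_genome_annotation(c("a", "a")), "duplicate")
  expect_error(generate_genome_annotation(character(0)), "empty")
})

test_that("an injected arm concentration is detected by the binomial test", {
  # 30 of 50 signature genes forced onto one arm of a 1000-gene universe
  genes <- sprintf("g%04d", 1:1000)
  ann <- generate_genome_annotation(genes, n_chromosomes = 22, seed = 5)
  target <- ann$gene_id[ann$chromosome == "1" & ann$arm == "q"]
  sig <- c(target[1:min(30, length(target))],
           setdiff(genes, target)[1:20])
  res <- region_enrichment(sig, ann, level = "arm")
  expect_lt(res$p_tail[res$region == "1q"], 1e-4)
  expect_equal(res$stars[res$region == "1q"], "****")
})

test_that("the methylation generator plants hypermethylated promoters among down genes only", {
  cfg <- synthetic_config(n_genes = 200, frac_de = 0.2, seed = 29,
                          n_studies_human = 1,
                          n_replicates_per_group = 2)
  gen <- generate_study_set(cfg)
  down <- gen$truth$gene_id[gen$truth$status == "down"]

  meth1 <- generate_methylation_table(gen$truth, 1, seed = 11)
  hyper <- function(m, cmp)
    m$gene_id[m$comparison == cmp & m$meth_logfc > 1.5 & m$meth_adj_p < 0.1]
  expect_setequal(hyper(meth1, "MPNST_vs_NF"), down)
  expect_setequal(hyper(meth1, "MPNST_vs_control"), down)
  expect_length(hyper(meth1, "NF_vs_control"), 0)
  expect_identical(meth1, generate_methylation_table(gen$truth, 1,
                                                     seed = 11))

  # with every down gene passing the expression conditions, the filter
  # recovers exactly the planted-down set
  meta <- data.frame(gene_id = gen$truth$gene_id,
                     score = ifelse(gen$truth$status == "down", -1,
                                    ifelse(gen$truth$status == "up", 1, 0)),
                     logFC = gen$truth$human_effect)
  out <- methylation_silencing_filter(meta, meta, meth1)
  expect_setequal(out$gene_id, down)

  # frac = 0 silences nothing
  meth0 <- generate_methylation_table(gen$truth, 0, seed = 11)
  out0 <- methylation_silencing_filter(meta, meta, meth0)
  expect_equal(nrow(out0), 0)
})

test_that("noisier generation recovers fewer planted genes in the signature", {
  recover_count <- function(noise_sd, seed) {
    cfg <- synthetic_config(n_genes = 300, n_studies_human = 3,
                            include_mouse = FALSE,
                            n_replicates_per_group = 4,
                            noise_sd = noise_sd, seed = seed)
    gen <- generate_study_set(cfg)
    # at extreme noise the prefilter may legitimately empty a study:
    # that run recovers nothing
    tryCatch({
      res <- suppressMessages(suppressWarnings(
        run_meta_analysis(gen$studies)))
      sum(res$signature$gene_id %in%
            gen$truth$gene_id[gen$truth$status != "null"])
    }, error = function(e) 0)
  }
  seeds <- c(37, 41, 43)
  low <- sum(vapply(seeds, function(s) recover_count(0.3, s), numeric(1)))
  high <- sum(vapply(seeds, function(s) recover_count(2.5, s), numeric(1)))
  expect_gt(low, high)
})
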