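test_that("ortholog mapping re-keys mouse genes and resolves many-to-one by variance", {
  mouse <- make_score_table(c("mg1", "mg2", "mg3"), c(0.4, 0.6, 0.2),
                            variance = c(1, 3, 2), study_id = "m1",
                            species = "mouse")
  map11 <- data.frame(mouse_gene_id = c("mg1", "mg2", "mg3"),
                      human_gene_id = c("h1", "h2", "h3"))
  out <- map_orthologs(mouse, map11)
  expect_equal(nrow(out), 3)
  expect_setequal(out$gene_id, c("h1", "h2", "h3"))

  # unmapped mouse gene dropped with a message
  expect_message(out2 <- map_orthologs(mouse, map11[-2, ]), "dropped")
  expect_setequal(out2$gene_id, c("h1", "h3"))

  # two mouse genes onto one human gene: higher variance wins
  map21 <- data.frame(mouse_gene_id = c("mg1", "mg2"),
                      human_gene_id = c("hX", "hX"))
  out3 <- map_orthologs(mouse, map21)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$s_std, 0.6)

  expect_error(map_orthologs(mouse, map11[0, ]), "empty")
})

test_that("score combination sums human studies and admits mouse only on sign agreement", {
  humans <- list(make_score_table("g1", 0.6, study_id = "h1"),
                 make_score_table("g1", 0.7, study_id = "h2"),
                 make_score_table("g1", 0.5, study_id = "h3"),
                 make_score_table("g1", 0.8, study_id = "h4"))
  mouse <- make_score_table("g1", 0.4, study_id = "m1", species = "mouse")
  out <- combine_scores(humans, mouse)
  expect_equal(out$score, 3.0)
  expect_equal(out$studies, 5)
  expect_equal(out$mouse, 1L)

  # discordant mouse sign is discarded
  mouse_neg <- make_score_table("g1", -0.4, study_id = "m1",
                                species = "mouse")
  out2 <- combine_scores(humans, mouse_neg)
  expect_equal(out2$score, 2.6)
  expect_equal(out2$mouse, 0L)
  expect_equal(out2$studies, 4)

  # genes exclusive to mouse are ignored
  mouse_extra <- make_score_table(c("g1", "gM"), c(0.4, 0.9),
                                  study_id = "m1", species = "mouse")
  out3 <- combine_scores(humans, mouse_extra)
  expect_false("gM" %in% out3$gene_id)

  # null human sum blocks mouse inclusion
  humans0 <- list(make_score_table("g1", 0, study_id = "h1"))
  out4 <- combine_scores(humans0, mouse)
  expect_equal(out4$score, 0)
  expect_equal(out4$mouse, 0L)

  # mouse weight scales only the mouse term
  out5 <- combine_scores(humans, mouse, mouse_weight = 0.5)
  expect_equal(out5$score, 2.6 + 0.5 * 0.4)

  expect_error(combine_scores(list()), "at least one")
})

test_that("median effect sizes follow the mouse sign rule", {
  expect_equal(median_effect_size(c(1, 2, 3)), 2)
  expect_equal(median_effect_size(c(1, 2, 3), -1.5), 2)  # sign differs
  expect_equal(median_effect_size(c(1, 3), 2), 2)        # sign agrees
  expect_equal(median_effect_size(c(-1, -3), -2), -2)
  expect_error(median_effect_size(numeric(0)), "at least one")
})

test_that("bd_ratio matches its definition on worked cases", {
  expect_equal(bd_ratio(c(1, 1, 1, 1)), 0)
  expect_equal(bd_ratio(c(1, 0, 0)), 1)
  # hand computation: BC = 2*sqrt(0.5/3), BD = -ln BC, BD_max = ln(3)/2
  expect_equal(bd_ratio(c(0.5, 0.5, 0)),
               -log(2 * sqrt(0.5 / 3)) / (log(3) / 2), tolerance = 1e-12)
  expect_equal(bd_ratio(0.7), 0)       # single study: forced zero
  expect_equal(bd_ratio(c(0, 0, 0)), 0)
  expect_error(bd_ratio(numeric(0)), "no study")
})

test_that("bd_ratio equals the brute-force oracle and is permutation- and scale-invariant", {
  set.seed(101)
  for (n in 2:5) {
    # structured compositions plus random score vectors
    grid <- list(rep(1, n), c(1, rep(0, n - 1)),
                 seq_len(n) / n, c(rep(0.5, 2), rep(0, n - 2))[1:n])
    for (i in 1:10) grid <- c(grid, list(runif(n)))
    for (s in grid) {
      expect_equal(bd_ratio(s), bd_oracle(s), tolerance = 1e-12)
      perm <- sample(s)
      expect_equal(bd_ratio(perm), bd_ratio(s), tolerance = 1e-12)
      expect_equal(bd_ratio(3.7 * s), bd_ratio(s), tolerance = 1e-12)
      expect_gte(bd_ratio(s), 0)
      expect_lte(bd_ratio(s), 1)
    }
  }
})

test_that("integrate_studies assembles scores, medians and bias per gene", {
  h1 <- make_score_table(c("g1", "g2"), c(0.5, -0.4),
                         logFC = c(1.0, -2.0), study_id = "h1")
  h2 <- make_score_table(c("g1", "g2"), c(0.5, -0.2),
                         logFC = c(3.0, -1.0), study_id = "h2")
  mouse <- make_score_table(c("g1", "g2"), c(0.5, 0.3),
                            logFC = c(2.0, 1.5), study_id = "m1",
                            species = "mouse")
  meta <- integrate_studies(list(h1, h2), mouse)
  g1 <- meta[meta$gene_id == "g1", ]
  expect_equal(g1$score, 1.5)
  expect_equal(g1$studies, 3)
  expect_equal(g1$mouse, 1L)
  expect_equal(g1$logFC, 2.0)                 # median of {1, 3, 2}
  expect_equal(g1$bd_ratio, bd_oracle(c(0.5, 0.5, 0.5)))
  g2 <- meta[meta$gene_id == "g2", ]
  expect_equal(g2$score, -0.6)                # mouse sign disagrees
  expect_equal(g2$mouse, 0L)
  expect_equal(g2$logFC, -1.5)                # human median only
  expect_equal(g2$bd_ratio, bd_oracle(c(-0.4, -0.2)))
})

test_that("the consistency screen removes sign conflicts and null scores", {
  rec <- data.frame(gene_id = c("a", "b", "c", "d"),
                    score = c(1.2, 1.2, 0, -0.5),
                    logFC = c(-0.3, 2.0, 1.0, -1.0))
  out <- consistency_screen(rec)
  expect_setequal(out$gene_id, c("b", "d"))
})

test_that("the signature filter takes the top decile per sign and enforces the logFC bound", {
  # 500 positive-score genes, all passing the fold-change bound
  set.seed(5)
  rec <- data.frame(gene_id = sprintf("g%03d", 1:500),
                    score = runif(500, 0.01, 3),
                    logFC = rep(2, 500))
  sig <- final_signature_filter(rec)
  expect_equal(nrow(sig), 50)
  expect_true(all(sig$score >= sort(rec$score, decreasing = TRUE)[50]))
  expect_true(all(diff(sig$score) <= 0))     # sorted by descending score

  # a top-ranked gene with |logFC| below the bound is excluded
  rec$logFC[which.max(rec$score)] <- 0.5
  sig2 <- final_signature_filter(rec)
  expect_false(rec$gene_id[which.max(rec$score)] %in% sig2$gene_id)
  expect_equal(nrow(sig2), 49)

  # all genes failing the bound -> empty signature with a warning
  rec3 <- data.frame(gene_id = c("x", "y"), score = c(1, -1),
                     logFC = c(0.5, -0.9))
  expect_warning(sig3 <- final_signature_filter(rec3), "empty")
  expect_equal(nrow(sig3), 0)

  # size bound per sign
  rec4 <- data.frame(gene_id = sprintf("n%03d", 1:200),
                     score = c(runif(120, 0.1, 2), -runif(80, 0.1, 2)),
                     logFC = c(runif(120, 1, 3), -runif(80, 1, 3)))
  sig4 <- final_signature_filter(rec4)
  expect_lte(sum(sig4$direction == "up"), ceiling(0.1 * 120))
  expect_lte(sum(sig4$direction == "down"), ceiling(0.1 * 80))
  expect_true(all(sign(sig4$score) == sign(sig4$logFC)))
})

test_that("format_meta_table rounds to report precision and scales the BD ratio", {
  meta <- data.frame(gene_id = "g", score = 3.06123, logFC = 4.18751,
                     logFC_m = 4.46999, bd_ratio = 0.13675)
  rep <- format_meta_table(meta)
  expect_equal(rep$score, 3.06)
  expect_equal(rep$bd_ratio, 13.68)
  expect_equal(format_meta_table(meta, bd_percent = FALSE)$bd_ratio, 0.14)
})
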