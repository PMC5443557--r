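# small deterministic study builders used across the test files

# study with explicit per-probe case/reference means and optional noise
make_toy_study <- function(means_case, means_ref, n_rep = 4,
                           noise_sd = 0, seed = 42, species = "human",
                           study_id = "toy", genes = NULL) {
  set.seed(seed)
  np <- length(means_case)
  probe_ids <- sprintf("%s_P%03d", study_id, seq_len(np))
  mat <- cbind(matrix(rep(means_case, n_rep), ncol = n_rep),
               matrix(rep(means_ref, n_rep), ncol = n_rep))
  if (noise_sd > 0)
    mat <- mat + matrix(rnorm(length(mat), 0, noise_sd), nrow = np)
  rownames(mat) <- probe_ids
  colnames(mat) <- paste0("s", seq_len(2 * n_rep))
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(np))
  expression_study(mat, groups = rep(c("MPNST", "NF"), each = n_rep),
                   probe_map = data.frame(probe_id = probe_ids,
                                          gene_id = genes),
                   species = species, study_id = study_id,
                   case = "MPNST")
}

# a minimal per-gene study score table as combine_scores consumes
make_score_table <- function(gene_id, s_std, logFC = s_std,
                             logFC_m = logFC, variance = 1,
                             study_id = "st", species = "human") {
  tab <- data.frame(gene_id = gene_id, s_std = s_std, logFC = logFC,
                    logFC_m = logFC_m,
                    variance = rep_len(variance, length(gene_id)),
                    stringsAsFactors = FALSE)
  attr(tab, "study_id") <- study_id
  attr(tab, "species") <- species
  tab
}

# brute-force Bhattacharyya-coefficient oracle, written directly from the
# definition and kept independent of bd_ratio()
bd_oracle <- function(scores) {
  n <- length(scores)
  if (n == 1) return(0)
  w <- abs(scores)
  if (sum(w) == 0) return(0)
  bc <- 0
  for (j in seq_len(n)) bc <- bc + sqrt((w[j] / sum(w)) * (1 / n))
  (-log(bc)) / (0.5 * log(n))
}

# exact binomial upper tail by direct enumeration (n small)
binom_tail_oracle <- function(x, n, p) {
  if (x <= 0) return(1)
  s <- 0
  for (k in x:n) s <- s + choose(n, k) * p^k * (1 - p)^(n - k)
  s
}
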