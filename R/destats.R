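#' Mean-based log2 fold change
#'
#' Difference of group means on the log2 scale, case minus reference.
#'
#' @param values_a,values_b numeric vectors of log2 expression values for
#'   the case and reference phenotype.
#' @return A single number, `mean(values_a) - mean(values_b)`.
#' @export
compute_logfc <- function(values_a, values_b) {
  .check_groups(values_a, values_b)
  mean(values_a) - mean(values_b)
}

#' Median-ratio log2 fold change
#'
#' Robust effect size: all case/reference sample pairs are formed, their
#' linear expression ratios `2^(a - b)` computed, and the log2 of the
#' median ratio returned.  With one sample per group this reduces to the
#' ordinary log fold change.
#'
#' @inheritParams compute_logfc
#' @return log2 of the median cross-pair expression ratio.
#' @export
compute_logfc_m <- function(values_a, values_b) {
  .check_groups(values_a, values_b)
  log2(stats::median(2 ^ .cross_log_ratios(values_a, values_b)))
}

#' Median absolute deviation of cross-pair log ratios
#'
#' The reproducibility penalty input of the gene score: the unscaled MAD
#' (no 1.4826 consistency factor) of the same cross-pair log2 ratios used
#' by [compute_logfc_m()].  Zero when replicates are perfectly consistent.
#'
#' @inheritParams compute_logfc
#' @return Non-negative number.
#' @export
compute_mad <- function(values_a, values_b) {
  .check_groups(values_a, values_b)
  d <- .cross_log_ratios(values_a, values_b)
  stats::median(abs(d - stats::median(d)))
}

.check_groups <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both phenotype groups must contain at least one value")
  if (anyNA(a) || anyNA(b)) stop("missing expression values")
  invisible(NULL)
}

.cross_log_ratios <- function(a, b) as.vector(outer(a, b, "-"))

#' Benjamini-Hochberg adjustment
#'
#' Thin validating wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH step-up adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Per-probe two-group ANOVA
#'
#' One-way equal-variance ANOVA of each probe between the two phenotypes.
#' For two groups the F statistic is the square of the ordinary pooled
#' two-sample t statistic.  Probes that are constant in both groups get
#' p = 1; probes with zero within-group variance but distinct group means
#' get p = 0.
#'
#' @param study an [expression_study()].
#' @return Data frame with columns `probe_id`, `F`, `p`, `adj_p`.
#' @export
anova_fdr <- function(study) {
  g <- study$groups
  if (any(table(g) < 2L))
    stop("ANOVA prefilter needs >= 2 samples per group; ",
         "use skip_prefilter = TRUE (or prefilter = FALSE) for this study")
  bl <- .study_blocks(study)
  nA <- ncol(bl$A); nB <- ncol(bl$B); n <- nA + nB
  mA <- rowMeans(bl$A); mB <- rowMeans(bl$B)
  m <- (nA * mA + nB * mB) / n
  ss_between <- nA * (mA - m) ^ 2 + nB * (mB - m) ^ 2
  ss_within <- rowSums((bl$A - mA) ^ 2) + rowSums((bl$B - mB) ^ 2)
  df2 <- n - 2L
  f <- (ss_between / 1) / (ss_within / df2)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  # degenerate probes: flat everywhere -> certainly null; flat within
  # groups but split between them -> certainly differential
  p[ss_within == 0 & ss_between == 0] <- 1
  p[ss_within == 0 & ss_between > 0] <- 0
  f[ss_within == 0 & ss_between == 0] <- 0
  data.frame(probe_id = rownames(study$matrix), F = f, p = p,
             adj_p = bh_adjust(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' ANOVA false-discovery-rate prefilter
#'
#' Removes probes whose two-group ANOVA BH-adjusted p-value exceeds the
#' FDR threshold, mirroring the preprocessing step applied to each study
#' before scoring.
#'
#' @param study an [expression_study()].
#' @param fdr FDR threshold; probes with adjusted p above it are dropped.
#' @return The filtered `ExpressionStudy`, with attribute
#'   `prefilter_removed` holding the number of discarded probes.
#' @export
anova_prefilter <- function(study, fdr = 0.05) {
  res <- anova_fdr(study)
  keep <- res$adj_p <= fdr
  out <- study
  out$matrix <- study$matrix[keep, , drop = FALSE]
  attr(out, "prefilter_removed") <- sum(!keep)
  out
}

#' Moderated t, p-values and B statistic for one study
#'
#' Fits the two-group comparison per probe and shrinks residual variances
#' towards a common prior with the standard empirical-Bayes linear-model
#' machinery (Smyth 2004): posterior variance
#' `(d0*s0^2 + d*s^2) / (d0 + d)`, moderated t on `d0 + d` degrees of
#' freedom (capped at the pooled residual degrees of freedom), two-sided
#' p-values, BH adjustment across probes, and the log posterior odds of
#' differential expression B computed from the moderated t, the prior
#' proportion of differential probes and a fitted variance-inflation term.
#'
#' By default the prior degrees of freedom `d0` and prior variance `s0^2`
#' are fitted by matching the first two moments of the log sample
#' variances to a scaled log-F distribution; when that fit fails (tiny or
#' homogeneous fixtures) the fallback is `d0 = 4`, `s0^2 = median(s^2)`.
#' Passing `d0 = 0` recovers the ordinary pooled t test; `d0 = Inf`
#' replaces every probe variance by `s0^2`.
#'
#' @param study an [expression_study()].
#' @param prior_prop assumed prior proportion of differentially expressed
#'   probes used by the B statistic.
#' @param d0,s0 optional prior degrees of freedom and prior standard
#'   deviation, overriding the moment fit.
#' @param v0 optional prior variance of the (unscaled) log fold change
#'   used in the B statistic; fitted from the top `prior_prop` probes by
#'   quantile matching when omitted.
#' @param v0_lim numeric length-2 clamp for the fitted `v0`.
#' @return Data frame with columns `probe_id`, `t`, `p`, `adj_p`, `B`;
#'   the fitted hyperparameters are attached as attributes `d0`, `s0`,
#'   `v0`.
#' @export
moderated_stats <- function(study, prior_prop = 0.01,
                            d0 = NULL, s0 = NULL, v0 = NULL,
                            v0_lim = c(0.01, 16)) {
  bl <- .study_blocks(study)
  nA <- ncol(bl$A); nB <- ncol(bl$B); n <- nA + nB
  d_res <- n - 2L
  if (d_res < 1L)
    stop("need at least 3 samples to estimate residual variance")
  mA <- rowMeans(bl$A); mB <- rowMeans(bl$B)
  s2 <- (rowSums((bl$A - mA) ^ 2) + rowSums((bl$B - mB) ^ 2)) / d_res
  if (all(s2 == 0))
    stop("all probes constant: cannot fit variance hyperparameters")
  coef <- mA - mB
  u2 <- 1 / nA + 1 / nB
  if (is.null(d0) || is.null(s0)) {
    fit <- .fit_variance_prior(s2, d_res)
    if (is.null(d0)) d0 <- fit$d0
    if (is.null(s0)) s0 <- fit$s0
  }
  s2_post <- if (is.infinite(d0)) rep(s0 ^ 2, length(s2)) else
    (d0 * s0 ^ 2 + d_res * s2) / (d0 + d_res)
  if (any(s2_post == 0))
    stop("zero posterior variance; increase d0 or drop constant probes")
  tstat <- coef / sqrt(u2 * s2_post)
  df_total <- pmin(d0 + d_res, length(s2) * d_res)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  adj_p <- bh_adjust(p)
  # v0 and the inflation ratio live on the relative coefficient-variance
  # scale u2 = 1/nA + 1/nB (sigma factored out), as in the standard
  # empirical-Bayes formulation
  v1 <- rep(u2, length(tstat))
  if (is.null(v0))
    v0 <- .fit_v0(tstat, v1, df_total, prior_prop, v0_lim,
                  fallback = 1 / s0 ^ 2)
  B <- .log_odds_de(tstat, v1, v0, df_total, prior_prop)
  out <- data.frame(probe_id = rownames(study$matrix), t = tstat, p = p,
                    adj_p = adj_p, B = B, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0; attr(out, "s0") <- s0; attr(out, "v0") <- v0
  out
}

# method-of-moments fit of the scaled F prior on sample variances:
# log s^2 ~ log s0^2 + log F(d, d0); solve the trigamma equation for d0
.fit_variance_prior <- function(s2, d_res) {
  z <- log(s2[s2 > 0])
  fallback <- list(d0 = 4, s0 = sqrt(stats::median(s2[s2 > 0])))
  if (length(z) < 2L) return(fallback)
  target <- stats::var(z) - trigamma(d_res / 2)
  if (!is.finite(target) || target <= 0) return(fallback)
  d0 <- 2 * .trigamma_inverse(target)
  log_s02 <- mean(z) - digamma(d_res / 2) + digamma(d0 / 2) -
    log(d0 / d_res)
  list(d0 = d0, s0 = sqrt(exp(log_s02)))
}

# Newton solve of trigamma(y) = x on the log scale; x > 0
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# prior variance of the coefficient, estimated by matching the upper
# quantiles of the observed moderated t to the two-component mixture with
# the assumed proportion of differential probes (Smyth 2004, sec. 6)
.fit_v0 <- function(tstat, v1, df, proportion, lim, fallback) {
  ng <- length(tstat)
  ntop <- ceiling(proportion / 2 * ng)
  if (ntop < 1L) return(fallback)
  prop <- max(ntop / ng, proportion)
  at <- abs(tstat)
  dfc <- max(df[is.finite(df)], 4)
  ord <- order(at, decreasing = TRUE)[seq_len(ntop)]
  tt <- at[ord]
  p0 <- 2 * stats::pt(tt, df = dfc, lower.tail = FALSE)
  p_target <- ((seq_len(ntop) - 0.5) / ng - (1 - prop) * p0) / prop
  v0 <- numeric(ntop)
  pos <- p_target > p0 & p_target < 1
  if (any(pos)) {
    q <- stats::qt(p_target[pos] / 2, df = dfc, lower.tail = FALSE)
    v0[pos] <- v1[ord][pos] * ((tt[pos] / q) ^ 2 - 1)
  }
  est <- mean(pmax(v0, 0))
  if (!is.finite(est) || est <= 0) est <- fallback
  min(max(est, lim[1]), lim[2])
}

# log posterior odds of differential expression given the moderated t
.log_odds_de <- function(tstat, v1, v0, df, proportion) {
  r <- (v1 + v0) / v1
  t2 <- tstat ^ 2
  df <- rep_len(df, length(tstat))
  kernel <- ifelse(is.finite(df),
                   (1 + df) / 2 * log((t2 + df) / (t2 / r + df)),
                   t2 * (1 - 1 / r) / 2)
  log(proportion / (1 - proportion)) - log(r) / 2 + kernel
}

#' Full per-probe statistics table for one study
#'
#' Combines the effect sizes ([compute_logfc()], [compute_logfc_m()]),
#' the MAD reproducibility penalty, the moderated significance statistics
#' and the across-sample variance (used later for probe-to-gene collapse)
#' into one table.
#'
#' @inheritParams moderated_stats
#' @param ... passed to [moderated_stats()].
#' @return Data frame with columns `probe_id`, `logFC`, `logFC_m`, `MAD`,
#'   `t`, `p`, `adj_p`, `B`, `variance`.
#' @export
probe_stats <- function(study, ...) {
  bl <- .study_blocks(study)
  logfc <- rowMeans(bl$A) - rowMeans(bl$B)
  np <- nrow(study$matrix)
  logfc_m <- numeric(np); mad <- numeric(np)
  for (i in seq_len(np)) {
    d <- .cross_log_ratios(bl$A[i, ], bl$B[i, ])
    logfc_m[i] <- log2(stats::median(2 ^ d))
    mad[i] <- stats::median(abs(d - stats::median(d)))
  }
  mod <- moderated_stats(study, ...)
  data.frame(probe_id = rownames(study$matrix),
             logFC = logfc, logFC_m = logfc_m, MAD = mad,
             t = mod$t, p = mod$p, adj_p = mod$adj_p, B = mod$B,
             variance = apply(study$matrix, 1, stats::var),
             row.names = NULL, stringsAsFactors = FALSE)
}
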