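---
title: "Gene score-based meta-analysis: model, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene score-based meta-analysis: model, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoremeta)
```

## Why a score-based meta-analysis

Expression studies of rare phenotypes — here the transformation of benign
neurofibromas (NF) into malignant peripheral nerve sheath tumors
(MPNST) — are small, scattered across incompatible microarray platforms,
and sometimes come from mouse models rather than patients. Classical
effect-size meta-analysis struggles when the probe universes barely
overlap and the expression-ratio scales differ by platform. The approach
implemented here sidesteps scale incompatibility by converting each
study's evidence into a *bounded score* per gene and study, and summing
standardized scores. A gene rises to the top of the final ranking only
when several studies independently place it near the top of their own
rankings.

## The per-study model

Each study is a probes × samples matrix of normalized log2 intensities
with exactly two phenotype groups; the first group level is the case, so
positive effects mean higher expression in the case phenotype.

**Prefilter.** Probes are screened by two-group one-way ANOVA at a BH
FDR threshold (default 0.05). For two groups the F statistic is exactly
the squared pooled t statistic, which the tests assert. Studies with a
single sample in a group have no within-group degrees of freedom; the
prefilter refuses them and points to the skip flag (`prefilter = FALSE`),
since scoring itself can still proceed through the moderated model.
Whether the original procedure filtered before or after scoring on the
same samples is not decidable from its description; filtering per
comparison, before scoring, is the conservative reading and is what
`run_meta_analysis()` does.

**Effect sizes.** Besides the mean-based `logFC`, the score uses a
median-based effect: all case × reference sample pairs are formed and
`logFC_m = log2(median(2^(a_k - b_l)))`. The median is taken on the
*linear* ratio scale, matching the definition "log2 of the median of all
expression ratios". One numerical consequence of the midpoint convention
for even counts: with an even number of cross pairs, swapping the
phenotype labels negates `logFC_m` only approximately (the midpoint of
reciprocals is not the reciprocal of the midpoint). With odd pair counts
(e.g. 5 × 5 replicates) the antisymmetry is exact, and the tests pin it
there.

**Reproducibility penalty.** The unscaled median absolute deviation
(no 1.4826 consistency factor) of the same cross-pair log ratios. The
unscaled form is the smaller of the two conventions, which keeps the
penalty — and therefore the scores — conservative.

**Moderated significance.** Residual variances are shrunk towards a
common prior with the standard empirical-Bayes linear-model machinery:
posterior variance `(d0 s0^2 + d s^2)/(d0 + d)`, moderated t on
`d0 + d` degrees of freedom (capped at the pooled residual df),
two-sided p-values, BH adjustment, and the log posterior odds of
differential expression `B` with prior proportion 0.01. `d0` and `s0`
are fitted by matching the first two moments of `log s^2` to a scaled
log-F distribution (a trigamma equation solved by Newton iteration); on
tiny or variance-homogeneous fixtures where that fit fails the fallback
is `d0 = 4`, `s0^2 = median(s^2)`. The coefficient prior variance `v0`
of the B statistic is fitted by quantile matching on the top `prior_prop`
of |t| values. The implementation is exercised against an independent
reference fit: injecting the reference's fitted hyperparameters must
reproduce its t, p and B values to 1e-9. `d0 = 0` recovers the ordinary
pooled t test exactly; `d0 = Inf` replaces every probe variance by
`s0^2`; both limits are asserted in the tests.

## The score

Per study, `logFC_m` values are normalized to `[0, 1]` for upregulated
and `[-1, 0]` for downregulated genes by dividing each sign by its own
extreme; this removes platform ratio-scale bias. The normalization is
computed over all probes of the study before gating — the alternative
(normalizing only gated survivors) would make a gene's normalized effect
depend on which *other* genes pass significance, an undesirable
coupling. The raw score is

```
s = n * |logFC_m| / (|logFC_m| + c * MAD) * gate,
gate = 1  iff  adj_p <= alpha  and  B > 0
```

with `alpha = 0.05` and penalty weight `c = 1` by default. The
reliability ratio lies in `(0, 1]`, decreases monotonically in MAD and
increases in `|logFC_m|` (tested as properties); a gene with `logFC_m =
0` scores 0. The exact published score formula is not publicly printed;
this reconstruction satisfies every stated constraint of it — signed
up/down scores, median-based effect, per-sign `[-1, 1]` normalization,
MAD penalty that makes scores more stringent, and the `B > 0` third
gate — and is isolated behind `probe_score()` so an alternative can be
swapped in.

When a platform carries several probes for a gene, the probe with the
largest variance of expression across all samples of both phenotypes is
kept; variance ties fall to the lexicographically smallest probe ID for
determinism. Raw gene scores are then standardized by the study's
maximum absolute score. Range standardization (not z-scoring) was
chosen because it keeps gated zeros at exactly zero and bounds each
study's contribution to the final sum by 1, consistent with final
scores of magnitude ≈ study count.

## Cross-study integration

The human score is the sum of standardized scores over the human studies
in which the gene is represented. Mouse expression enters through a
user-supplied ortholog map (many-to-one mappings resolved by the same
maximal-variance rule) and is included — weighted by `mouse_weight`,
default 1 — only for genes whose human sum is non-null and agrees in
sign with the mouse score; genes observed only in mouse are ignored.
The default weight of 1 reflects that the human studies already dominate
the sum; no numeric weight is prescribed by the method's description, so
it is exposed as a parameter.

Final `logFC` and `logFC_m` are medians across the per-study values,
with the mouse value joining only when its sign matches the human
median.

**Bhattacharyya-distance ratio.** With per-study scores `s_j` over the
`n` studies where the gene is represented, `p_j = |s_j| / Σ|s_j|` is
compared with the uniform `q_j = 1/n`:

```
BD = -ln Σ_j sqrt(p_j q_j),   BD_ratio = BD / (ln(n)/2)
```

`BD_max = ln(n)/2` is attained when all mass sits in one study. Genes
represented in a single study are assigned ratio 0 by convention —
deliberately distinct from the multi-study gene whose mass happens to
concentrate in one study (ratio 1). The implementation is checked
against a brute-force oracle to 1e-12 and for permutation and scale
invariance. Reports multiply the ratio by 100
(`format_meta_table(bd_percent = TRUE)`), matching the printed
convention of published signature tables.

**Filters.** The consistency screen removes genes whose score sign
contradicts their median `logFC` (and null scores). The signature filter
takes `floor(0.10 * N)` genes per score sign — rounding is not specified
by the method's description; `floor` with ties broken by larger `|logFC|`
then gene ID keeps the cut deterministic — and retains those with
`|logFC| > 0.99` (strict). The 10% cut is applied to the sign-consistent
non-null list per sign, not the whole gene universe.

## Downstream genomics

**Region enrichment.** For each chromosome arm or band, the observed
signature count is tested with the exact binomial upper tail
`P(X ≥ x)` at the region's genome-wide frequency in the annotated
universe. Band-level expected frequencies are also genome-wide (the
within-chromosome alternative is a flag away in principle, but
genome-wide matches the arm-level definition and is the default).
Genes lacking a band label still join arm-level tests. Stars follow the
published open intervals (`****` < 1e-4 < `***` < 1e-3 < `**` < 0.01 <
`*` < 0.05), with boundary values assigned to the less significant bin.
No multiple-testing correction is applied across regions; raw tails with
stars are reported, as in the original figures.

**Hypermethylation silencing filter.** Candidate silenced genes must
have score < 0 and `logFC < -0.5` in the malignant-vs-benign comparison,
`logFC < -0.5` in the malignant-vs-control comparison, and promoter
methylation `logFC > 1.5` at adjusted p < 0.1. The methylation condition
is required in *both* tumor methylome comparisons by default, because
the selection is described over both; `require_both = FALSE` relaxes it
to either. All thresholds are strict inequalities and the filter is
monotone in each (tested). The package ships the published 10-gene panel
(`hypermethylation_panel()`) that this filter must retain in full — the
RASSF1 tumor suppressor, whose promoter hypermethylation in MPNST is an
established positive control, plus nine downregulated signature genes.

## The synthetic-data generator

`synthetic_config()` defaults encode the emulated design: 4 human
studies plus 1 mouse study, 1000 genes, 10% planted differential genes
with absolute log2 effects uniform in [2, 4], 5 replicates per group,
and per-replicate Gaussian noise of 0.5 on the log2 scale. Values not
fixed by the emulated design were chosen once as realistic for
two-channel/oligo microarray compendia: platform coverage 0.8 of the
gene universe per study (public platforms rarely cover everything), 1–3
probes per gene, probe-specific baseline offsets (SD 0.3) so the
max-variance collapse has something to choose between, gene baselines
uniform in [5, 10] (normalized log2 intensity range), and a mouse
sign-flip fraction of 0.1 emulating modest cross-species discordance.

With `noise_sd = 0`, planted effects propagate exactly through
`compute_logfc` and `compute_logfc_m` (asserted to 1e-12). Identical
seeds give bit-identical outputs. What the generator does *not*
emulate: probe cross-hybridization, batch effects, intensity-dependent
variance, correlated genes, or array-image artifacts — so passing tests
demonstrate the pipeline's arithmetic and its selection logic, not
robustness to every real-data pathology.

```{r recovery}
cfg <- synthetic_config(seed = 11)
gen <- generate_study_set(cfg)
res <- suppressMessages(
  run_meta_analysis(gen$studies, ortholog_map = gen$ortholog_map))
res$signature
truth <- gen$truth[match(res$signature$gene_id, gen$truth$gene_id), ]
table(planted = truth$status, direction = res$signature$direction)
```

At these defaults the signature is small but essentially pure: planted
genes recovered in the correct direction. Problem sizes throughout the
examples and tests (hundreds to a thousand genes, 2–5 studies) were
chosen as comfortably desk-scale while leaving every statistical fit
(variance prior, v0 quantile matching) non-trivial.

## Degenerate inputs and numerical choices

- Probes constant in both groups: prefilter p = 1 (discarded); constant
  within groups but split between them: p = 0 (kept).
- An all-constant matrix cannot support the variance prior fit and is
  refused.
- Even-count medians use the midpoint convention everywhere.
- `bd_ratio` clamps tiny negative values (floating-point) to [0, 1].
- Empty signature candidate sets yield an empty signature with a
  warning, not an error.
- All tables are TSV with a single header row; `NA` for missing values;
  machine outputs keep full precision, `format_meta_table()` rounds to
  the 2-decimal report convention.

## Known limitations

The exact published score standardization and human-weighting constants
are not public; the choices here (range standardization, mouse weight 1)
are flagged configurable and isolated behind their operations. The
pipeline consumes pre-computed methylation statistics rather than raw
methylome reads, and performs no array normalization — inputs are
assumed normalized log2 matrices. Reproducing any particular published
signature would additionally require the original accessions, annotation
versions and preprocessing.
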