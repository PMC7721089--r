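---
title: "Methods behind the m6A pattern and m6Ascore analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the m6A pattern and m6Ascore analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical methods, model assumptions and
numerical choices behind `m6Apattern`, in pipeline order. Code chunks are
illustrative and not evaluated at build time; the worked example in the
README runs the whole pipeline.

## 1. The regulator panel

The analysis starts from 23 m6A regulators: 8 writers (METTL3, METTL14,
RBM15, RBM15B, WTAP, KIAA1429, CBLL1, ZC3H13), 2 erasers (ALKBH5, FTO) and
13 readers (YTHDC1, YTHDC2, YTHDF1, YTHDF2, YTHDF3, HNRNPC, FMR1, LRPPRC,
HNRNPA2B1, IGF2BP1, IGF2BP2, IGF2BP3, ELAVL1). The three IGF2BP-family
readers are removed before clustering because their strong
proliferation-linked expression dominates distance computations and masks
the writer/eraser structure; `clustering_panel()` therefore returns a
20-gene panel. Panel genes absent from a cohort are dropped with an
explicit report (`restrict_panel()`).

## 2. The synthetic cohort generator

Matched expression + survival data cannot be redistributed, so the
package simulates an HCC-like cohort with fully known ground truth
(`simulate_cohort()`). Defaults encode the reference study conditions:
300 samples, 2 000 genes, three latent patterns with proportions
(1/3, 1/3, 1/3), regulator shift 1.5, unit Gaussian noise, exponential
survival with baseline hazard 0.2/year and per-pattern log-hazard offsets
(0, 0.6, 1.6) under Uniform(0, 10) censoring, a metabolic activity axis
with correlation −0.8 to the pattern index, and per-pattern response
probabilities (0.2, 0.2, 0.6).

Expression is generated directly on the log2 scale as
`baseline + structure + N(0, noise_sd)`. The structured blocks are:

* **Regulators.** With `k` patterns, shift `s` and span `S = s (k − 1)`,
  pattern `z` shifts readers by `S · 1[z ≥ 2]`, writers by
  `S · 1[z = k]` and erasers by `s (z − 1)`. The role-specific
  *transition boundaries* (readers separate pattern 1 from the rest,
  writers separate pattern `k` from the rest, erasers grade linearly)
  make the three pattern centroids non-collinear in regulator space. This
  matters: if all regulators moved proportionally to `z`, the three
  centroids would be collinear and equidistant, a geometry that validity
  indices resolve as two clusters, not three. The detectability of the
  planted pattern count is what `regulator_shift` controls; setting it to
  0 removes the structure entirely (used by the null-calibration tests).
* **Prognostic signature genes.** 40 risk genes rise with `z`, 40
  protective genes fall with `z`, tying pattern membership to survival
  through expression as well as through the hazard offsets.
* **Metabolic genes.** A per-category latent axis `m` is built from a
  monotone non-increasing profile of `z` (a step down after pattern 1 for
  carbohydrate, a concave quadratic decline for lipid, a step at pattern
  `k` for amino-acid, linear for other), standardized and mixed with
  independent noise so that `cor(z, m)` equals `metabolic_coupling`
  exactly in expectation. The category-specific shapes keep the metabolic
  centroids non-collinear (same rationale as above) while every category
  remains anti-correlated with the pattern index. Member genes add
  `scale · m` with category scales lipid 1.5, carbohydrate 1.0,
  amino-acid 1.0, other 0.8.

Survival times are exponential, `T ~ Exp(h0 · exp(offset_z))`, censored
at `C ~ Uniform(0, 10)`; this gives closed-form checkable Cox parameter
recovery. Gene sets are simulated per category with sizes 10–20 and a
bounded within-category overlap, plus an `MRNA_METHYLATION` set holding
the 23 regulators and 10 decoys.

## 3. Single-sample enrichment (GSVA-style)

For each gene, expression across samples is mapped through a kernel CDF:
the Gaussian option evaluates
`F(x_j) = mean_i Φ((x_j − x_i) / h)` with bandwidth `h = sd/4` (floored
at machine epsilon), the `ecdf` option uses `rank / n` with max ties.
Within each sample, transformed values are ranked in decreasing order
(ties broken lexicographically by gene name for determinism), and the
symmetric rank statistic `r = |G|/2 − rank + 1/2` is formed, which sums
to zero over all genes.

The score of a gene set is a signed random walk over the ranked gene
list: in-set genes step up by `|r|^τ` (τ = 1 by default), normalized by
the in-set total, out-of-set genes step down by `1/(|G| − |set|)`. The
default statistic is `diff_of_maxima` — the largest positive deviation
plus the smallest negative deviation — which is bounded in [−1, 1] and
antisymmetric under rank reversal; `max_deviation` keeps only the largest
absolute excursion. Sets outside the size window [5, 500] are skipped and
reported. A set whose in-set rank weight is identically zero (a single
gene at the exact middle rank of an odd-length list) has no defined walk
and raises an error rather than returning 0/0.

## 4. Pattern discovery

Samples are clustered on the standardized regulator panel (genes centred
and scaled; constant genes dropped with a warning). The cluster count is
a **majority vote of four validity indices** over k = 2…15: mean
silhouette width, Calinski–Harabasz (maximized), Davies–Bouldin
(minimized) and the gap statistic (with `B = 20` uniform reference draws
over the data's bounding box, one-standard-error rule). Vote ties resolve
to the smaller k. Each candidate k is fit by Lloyd's k-means with 25
random starts (falling back to Hartigan–Wong if Lloyd fails), and the
final labels are renumbered by ascending centroid row-means so that
cluster indices are reproducible and ordered.

## 5. Differential expression between patterns

Pairwise contrasts between patterns use a moderated t-statistic: per-gene
pooled variances `s²` are shrunk toward a prior via empirical-Bayes
moment matching on `log s²` — the prior degrees of freedom `d0` solve
`trigamma(d0/2) = var(log s²) − trigamma(d/2)` by Newton iteration on the
inverse trigamma, exactly the scaled-inverse-chi-square hierarchy of the
standard limma model (which the test suite uses as an independent
oracle). `prior_df = 0` recovers the ordinary pooled t-test. P-values are
BH-adjusted; genes pass at adjusted p < 0.05 and |log2 FC| > 1, and the
union over contrasts defines the m6A phenotype signature space.

## 6. The m6Ascore

Each DEG is screened with a univariate Cox model (Breslow ties). Genes
with p < 0.05 split into risk (HR > 1) and protective (HR < 1) sets;
genes with HR exactly 1 are excluded with a warning. Expression of
signature genes is min–max scaled to [−1, 1] per gene, and

```
m6Ascore = Σ scaled(risk genes) − Σ scaled(protective genes)
```

The scaling bounds are **frozen** at fit time and stored with the
signature (`freeze_signature()`, TSV round-trip via `write_signature()`),
so external cohorts are scored on the training scale. Patients split into
low/high groups at the cohort median (ties to low), or at a supplied
numeric cutoff.

## 7. Metabolic subtyping

The 50 metabolic pathway scores feed the same k-selection and ordered
k-means machinery. With three clusters, they are labelled by mean
lipid-pathway enrichment — LML (lowest), LMI, LMH — with ties broken by
cluster size; any other k falls back to generic ordered labels with a
warning. The most altered category is the one with the largest mean
pairwise centroid distance computed on its own sets and divided by the
square root of the set count, a normalization that makes categories of
different sizes comparable (duplicating a category's sets leaves its
distance unchanged).

## 8. Survival analytics

* **Kaplan–Meier / log-rank.** Product-limit curves with Greenwood
  standard errors; unweighted k-group log-rank with df = k − 1.
* **Multivariate Cox.** Score group (reference "low"), TNM stage
  (ordered i < ii < iii < iv, reference i) and age, Breslow ties;
  duplicated covariate columns are rejected as collinear and < 10 events
  per covariate raises a warning.
* **Nomogram.** Each covariate's centred linear-predictor contribution is
  rescaled so the widest-range covariate spans exactly 0–100 points;
  total points are an affine function of the linear predictor, so the
  points-to-survival lookup `S0(t)^exp(lp)` (Breslow baseline) is exact,
  not an approximation. Horizons beyond the observed follow-up are
  refused with a warning.
* **Time-dependent AUC.** Cumulative-case/dynamic-control AUC at each
  horizon with inverse-probability-of-censoring weights `1/G(T−)`, where
  `G` is the Kaplan–Meier estimate of the censoring distribution; ties in
  the score count 1/2.

## 9. Association reports

Cross-tabulations use the Pearson chi-square without continuity
correction by default (Yates available for 2×2), flagging tables with
expected cells below 5. Score–pathway associations are Pearson
correlations of the m6Ascore against every pathway score. The
treatment-response contrast reports PR/SD rates per score group with a
2×2 chi-square, degrading gracefully (rates only, test skipped with a
warning) when responses are one-sided. The alluvial table counts every
distinct path through the stratifications, with missing labels kept as an
explicit level so counts always sum to the cohort size.

## 10. Reproducibility and limitations

Every stochastic step (k-means restarts, gap-statistic reference draws,
simulation) is seed-controlled; re-running a config through
`run_pipeline()` reproduces byte-identical outputs, and each output
directory carries a manifest with the package version, seed and config.

Limitations worth keeping in mind:

* The simulator generates Gaussian log-scale expression without a count
  layer, library-size effects or batch structure beyond an optional
  constant shift in `merge_cohorts()`.
* The enrichment implementation covers the single-sample rank-walk family
  described above; it is not a drop-in replacement for every published
  GSVA variant (no Poisson kernel, no per-gene precomputed null).
* The nomogram assumes proportional hazards and the Breslow baseline of
  the fitted model; no internal calibration/validation split is
  performed.
* The IPCW AUC assumes censoring independent of the score within the
  cohort.
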