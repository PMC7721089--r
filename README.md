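# m6Apattern

N6-methyladenosine (m6A) is the most common internal mRNA modification. Its
deposition, removal and recognition are controlled by 23 regulator genes —
8 "writers" (METTL3, METTL14, RBM15, RBM15B, WTAP, KIAA1429, CBLL1, ZC3H13),
2 "erasers" (ALKBH5, FTO) and 13 "readers". In hepatocellular carcinoma
(HCC), tumours fall into distinct m6A modification patterns with different
prognoses, and the transcriptomic consequences of those patterns can be
condensed into a per-patient **m6Ascore** that stratifies survival,
metabolic activity and treatment response.

`m6Apattern` implements this analysis end to end:

1. **Regulator panel** — the 23 m6A regulators, with the three IGF2BP
   readers removed before clustering (a 20-gene clustering panel).
2. **Pattern clustering** — k-means on the standardized regulator panel,
   with the cluster count chosen by a majority vote of four validity
   indices (silhouette, Calinski–Harabasz, Davies–Bouldin, gap statistic)
   over k = 2…15.
3. **Single-sample enrichment** — a GSVA-style rank-based enrichment score
   per gene set and sample (Gaussian-kernel CDF transform, signed
   Kolmogorov–Smirnov-like random walk).
4. **Differential expression** — empirical-Bayes moderated t-tests between
   patterns with Benjamini–Hochberg correction; the DEG union defines the
   m6A phenotype signature space.
5. **m6Ascore** — univariate Cox screening of the DEGs, split into risk
   (HR > 1) and protective (HR < 1) sets, per-gene min–max scaling to
   [−1, 1], and score = Σ risk − Σ protective, with a median split into
   low/high groups.
6. **Metabolic subtyping** — clustering on the enrichment scores of 50
   metabolism pathways (carbohydrate / lipid / amino-acid / other),
   labelled LML / LMI / LMH by mean lipid-pathway enrichment.
7. **Survival analytics** — Kaplan–Meier curves, log-rank tests, a
   multivariate Cox model (score group, TNM stage, age), a nomogram point
   system and time-dependent (IPCW cumulative/dynamic) AUC at 1/3/5 years.
8. **Association reports** — chi-square cross-tabulations, score–pathway
   correlations, treatment-response contrasts and the flow table behind an
   alluvial diagram.

Because matched public expression + survival data cannot ship with the
package, it includes a fully parameterized cohort simulator
(`simulate_cohort()`) whose defaults encode the reference study
conditions: 300 samples, 2 000 genes, three latent m6A patterns with
pattern-linked survival hazard, prognostic signature blocks, a metabolic
activity axis anti-correlated with the pattern index, and 50 simulated
metabolic gene sets. Every simulated truth is returned alongside the data,
so each analytical claim in the pipeline is testable against a known
ground truth.

## Worked example

```r
library(m6Apattern)

cohort <- simulate_cohort(sim_config(seed = 1))
fit <- m6a_pipeline(cohort$expression, cohort$clinical, cohort$gene_sets,
                    categories = cohort$categories)
print(fit)
```

```
m6A pattern analysis: 300 samples, 2000 genes
  m6A clusters: k = 3 (sizes 90/101/109)
  signature: 63 risk + 1159 protective genes (of 1223 DEGs)
  metabolic subtypes: LMH=98 LMI=92 LML=110
  score-group log-rank: chi2 = 58.48, p = 2.05e-14
```

`summary()` adds the nomogram discrimination and the multivariate Cox
table:

```r
summary(fit)
```

```
nomogram time-dependent AUC:
  horizon   auc n_cases n_controls
1       1 0.743     115        169
2       3 0.741     195         63
3       5 0.780     218         31
multivariate Cox:
             term    hr  lo95 hi95        p
1 score_grouphigh 2.611 1.953 3.49 9.26e-11
2     stage_tnmii 0.719 0.491 1.05 8.93e-02
3    stage_tnmiii 1.402 0.993 1.98 5.47e-02
4     stage_tnmiv 1.214 0.817 1.80 3.36e-01
5             age 1.001 0.988 1.01 8.79e-01
```

The metabolic subtyping reports the most altered pathway category:

```r
print(fit$metabolic)
```

```
metabolic subtypes: LMH=98 LMI=92 LML=110
most altered category: carbohydrate
```

The fitted signature is frozen (per-gene scaling bounds recorded at fit
time), so new cohorts can be scored consistently:

```r
head(predict(fit, cohort$expression[, 1:6]))
```

```
  sample_id   m6ascore score_group
1     S0001  -69.65988        high
2     S0002  179.47473        high
3     S0003  247.97128        high
4     S0004 -170.40765         low
5     S0005 -116.66872         low
6     S0006 -281.66240         low
```

### File-level interface

The same analysis runs from files via a config (YAML or JSON):

```r
paths <- write_fixture(cohort, "cohort_dir")
run_pipeline(list(expression = paths[["expression"]],
                  clinical   = paths[["clinical"]],
                  gene_sets  = paths[["gene_sets"]],
                  categories = paths[["categories"]],
                  out_dir    = "results"))
```

which writes every intermediate table (cluster assignments, enrichment
scores, DEG table, Cox screen, signature, m6Ascores, metabolic subtypes,
nomogram lookup, AUC, association tests) plus a reproducibility manifest.
A thin CLI wrapper is installed under
`system.file("scripts", "m6a-pipeline.R", package = "m6Apattern")` with
`simulate` and `run` subcommands.

## Package layout

| file | contents |
|---|---|
| `R/regulator_panel.R` | the 23-regulator catalogue and the 20-gene clustering panel |
| `R/simulate.R` | synthetic HCC-like cohort generator + fixture writer |
| `R/cohort_io.R` | TSV/GMT readers with validation, cohort alignment and merging |
| `R/gsva.R` | single-sample enrichment scoring |
| `R/clustering.R` | validity-index vote, ordered k-means, PCA view |
| `R/deg.R` | moderated t-tests, BH adjustment, per-contrast DEG tables |
| `R/m6ascore.R` | Cox screen, signature partition, frozen scaling, scoring |
| `R/survival.R` | KM, log-rank, multivariate Cox, nomogram, IPCW AUC |
| `R/metabolic.R` | metabolic subtyping and LML/LMI/LMH labelling |
| `R/report.R` | cross-tabulations, correlations, response contrast, alluvial table |
| `R/pipeline.R` | `m6a_pipeline()` / `run_pipeline()` orchestration |
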