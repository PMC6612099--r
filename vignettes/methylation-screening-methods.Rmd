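---
title: "Methods: promoter-methylation screening and biomarker evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter-methylation screening and biomarker evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methscreen)
```

## The model

`methscreen` implements the discovery cascade used to find
epigenetically silenced genes in an acquired-resistance cell-model
comparison, plus the downstream statistics used to validate candidates
and evaluate one of them as a patient biomarker.

The measurement model is deliberately simple, matching how such studies
are analysed in practice. A 450K-style array reports, per CpG probe, a
beta value in $[0,1]$ — the fraction of methylated alleles. The
cascade works entirely on condition-mean betas:

* $\Delta\beta = \bar\beta_{res} - \bar\beta_{sens}$, with *gained* /
  *lost* calls at $|\Delta\beta| \ge 0.20$ (boundary inclusive, as the
  threshold is stated);
* the stringent call
  $\text{hyper} \iff \bar\beta_{sens} < 0.20 \wedge \bar\beta_{res} > 0.60$,
  with the mirrored rule for hypomethylation. Both comparisons are
  strict, again following how the thresholds are stated. The two rules
  are mutually exclusive, mirror-symmetric under condition relabeling,
  and every stringent call implies a gain/loss call (the gap
  $0.60 - 0.20 = 0.40$ exceeds $0.20$).

No per-probe variance model is fitted: the source analyses have one
array per condition, so the statistics are threshold rules, not
moderated tests. Where replicates exist (synthetic data), condition
summaries are arithmetic means.

### Regulatory restriction and gene assignment

Silencing acts through promoter CpG islands, so stringent calls are
evaluated only at probes that are (a) in a CpG island and (b) annotated
to at least one promoter-class gene region (TSS200, TSS1500, 5'UTR,
1stExon). The conjunction is a declared decision — the source
description ("promoters and islands") does not state the connective —
and `select_regulatory(policy = "island_or_promoter")` provides the
disjunction. A probe is assigned to *every* gene for which it has a
qualifying (symbol, region) entry; annotation entries are
positionally-zipped symbol/region pairs, deduplicated on the pair, so a
probe annotated `LRRC61;ACTR3C;LRRC61` contributes to both symbols.

On the shipped 46-CpG panel the default policy assigns 32 distinct gene
symbols (33 appear in the printed symbol lists; the Body-only entry
EXOC3L is excluded, the TSS1500-annotated microRNA host MIR1469 is
kept). The published count for this table is 31; the text does not
state the counting rule that produced it, so the package documents the
discrepancy rather than guessing a rule that reproduces the number.

### Integration with expression

Expression input is a normalized positive per-gene table; the package
computes condition-mean ratios oriented to $\ge 1$ with a direction
flag, partitions genes at fold change $\ge 1.5$ (inclusive), and
intersects the stringently hypermethylated gene set with the
downregulated set. Candidates with $\ge 3$ stringent CpGs form the
shortlist, ordered by CpG support, then fold change, then symbol — the
tie-break is this package's own convention (the original selection also
weighed prior literature, which is out of computational scope). A
pseudocount of 0.5 is added to condition means only when one of them is
zero, so noiseless integer examples keep exact fold changes.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `delta_min` | 0.20 | gain/loss and clustering threshold (beta units) |
| `stringent_low` / `stringent_high` | 0.20 / 0.60 | stringent classification bounds |
| `stringent_tol` | 0 | rounding tolerance; use 0.005 for tables printed at two decimals |
| `fc_min` | 1.5 | inclusive expression fold-change cut |
| `min_cpgs` | 3 | CpG support for the shortlist |
| `detection_p_max` | 0.01 | probe detection filter, *any sample fails* semantics |
| `cutoff_pct` | 20 | low/high methylation dichotomization (percent) |
| `alpha` | 0.05 | significance level |

All defaults are the values used in the source analysis. The detection
filter's per-sample semantics is a declared decision: only an aggregate
CpG count is reported upstream, so "remove the probe if it fails in any
sample" was chosen as the conservative reading.

## Numerical choices

* **Printed-value validation.** Published beta values are printed at
  two decimals, and one panel probe prints a resistant beta of exactly
  0.60; `stringent_tol = 0.005` (half an ulp of two decimals) accepts
  such rounding artifacts without loosening the rule on raw data.
  Ten of the 46 printed difference-column entries differ from
  subtraction of the rounded betas by 0.01 (upstream unrounded
  arithmetic); recomputed $\Delta\beta$ is therefore compared only on
  the self-consistent rows.
* **Rank tests.** `mann_whitney()` uses the exact null distribution
  when $n_1+n_2 \le 12$ without ties, otherwise the normal
  approximation with tie and continuity correction; two-sided p-values
  follow the doubling rule capped at 1. All-identical pooled values
  return $p = 1$ (no evidence either way). Kruskal-Wallis reports the
  tie-corrected $H$ with a $\chi^2_{k-1}$ p-value and falls back to the
  rank-sum test for two groups.
* **ROC.** AUC via the Mann-Whitney concordance identity with ties
  counted one half; the confidence interval uses the DeLong estimator
  (the default of the MedCalc-style analysis), with a bootstrap
  option. Positives are post-treatment non-responder samples,
  negatives pre-treatment samples.
* **Logistic calibration.** IRLS (via `stats::glm`) with deviance
  tolerance $10^{-10}$ and at most 100 iterations; separation is
  detected and flagged, with last-iterate probabilities still
  returned. The Hosmer-Lemeshow statistic is
  $\sum_g (O_g - E_g)^2 / (E_g(1 - E_g/n_g))$ over quantile bins (ties
  kept together, empty bins collapsed), $df = G - 2$.
* **Clustering.** Average-linkage agglomerative clustering of
  Euclidean distances over probes with $|\Delta\beta| \ge$
  `delta_min`, ties resolved by input order for determinism.
* **Dichotomization.** The stated rule "low ≤ 20%, high ≥ 20%"
  overlaps at exactly 20; the package assigns the boundary to the
  high (risk) class and records that in the function contract.
* **Paired pre/post comparison.** The source figure credits the
  rank-sum test for the paired panel, so that is the default; the
  Wilcoxon signed-rank test is computed alongside and reported too.

## The synthetic-data generator

`generate_study()` emulates the study inputs with known ground truth:

* **Methylome.** Beta values are simulated as
  $\mathrm{logit}^{-1}(\mu + \epsilon)$, $\epsilon \sim N(0,
  \sigma^2)$ on the logit scale, clipped to $[0,1]$ — this keeps draws
  in range with controllable spread (no noise model is reported
  upstream). Planted genes receive 3–5 promoter-island probes with
  true betas 0.10 / 0.70 (sensitive / resistant), mirroring both the
  stringent thresholds' margins and the ≥ 3-CpG selection regime;
  background probes share a per-probe baseline across conditions,
  islands mostly unmethylated and open sea mostly methylated. A fixed
  5% of background probes sit on X/Y so the exclusion filter is always
  exercised. Defaults: `beta_noise_sd = 0.3`, 3 replicates per
  condition.
* **Expression.** Planted genes are knocked down by
  `expr_log2fc_planted = 2` (4-fold, comfortably beyond the 1.5-fold
  cut, of the order reported for validated candidates); null genes
  share means across conditions with log2 noise sd 0.25.
* **Cohort.** 4 complete responders (pre-treatment only) and 10
  non-responders with paired pre/post samples — the paired subset of
  the source cohort. Pre-treatment methylation is drawn near 6% with
  sd 5, non-responder post-treatment values at +24 percentage points,
  matching the reported group means (6.08 ± 1.51 → 30.26 ± 3.52,
  reported as mean ± SEM). Covariates (age, menopause, ER, stage,
  grade, surgery) are drawn from fixed categorical distributions and
  carry no planted association with methylation.

With zero noise the cascade must return exactly the planted gene set
(this is asserted in the tests); at logit noise sd 0.3 the mean recall
over 20 seeds stays above 0.9 at the default thresholds.

What the generator does **not** emulate: array measurement artifacts
(probe-type chemistry, background, dye bias — the pipeline starts from
normalized betas by design), correlated probes within a locus beyond
the planted blocks, copy-number-driven beta shifts, cohort
heterogeneity beyond Gaussian noise, or any true covariate–methylation
association. Passing recovery tests therefore demonstrates the
correctness of the cascade's logic under its stated model, not
robustness to real-data artifacts.

## Problem sizes

The test-suite and acceptance computations use desk-scale inputs chosen
as the package's own validation regime: 2 000-probe / 300-gene
methylomes, 20 recovery seeds, 200-replicate calibration simulations at
$n = 2000$, and exhaustive enumeration oracles up to $n_1 + n_2 = 10$
(rank tests) and 12-gene universes (enrichment). The genome-scale
counts of the source study (tens of thousands of differential CpGs)
require the deposited arrays and an unspecified normalization, and are
deliberately not reproduction targets; the shipped 46-CpG panel is the
fully-printed worked example the package reconstructs exactly.

## Known limitations

* Gene-level aggregation trusts the annotation's symbol lists;
  multi-gene probes count once per annotated gene, so dense loci (e.g.
  an LRRC61/ACTR3C-style pair) can both reach the shortlist from the
  same CpGs.
* The expression filter is a plain fold-change rule on a normalized
  table — no dispersion modelling, by design, since that is the rule
  being implemented.
* The Hosmer-Lemeshow test needs enough distinct predicted
  probabilities to form ≥ 3 bins; under complete separation (as on a
  strongly shifted small cohort) it is skipped and reported as such.
* The DeLong interval is asymptotic; at the shipped cohort size (10
  vs 14) it is reported but should be read qualitatively.
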