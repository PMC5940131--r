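---
title: "Methods: strain-resolved caloric-restriction transcriptome analysis"
author: "strainCR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-resolved caloric-restriction transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainCR)
```

## Scope and model overview

strainCR analyzes transcriptional responses to caloric restriction (CR)
measured across several inbred mouse strains and tissues, and relates them to
human adipose responses from paired weight-loss experiments. The statistical
spine is:

1. **Detection and filtering.** A gene is detectable in a sample when at
   least 50% of its probe sets pass an above-background call at p < 0.05; the
   call is a one-sided Wilcoxon signed-rank test that perfect-match
   intensities exceed mismatch intensities. A gene enters a CR-vs-control
   comparison only when detectable in at least one third of that comparison's
   samples. When several probes map to one gene, the probe with the highest
   mean intensity represents the gene.
2. **Moderated differential expression.** Per-gene ordinary least squares on
   the log2 scale, with empirical-Bayes variance moderation: the gene
   residual variances $s^2_g$ (with $d_g$ residual df) are shrunk toward a
   prior $(d_0, s_0^2)$, giving posterior variances
   $\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$ and a moderated
   t-statistic on $d_g + d_0$ degrees of freedom. A gene is called
   differentially expressed when its Benjamini-Hochberg FDR is below 0.10 and
   its linear fold-change exceeds 1.50 or falls below 0.67.
3. **Interaction scans.** For a focal strain,
   $\mathrm{expression} = \mathrm{diet} + \mathrm{strain} + \mathrm{diet}
   \times \mathrm{strain}$ with diet coded 1 for CR and strain coded 1 for
   the focal strain versus all other strains pooled; the moderated test is
   applied to the interaction coefficient, with FDR control within the scan
   and both 0.10 and 0.15 reporting thresholds available.
4. **Global structure.** Per-gene Gaussian likelihood-ratio tests compare
   the full strain + diet model against each reduced model; the factor with
   the larger $-\log_{10} p$ is dominant. Samples are also projected onto
   the first two principal components of the gene-centered matrix, and each
   strain's CR response is drawn as an arrow from the bivariate mean of its
   control samples to that of its CR samples.
5. **Shared responses.** A gene responds in a strain when its raw p-value is
   below 0.05; it counts toward "shared in k strains" only when all
   responding strains agree in fold-change direction. Observed counts are
   compared against a permutation null that shuffles each strain's
   (p, direction) pairs across the gene universe independently, preserving
   each strain's marginals exactly while breaking cross-strain association.
6. **Human meta-analysis.** Each paired experiment contributes per-gene mean
   paired log2 differences and their standard errors (after removing its 15%
   lowest-expressed genes). Experiments sharing a baseline sample set are
   dependent; exactly one per baseline set is retained — the one with the
   lowest average standard error. Genes measured in at least 6 retained
   experiments are synthesized by the DerSimonian-Laird random-effects
   estimator with inverse-variance weighting:
   $Q = \sum w_i (y_i - \bar y_w)^2$ with $w_i = 1/se_i^2$,
   $\hat\tau^2 = \max\{0, (Q - (k-1))/(\sum w - \sum w^2 / \sum w)\}$, and
   pooled effect $\hat\mu = \sum w^*_i y_i / \sum w^*_i$ with
   $w^*_i = 1/(se_i^2 + \hat\tau^2)$. One BH pass is applied over the final
   gene set.
7. **Cross-species concordance.** Mouse and human fold-change vectors are
   joined through an explicit one-to-one ortholog map (no case-folding
   heuristics), compared by Spearman correlation per (strain, experiment)
   cell, and the top-100 CR-increased/decreased genes of each strain are
   tested for concentration in the human ranking by a cumulative-overlap
   statistic (below).

## The synthetic-data generator

Because the original microarray collections are external downloads, every
stage is exercised on synthetic data with known ground truth.

**Mouse studies.** The default design is the full factorial
7 strains × 4 tissues × 2 diets × 8 replicates = 448 samples. Expression of
gene $g$ in a sample of strain $s$ under diet $d$ is, on the log2 scale,

$$y = \beta_{0,g} + o_{g,s} + d \cdot \delta_{g,s} + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2_g),$$

with gene baselines $\beta_{0,g} \sim N(7, 1.5^2)$, strain offsets
$o_{g,s} \sim N(0, 0.5^2)$, and gene variances $\sigma^2_g$ drawn from a
scaled inverse-chi-square prior (scale $0.5^2$, 4 df) so that variance
moderation has a correctly specified target to recover. By default 10% of
genes carry a shared CR effect $\delta_{g,\cdot} \sim N(0, 0.5^2)$ common to
all strains, and 5% carry a strain-specific effect in a single focal strain
(the signal an interaction scan should detect). Planted effects are common
to all tissues of a strain; per-tissue effect heterogeneity is not modeled,
so cross-tissue contrasts on synthetic data share one truth table.

**Human experiments.** The default collection emulates 28 paired
experiments grouped into 18 distinct baseline sample sets. Experiments in a
set share identical baseline samples (and are therefore dependent by
construction). Subject counts are drawn log-uniformly on [3, 40]; the
geometric mean of that law is about 11 subjects, matching the typical size
of small clinical weight-loss experiments. True human effects are built as
$\rho \, z_g + \sqrt{1-\rho^2}\,\epsilon_g$ from the standardized mouse
shared effects, rescaled, so the mouse-human rank correlation of true
effects approximates the configurable `concordance_rho` (default −0.3, i.e.
opposite responses on average). Each experiment adds a per-experiment effect
deviation with variance `tau2` (default 0.05 log2², exposed as a parameter
because within-collection heterogeneity is not pinned down by any single
design) and drops a random 20% of genes, emulating platform differences.

**What passing tests do not show.** The generator is Gaussian on the log2
scale with independent genes; it has no gene-gene correlation, no
intensity-dependent variance trend, no batch structure, and no probe-level
cross-hybridization. Calibration and recovery results on synthetic data
therefore certify the estimators under their nominal assumptions, not
robustness to those real-data violations.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `q_max`, `fc_up`, `fc_down` | 0.10, 1.50, 0.67 | FDR / linear FC | DEG thresholds |
| `alpha` | 0.05 | p-value | per-strain shared-response threshold |
| detection fraction | 1/3 | proportion of samples | expression filter ("33%" read as the exact fraction 1/3) |
| `min_experiments` | 6 | experiments | meta-analysis gene inclusion |
| `low_expr_fraction` | 0.15 | proportion of genes | per-experiment low-expression removal (floor convention) |
| `shared_B` / `gsea_B` | 1000 / 10000 | permutations | null resolution; empirical p is bounded below by 1/(B+1) |

## Numerical choices

- **Signed-rank null.** Exact (`psignrank`) for up to 25 untied differences;
  exhaustive sign-flip enumeration (exact under ties) for up to 15 tied
  differences; tie-corrected normal approximation with continuity correction
  otherwise. Zero differences are dropped before ranking; an all-zero probe
  set is undetected (p = 1).
- **Variance-prior estimation.** The moment estimator works on
  $e_g = \log s^2_g - \psi(d_g/2) + \log(d_g/2)$; the excess of
  $\mathrm{var}(e)$ over $\overline{\psi'(d_g/2)}$ is matched to
  $\psi'(d_0/2)$ by Newton iteration on the trigamma inverse (tolerance
  1e-8, at most 50 iterations). Non-positive excess gives $d_0 = \infty$
  (normal reference). Zero-variance genes are excluded from prior estimation
  but still moderated. Note the log-scale bias correction means that when
  all $s^2$ are identical, $s_0^2 = s^2 (d/2)/e^{\psi(d/2)}$, a few percent
  above the common value at typical df.
- **Likelihood-ratio dominance.** Chi-square reference with df equal to the
  number of dropped parameters (1 for diet, number of strains − 1 for
  strain); exact Log10P ties break toward strain. The statistic
  $n \ln(\mathrm{RSS}_r/\mathrm{RSS}_f)$ is nonnegative by construction.
- **PCA.** Covariance PCA on gene-centered (not standardized) data —
  standardization would upweight low-variance genes whose log2 changes are
  least reliable. Each component's loadings are sign-fixed to sum positive
  for deterministic output.
- **Ties.** Probe collapsing breaks average-expression ties toward the
  lexicographically smallest probe ID; the low-expression filter removes
  lexicographically smallest symbols first among tied means; top-n gene
  lists break fold-change ties by smaller p then symbol; the independence
  filter breaks average-se ties by experiment ID. All tie-breaks are
  deterministic so pipeline reruns are byte-identical.
- **Degenerate inputs.** se = 0 genes in a meta-analyzed experiment are
  floored at the 1st percentile of that experiment's positive se values
  (capping the weight instead of letting it diverge); genes contributed by
  fewer than 2 retained experiments are excluded from the meta-signature;
  fold-change pairs on either axis (FC = 1) are excluded from quadrant
  tests.

## Design decisions made where the design was open

- **Sidedness of the detection call.** Above-background means perfect-match
  exceeding mismatch, so the signed-rank test is one-sided (PM > MM).
- **Enrichment statistic.** The cumulative-overlap statistic is defined
  here as the signed, set-size-normalized supremum deviation
  $(D^+ - D^-)/m$ of the running overlap from its uniform expectation, with
  a two-sided permutation p-value over random same-size sets. This is a
  package-defined Kolmogorov-style statistic, and output tables label it as
  such.
- **Median fold-change test.** Testing a sample of fold-changes against the
  constant 1.00 is degenerate as a two-sample rank-sum problem; it is
  implemented as the one-sample signed-rank test of log2 FC against 0,
  two-sided.
- **Meta-analysis effect scale.** Mean paired log2 difference (a
  fold-change-scale synthesis), not a standardized mean difference, because
  the quantity of interest downstream is a meta fold-change.
- **Experiment ranking order.** The average standard error used to rank
  dependent experiments is computed after each experiment's low-expression
  exclusion, i.e. over the genes that actually enter the analysis; the
  ordering of ranking versus gene filtering is ambiguous in principle and
  this choice is explicit and configurable.
- **BH scope.** FDR is controlled separately within each strain-tissue
  contrast, within each interaction scan, and once over the final
  meta-analyzed gene set.

## Problem sizes used by the test suite

Calibration and recovery tests run at desk scale, chosen to keep Monte-Carlo
error well inside the asserted bounds: 5000-gene null studies for type-I
error and uniformity checks; the permutation-null oracle comparison at
10000 genes × 7 strains × 1000 permutations; fold-change recovery over 20
seeds at 500 genes; heterogeneity recovery at 18 experiments × 1500 genes;
end-to-end pipeline determinism at 120–150 genes. These sizes are the
package's own choices for a reproducible desk-scale suite; all estimators
are dimension-free and run unchanged at genome scale.

## Known limitations

- Gene-gene independence in the generator understates the variance of
  genome-wide summaries (correlation grids, shared-response counts) relative
  to real arrays.
- The pooled "other strains" group of an interaction scan treats residual
  strain heterogeneity as noise; with strong strain baseline offsets the
  scan is conservative.
- The DerSimonian-Laird variance $\hat\tau^2$ is a moment estimator:
  noisy at small k and truncated at zero, so per-gene heterogeneity
  estimates should be read in aggregate (the suite checks the median).
- Raw array normalization, probe-level QC metrics, and annotation-based
  (GO/KEGG) enrichment are out of scope; QC verdicts arrive as sample flags
  and gene sets arrive as plain lists.
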