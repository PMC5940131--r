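# strainCR

Strain-resolved transcriptome analysis of caloric restriction (CR) in R.

Caloric restriction extends lifespan in many rodent models, but its
transcriptional effects differ across inbred mouse strains — and responses in
the most commonly studied strain need not generalize to other genotypes, let
alone to humans. strainCR is for quantitative biologists who want to ask,
with multi-strain expression data: which CR responses are shared across
strains, which are strain-specific, and do they agree with the responses
seen in human adipose tissue during weight loss?

## What it computes

- **Moderated differential expression** per strain-tissue contrast:
  per-gene OLS on log2 expression with empirical-Bayes variance moderation
  (posterior variance $\tilde s^2_g = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$,
  moderated t on $d_g + d_0$ df), Benjamini-Hochberg FDR, and DEG calls at
  FDR < 0.10 with linear fold-change > 1.50 or < 0.67.
- **Strain-by-diet interaction scans**:
  `expression = diet + strain + diet:strain` with the focal strain
  contrasted against all other strains pooled.
- **Global structure**: per-gene likelihood-ratio factor dominance
  (strain vs diet), principal-component CR response vectors per strain,
  Spearman fold-change correlation matrices, and average-linkage strain
  clustering exported as Newick.
- **Cross-strain shared responses**: counts of genes responding in the same
  direction in k strains at p < 0.05, tested against a permutation null that
  shuffles each strain's (p, direction) pairs independently.
- **Human meta-signature**: paired log2 differences per experiment, a
  baseline-sharing independence filter (one experiment per baseline sample
  set, lowest average SE wins), a ≥ 6-experiment gene-inclusion rule, and
  DerSimonian-Laird random-effects synthesis
  ($\hat\tau^2 = \max\{0, (Q - (k-1))/(\sum w - \sum w^2/\sum w)\}$ with
  inverse-variance weights).
- **Cross-species concordance**: ortholog-mapped Spearman correlation grids
  (mouse strains × human experiments), top-100 cumulative-overlap
  enrichment with a permutation p-value, and median fold-change tests.
- **A synthetic-data generator** with planted ground truth (shared,
  strain-specific, and interaction effects; dependent human experiments
  sharing baseline sets; tunable mouse-human concordance), emulating a
  7-strain × 4-tissue × 2-diet × 8-replicate design at desk scale.

See `vignettes/strain-resolved-cr.Rmd` for the full methods account.

## Worked example

```r
library(strainCR)
sim <- simulate_mouse_study(study_design(n_genes = 2000), seed = 1, n_qc_fail = 12)
study <- exclude_flagged_samples(sim$study)

m <- study$sample_meta
sel <- m$tissue == "eWAT" & m$strain == "F1"
fit <- cr_contrast_fit(study$matrix[, sel], m$diet[sel])
nrow(call_degs(fit))

fits <- lapply(setNames(nm = unique(m$strain)), function(s) {
  sel <- m$tissue == "eWAT" & m$strain == s
  cr_contrast_fit(study$matrix[, sel], m$diet[sel])
})
shared_null(fits, alpha = 0.05, B = 200, seed = 2)

hs <- simulate_human_experiments(human_meta_config(), sim$truth, seed = 3)
msig <- meta_signature(hs$experiments)
```

This prints, among other things:

```
ExpressionStudy: 2000 genes x 448 samples (7 strains, 4 tissues, diets: CTL/CR)
QC removed: 12 ->  436 samples
F1 eWAT DEGs: 12 ( 7 up / 5 down)
  k observed null_mean null_sd p_empirical
6 6       10         0       0 0.004975124
7 7       15         0       0 0.004975124
meta-signature: 1997 genes from 18 independent experiments
ConcordanceGrid: 7 strains x 28 experiments (grand mean rho = -0.039)
```

Reading these numbers: the simulated full-factorial design has 448 samples,
of which 12 QC-flagged samples are dropped. At desk scale (2000 genes, 10%
planted shared effects) a single strain-tissue contrast yields a handful of
DEGs. The shared-response table shows 15 genes responding concordantly in
all 7 strains while the permutation null essentially never produces any —
the planted shared program is detected as a significant excess (empirical
p = 1/201 at B = 200). The human meta-analysis retains 18 of 28 experiments
(one per baseline sample set) and, with the generator's default negative
mouse-human concordance, every strain's fold-changes correlate negatively
with the human experiments (grand mean Spearman rho about −0.04).

The one-call orchestrator runs all stages and writes TSV outputs plus a
deterministic run manifest:

```r
run_pipeline(pipeline_config(seed = 1, out_dir = "cr_run"))
```

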