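---
title: "Gene-vector diversity and constrained response classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-vector diversity and constrained response classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genevec)
```

## The model

`genevec` analyses multi-SNP genotypic patterns rather than single markers.
For a gene with $m$ polymorphic SNPs, each SNP is coded additively,
$s_k \in \{0, 1, 2\}$ (copies of the alphabetically later allele), and the
gene's *gene vector* is the base-3 integer

$$v \;=\; \sum_{k = 1}^{m} s_k\, 3^{\,k-1}, \qquad 0 \le v \le 3^m - 1 .$$

Each realized value of $v$ is one *genotypic pattern*; at most $3^m$ exist.
The number of distinct patterns observed in a sample, the gene's *diversity
index* $d$, measures how finely the gene resolves between-subject
differences.  Under SNP independence the expected number of distinct
patterns in a sample of $n$ subjects is the coupon-collector sum
$\sum_c \left[1 - (1 - p_c)^n\right]$ over all $3^m$ patterns, with $p_c$
the product of the per-SNP state probabilities
(`expected_pattern_coverage()`, `expected_distinct_independent()`).  With
equally distributed SNPs, $n = 4 \cdot 3^m$ subjects are expected to show
about 95% of the possible patterns; `simulate_pattern_coverage()` verifies
the closed form by Monte-Carlo.

Dividing the summed observed diversity indices by the summed independence
expectations gives the *dependence ratio* (`dependence_ratio()`): values
well below 1 indicate within-gene SNP correlation.  Between-gene pattern
co-occurrence is measured by Cramér's V on the two genes' pattern
contingency table after pooling patterns with fewer than 5 pairwise-complete
carriers (`between_gene_association()`).  The Bergsma bias correction is
the default because the uncorrected statistic is strongly positively biased
for tables with many categories, which is exactly the regime pattern
catalogs live in; the uncorrected statistic remains available
(`correct = "none"`).  This coefficient is a standard categorical
association measure chosen because no specific definition of pattern
"correlation" is canonical; its values are not comparable to correlation
coefficients computed by other conventions.

## Clinical labels

Repeated scale scores (HAM-D17 for depressive/F3 subjects, PANSS-P and
PANSS-G for schizophrenic/F2 subjects) are completed to the 8-visit/42-day
schedule `{0, 3, 7, 10, 14, 21, 28, 42}` by last observation carried
forward (`locf_fill()`); the exact nominal days are a package convention,
as only "up to 8 assessments over 6 weeks" is fixed by the protocol.
Labels follow percent-of-baseline reduction rules:

* **response** — sustained 50% (HAM-D17, F3) or 40% (PANSS-P, F2)
  baseline-score reduction;
* **onset of improvement** — sustained 20% reduction; reaching onset within
  14 days makes an *early improver*;
* **sustained** — no later visit gives back more than 15% of the achieved
  reduction.

The give-back anchor is ambiguous in principle: the default
(`anchor = "first"`) compares later visits to the reduction at the first
qualifying visit, the simplest reading; `anchor = "max"` compares to the
running maximum reduction, which is stricter (a relapse from a deeper
trough disqualifies).  Severity bands (HAM-D17: `<20` mild, `20–24`
moderate, `>24` severe; PANSS-G: `<30` / `30–40` / `>40`) treat boundary
values as moderate.  Inclusion requires the diagnosis-specific baseline
threshold (HAM-D17 ≥ 15, PANSS-G ≥ 21) and at least three assessments in
the first two weeks; excluded subjects carry no outcome labels.

## Two-stage response-gene analysis

**Stage 1 — screen.**  `screen_cohort()` flags genes carrying a pattern
that is *characteristic* of one outcome class while *rare* (frequency
< 0.10) in the other, in either direction.  Only the rarity side has a
fixed cutoff; "characteristic" is operationalized as frequency ≥ 0.20 with
at least 5 carriers, both exposed as parameters.  No multiple-testing
correction is applied; instead the null-control machinery (below)
quantifies the false-positive behaviour of the rule.  Screening the full
labeled sample before cross-validation leaks label information into gene
discovery; `cv_with_screen()` provides the fold-honest variant in which
screening (and optionally gene selection) runs inside each training fold.

**Stage 2 — constrained network.**  Gene vectors enter the classifier as
one-hot pattern indicators (`one_hot_encode()`): per gene, one indicator
for each pattern with ≥ 5 carriers plus an `OTHER` bin; a missing gene
vector leaves the block at zero.  Raw base-3 codes are not ordinal, so
indicators are the defensible encoding.  The network is a one-hidden-layer
logistic net trained by online backpropagation,

$$\Delta w_{ij} = \alpha\,\varepsilon_i\, s_j\, s_i(1-s_i), \qquad
  \Delta w_{jk} = \alpha\,\varepsilon_i\, s_k\, s_i(1-s_i)\, w_{ij}\, s_j(1-s_j),$$

which is steepest descent on half the squared error of each probe; both
deltas use the pre-update weights.  Biases are weights to constant-1
units, so the printed equations apply unchanged.  One *iteration* is one
full epoch over all probes in reshuffled order (the per-probe formulas
imply online updating; the definition of an iteration is a package
convention).  Training stops at the epoch budget or when the epoch mean
squared error varies by less than a relative tolerance (default `1e-4`)
over a trailing 25-epoch window — the steady-state/oscillation rule.
Default hidden size is `min(2 * n_genes, 32)`, learning rate 0.5, initial
weight scale 0.5; desk-scale epoch budget 300.

**Criterion function.**  The decision threshold is placed just beyond the
most extreme output of the constraint class on the calibration set
($\tau = \max$ over constraint-class outputs $+\ 10^{-9}$), guaranteeing
100% constraint-class accuracy there by construction
(`criterion_evaluate()`).  In 10-fold stratified cross-validation
(`kfold_cv()`) the threshold is calibrated on each training fold only, and
test-fold counts are pooled.  Online training on near-collinear indicator
features lands in poor local minima often enough to matter, so each
training fold runs `fold_restarts` (default 3) random-walk restarts and
keeps the one with the best *training-fold* criterion — constraint
accuracy, then fewest false positives, then highest sensitivity, all
in-sample, so no test-fold information enters the choice.
`random_walk_search()` additionally repeats whole cross-validations from
independent initializations and keeps the restart with the best pooled
lexicographic key (constraint accuracy, fewest pooled false positives,
highest sensitivity), ties to the earliest restart.

**Gene selection.**  `select_classifier_genes()` grows a subset greedily
under a reproducibility constraint.  Two consequences of the hard
threshold shaped the design.  First, a *single* informative gene yields no
test sensitivity — its characteristic pattern also occurs among
constraint-class subjects, which pins the threshold above every carrier —
so forward selection from the empty set has no gradient to follow; the
subset is therefore seeded with the three genes of strongest class
contrast, computed on a restart-specific 70% subsample.  Second, a noise
feature set classifies test subjects essentially at random, making pooled
sensitivity approximately equal the false-positive rate; the growth
criterion is therefore the *excess* of sensitivity over the false-positive
rate (after the constraint-accuracy level), with differences below fixed
margins treated as ties.  Candidates within a step share folds and
initializations so that key differences reflect the features alone.  The
final subset is re-evaluated on fresh folds — the greedy loop's own key is
argmax-inflated — and discarded if its mean excess does not clear chance
level (0.035).  A gene is retained only if selected in at least 70% of
restarts.  Under planted signal the seeding is stable across subsamples;
under pure noise both the honest re-evaluation and the cross-restart
stability rule empty the set.

`cross_cohort_overlap()` scores another cohort at a trained model's
threshold through the shared pattern vocabulary (unseen patterns map to
`OTHER`); `split_half_stability()` reports the drop in correctly
classified fraction between full-sample cross-validation and repeated
train-on-half/test-on-half splits.  Training with the responders as the
constraint class (`constraint = "positive"`) is supported; on synthetic
cohorts it behaves far worse than the default direction, because the
responder class is smaller and its patterns are a superset of the
non-responder background — the asymmetry is reported, not asserted.

## The synthetic cohort generator

No subject-level data accompany the study design this package implements,
so `generate_cohort()` builds cohorts with the statistical structure the
analysis assumes; its defaults are the study conditions and every
downstream stage is tested against them.

* **Genotypes** — 264 F2 + 638 F3 subjects; 100 genes of 4–8 SNPs
  (uniform); per-SNP allele frequency uniform on (0.10, 0.50); genotypes
  from Hardy–Weinberg proportions.  Within-gene dependence comes from an
  equicorrelated latent Gaussian copula thresholded at the HWE quantiles;
  the equicorrelation (`within_gene_ld = 0.86`) was fixed once so that a
  study-sized cohort's dependence ratio lands near one third of the
  independence expectation, the dependence level the analysis is meant to
  operate at.  Cross-gene linkage copies a deterministic transform of the
  source gene's pattern into the linked gene with the configured
  probability (default: 16 disjoint pairs at strength 0.3).
* **Response genes** — ten genes carry one designated pattern planted into
  30% of responders and 5% of non-responders.  The designated pattern is
  drawn among naturally rare patterns (background frequency ≤ 2%), since a
  pattern that is common anyway cannot be rare in non-responders.
* **Trajectories** — a trigger model: improving subjects draw a trigger
  day (early, days 1–8, or late, 15–28), then decline linearly over 10–25
  days to a class-specific plateau — responders shed 55–85% of baseline,
  "stuck" subjects 20–50% — with i.i.d. Gaussian visit noise (SD 1 point)
  and integer rounding; non-improvers never trigger and drift at a
  configurable rate (default flat, since the shape of non-improvement is
  unspecified — upward drift is available via
  `trajectory$nonimprover_drift`).  The model is parametrized by the
  target final reduction rather than by a free slope so that the
  configured responder fraction is actually recoverable from the printed
  response rules; the slope is implied as baseline × reduction ÷ duration.
  Baselines come from truncated normals calibrated to the published
  mild/moderate/severe proportions (F3 HAM-D17: mean 22.7, SD 3.9,
  ≥ 15; F2 PANSS-G: mean 42.9, SD 8.7, ≥ 21; F2 PANSS-P: mean 22, SD 5).
* **Missingness** — 2% uniform masking plus a 15% subject tail with an
  extra 6–15% missing rate, placing them beyond the 5% analysis cutoff
  (`exclude_high_missing()`), mirroring a cohort in which roughly one
  seventh of subjects fail the missing-data criterion.
* **IgM** — elevated-IgM flags at 26% marginal prevalence; carriers of the
  designated patterns in three associated genes have relative risk
  `1 + strength` (default 3), with the non-carrier rate solved to keep the
  margin.

What the generator does *not* emulate: LD decay along chromosomes,
recombination, ancestry structure, genotyping batch effects, rater drift
in the clinical scores, or treatment-arm differences.  Passing tests on
these cohorts therefore demonstrate that the machinery recovers structure
it is pointed at under the stated noise — not that real psychiatric
cohorts contain such structure.

## Numerical choices and problem sizes

Determinism: every stochastic component consumes the R RNG, seeded once
per run from the configuration; the compiled training loop draws its
shuffles from the same stream, so pipelines are byte-reproducible under a
fixed seed.  Degenerate inputs fail loudly: empty classes, all-missing
vectors, single-class training labels and constant genes after pooling
raise typed errors rather than returning NaN.

The test suite runs the recovery analyses at the scale the package treats
as its reference desk experiment: cohorts of 600 single-diagnosis subjects
and 100 genes with ten (screen) or three (selection) planted response
genes, 20 seeds for screen recovery and the null control, 10 seeds for
cross-validated sensitivity and gene selection; coverage simulations use
500 replicates.  These sizes keep every Monte-Carlo standard error well
below the margins being asserted.

## Known limitations

* The greedy selection's seeding leans on the stage-1 contrast statistic;
  a gene informative only through interactions (no marginal pattern
  contrast) would not be seeded and could only enter during growth.
* The association coefficient, pooling threshold and `OTHER` binning make
  between-gene association values convention-dependent.
* Strand flips are not handled: genotypes are assumed to be consistently
  coded state counts.
* The constraint-threshold design makes test sensitivity hostage to the
  single most responder-like constraint-class subject in each training
  fold; this is inherent to the criterion, and the random-walk restarts
  mitigate but cannot remove it.
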