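---
title: "Models and methods behind betrescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind betrescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betrescue)
```

# The biological problem

BET bromodomain inhibitors (BETi) displace BRD4 from acetylated chromatin in
acute myeloid leukemia, but the transcriptional consequences are uneven: many
essential maintenance genes drop only transiently and recover within a day,
a compensation associated with increased p300 binding at exactly those loci.
`betrescue` packages the computational side of this analysis: quantifying
nascent transcription from metabolic-labeling (SLAM-seq-type) counts,
classifying genes by their temporal response, scoring reciprocal
BRD4-out/p300-in binding exchange at regulatory regions, quantifying the
synergy of sequential BETi-then-p300i dosing with the ZIP model, and
clustering longitudinal expression across resistance stages into named
temporal archetypes. Every stage can run on seeded synthetic data with
planted ground truth, so statistical behaviour (sensitivity, false discovery,
calibration) is measurable.

# Nascent-transcription quantification

## The labeling model

A read from a newly transcribed molecule carries at least one T>C conversion
with probability $q_{new} = 1-(1-c)^{k}$, where $c$ is the per-site
conversion rate and $k$ the number of convertible sites per read (default
$k = 20$); pre-existing molecules convert at a background rate, giving
$q_{old} = 1-(1-b)^{k}$. The labeled count given the total is then binomial
with mixture probability $f\,q_{new} + (1-f)\,q_{old}$, where $f$ is the
fraction of new molecules. The maximum-likelihood estimate of $f$ has the
closed form $(\hat p - q_{old})/(q_{new}-q_{old})$ clamped to $[0,1]$
(`estimate_new_fraction()`); the test suite verifies it against a brute-force
grid search over the binomial likelihood.

Defaults $c = 0.05$, $b = 0.001$ give $q_{new} \approx 0.64$ and
$q_{old} \approx 0.02$ — the conversion regime of a typical 4sU labeling
experiment.

## What is tested, and why not raw labeled counts

Raw labeled-count fold changes are attenuated toward zero by background
conversions: a true 4-fold drop of the nascent rate appears as roughly
3.4-fold in labeled counts at the default rates. `differential_timepoint()`
therefore tests the background-corrected nascent count
$(\mathrm{labeled} - \mathrm{total}\cdot q_{old})/(q_{new}-q_{old})$,
whose expected fold change equals the underlying nascent-rate fold change.
When labeling rates are unknown the raw labeled counts are used and the
attenuation is documented behaviour.

Size factors are always computed from **total** counts (median-of-ratios).
This matters: a treatment that globally reduces nascent transcription
reduces the labeled library as a whole, and size factors computed on the
labeled layer would absorb precisely the signal under study.

## The differential test

Per gene, the log2 fold change of normalized group means (pseudocount 0.5,
bounding the statistic for empty genes) is tested with a Wald statistic
whose variance comes from the negative binomial mean-variance relation
$\mathrm{Var}(K/s) = \mu/s + \alpha\mu^2$. Dispersion estimation with three
replicates needs moderation:

* a gene-wise method-of-moments estimate is computed per group and pooled;
* a mean-dispersion trend is fitted through **arithmetic bin means** of the
  raw estimates (20 bins over log mean). Fitting through per-gene log
  dispersions would be biased low because few-replicate moment estimates
  are strongly right-skewed (Jensen), which makes the test anticonservative;
* the default `"shrunk"` mode averages the gene-wise estimate and the trend
  half-and-half on the raw scale.

The Wald statistic is referenced against a $t$ distribution whose degrees of
freedom are the pooled residual df plus a prior df reflecting the
information contributed by moderation (prior df 16 at the default half
weight, fixed once by null-simulation calibration; trend-only dispersions
are treated as known and referenced against the normal). Under the default
study conditions the null fraction of $p<0.05$ sits at 0.053–0.055.

Genes with mean normalized count below 5 are reported untested
(`fdr = NA`) and excluded from the Benjamini–Hochberg adjustment: their
dispersion estimates are unstable and they would only dilute the FDR
control.

# Temporal rescue classification

With early (4 h) and late (24 h) contrasts against the untreated reference,
`classify_rescue()` applies explicit, configurable rules
(`rescue_thresholds()`; defaults $\alpha = 0.05$, $t_{down} = \log_2 1.5$,
$t_{recover} = \log_2 1.25$, $\delta_{min} = 1$):

* **rescued** — significant drop early, and late expression either back
  above $-t_{recover}$ or rebounded by at least $\delta_{min}$ log2 units.
  The OR captures both genes that return to baseline and genes that
  overshoot it.
* **redundant** — significantly down at both timepoints with no rebound:
  genes that simply depend on BRD4.
* **induced** — significantly up at 24 h.
* **unchanged** — everything else. Genes significant only at 24 h in the
  downward direction are deliberately *not* called redundant: the redundant
  notion is an immediate and sustained dependence, not a slow drift.

Precedence is rescued > redundant > induced > unchanged, making classes
mutually exclusive and exhaustive.

# Chromatin compensation

Regions are annotated to the gene with the nearest TSS by region midpoint
(strand ignored, ties to the lexicographically smaller gene id, default
search radius 1 Mb — permissive enough to catch distal enhancers, and
configurable). Differential binding is the log2 ratio of replicate-averaged
condition means with pseudocount 1 (enhancer regions can be empty in one
condition). Per-sample depth scaling (counts-per-million within each
factor/condition/replicate track) is the default; for signals that are
already library-scaled — including the package's own simulator output,
where a planted global BRD4 loss must remain observable — it can be
disabled, since compositional rescaling removes genuine global shifts by
construction.

The **compensation score** of a region is
$\Delta_{gained} - \Delta_{lost}$ (e.g. p300 log2 change minus BRD4 log2
change): antisymmetric under swapping the factors, zero when nothing moves,
and large positive where the gained factor moves in as the lost factor
moves out.

Cross-model concordance of "top 5 % gained" site sets is tested by a
permutation shift statistic (mean log2 change over the top set minus the
rest, against same-size random subsets, add-one corrected). Rank-based
top-fraction selection uses $\lceil f\,n\rceil$ sites, never returns
non-positive changes, and is nested in $f$.

# ZIP synergy scoring

Monotherapy rows are fitted with a bounded four-parameter logistic
(bottom $\in[-5,20]$, top $\in[50,110]$, slope $\in[0.2,10]$, EC50
initialized at the geometric mean of the nonzero doses; degenerate flat
data yield a flagged flat fit, non-convergence a flagged isotonic
interpolation). On the $[0,1]$ scale the zero-interaction-potency
expectation at a combination well is $y_A + y_B - y_A y_B$; the observed
potency-shifted response is the average of two constrained logistic refits
along the well's row and column, each with bottom pinned to the partner
drug's fitted monotherapy response and top at 1. The summary score is the
mean of (observed − expected) × 100 over combination wells; a 3×3
most-synergistic-window maximum is reported alongside. Calls use the
conventional thresholds: above +10 synergistic, below −10 antagonistic.

Scheduling mode (BETi-first, concomitant, p300i-first) is metadata only:
the scoring is identical per mode, and the biology enters exclusively
through the measured matrices. The package makes no claim about *why*
scheduling changes the measured surfaces.

The simulator's default design — four doses spanning roughly IC10–IC50
(50–400 against EC50 400) plus vehicle — mirrors how synergy screens are
dosed in practice and keeps combination wells below response saturation.
This is a substantive constraint, not a convenience: a planted
+20-percentage-point Bliss deviation is arithmetically unrecoverable at
wells whose expectation already exceeds 80 % inhibition, because measured
inhibition is clipped at 100 %.

# Resistance trajectories

Longitudinal expression over the four stages (untreated, 72 h treated,
incipient resistance at the parental IC50, full resistance at the IC90) is
summarized two independent ways, and the vignette's advice is to run both:

* **unsupervised**: the `n` most variable genes (log2, pseudocount 1) are
  z-scored per gene and clustered with Ward linkage on Euclidean distances
  (`hierarchical_cluster()`), cut at $k = 2$ for a simple up/down split or
  $k = 5$ for the full repertoire;
* **template-based**: each profile is correlated with the five named
  archetype templates — evolution (0,1,2,3), degression (3,2,1,0), stress
  (0,1,0,0), inflammation (0,0,1,0), interferon (0,1,1,−1) — and assigned
  the best match (`assign_archetypes()`). Correlations below 0.5, ties and
  constant profiles fall back to `flat`, avoiding forced labels on noise.

The named archetypes are post-hoc interpretations of unsupervised modules;
the two routes need not agree gene-by-gene and the package reports both.

Gene-set contrasts of treatment response (`geneset_delta()`) use one-sided
Mann–Whitney tests of "set A less down-regulated than set B" with BH
correction across set pairs — the statistic behind "the decrease of rescued
genes is blunted relative to other sets".

# The synthetic-data generators

The generators define the study conditions and are first-class, tested
code:

* **Time course** (`simulate_timecourse_counts()`): 5000 genes, classes
  rescued/redundant/induced/unchanged at 10/15/5/70 %, three replicates at
  0/4/24 h. Rescued genes drop 4-fold at 4 h (log2 −2) and return to
  baseline at 24 h; redundant genes stay down; induced genes rise at 24 h.
  Totals are negative binomial (dispersion 0.1) around log-normal baselines
  (meanlog 7.3, sdlog 1 — median ≈ 1500 total counts, putting the tested
  nascent signal at a base mean of a few hundred, the depth of a typical
  3'-end SLAM-seq library); the temporal signal lives entirely in the
  nascent fraction (baseline 0.5). Labeled counts are binomial draws from
  the per-read mixture model above, so labeled ≤ total holds by
  construction and the labeled layer inherits the NB dispersion.
* **Binding** (`simulate_binding()`): one region per gene; BRD4 loses
  1.5 log2 units globally under treatment, p300 gains 1.5 log2 units only
  at rescued-linked regions; log2-normal replicate noise (sd 0.25), two
  replicates per condition as in typical ChIP designs.
* **Dose matrices** (`simulate_dose_matrix()`): Hill monotherapies, Bliss
  combination wells plus a planted interaction (percentage points) plus
  Gaussian noise, clipped to [0,100].
* **Resistance course** (`simulate_resistance_course()`): per-gene stage
  means are an archetype template times a uniform amplitude (1–3) on a
  baseline of 5, plus Gaussian noise (default sd 0.25); an optional paired
  arm applies per-archetype log2 shifts.

What the generators deliberately do **not** emulate: mappability and GC
biases, transcript-length effects, correlated gene programs, batch
effects, compositional extremes, or dose-response drift between scheduling
modes. Passing recovery tests on these data demonstrates that the
estimators are correct and calibrated under their stated noise models — not
that real libraries satisfy those models.

# Numerical choices and degenerate inputs

* Identical seeds give bit-identical generator output; the pipeline runner
  derives a named substream seed per stage, so adding a stage never
  perturbs another stage's draws.
* Coordinates are 0-based half-open throughout; region midpoints use
  `floor((start+end)/2)`.
* All-zero count matrices, empty truth tables, grids without a vehicle
  dose, mismatched region universes and unpaired arms are errors, not
  warnings; malformed BED lines are reported with their line number.
* Constant profiles cannot be z-scored: clustering adopts them to the
  nearest non-constant neighbour and flags them; archetype assignment
  labels them `flat`.
* Problem sizes used by the packaged checks (ten 5000-gene runs for
  recovery and calibration, 2000 regions × 200 seeds for permutation
  calibration, 400-gene trajectories) were chosen as the smallest designs
  at which the measured quantities are stable to well within their
  acceptance margins.

# Known limitations

* The Wald test's prior df is calibrated for the default design (3 vs 3
  replicates, half-weight shrinkage); markedly different designs should be
  re-calibrated with a null run, which takes seconds.
* The ZIP refits inherit the logistic family's rigidity: interactions
  confined to a single well are smoothed across its row and column.
* Nearest-TSS annotation is a heuristic; without capture-C-type data a
  distal enhancer may be assigned to a bystander gene.
* The estimator of the new-RNA fraction assumes a common conversion rate
  across genes and reads; UTR composition differences are not modeled.
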