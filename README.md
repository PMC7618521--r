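# betrescue

Compensatory transcription after BET bromodomain inhibition, as a tested R
pipeline.

When BET inhibitors (BETi) strip BRD4 off chromatin in acute myeloid
leukemia cells, transcription of many essential maintenance genes drops only
transiently: nascent output falls sharply within hours and recovers by a
day, a rescue associated with reciprocal recruitment of the acetyltransferase
p300 at exactly those loci — and with a therapeutic corollary, since dosing
a p300 inhibitor *after* the BET inhibitor is synergistic. `betrescue`
implements the computational analyses behind this picture for analysts
working with SLAM-seq/nucRNA-seq count tables, ChIP signal tables,
dose-response matrices and longitudinal RNA-seq:

* **Nascent quantification** — the new-RNA fraction of a gene is estimated
  from T>C conversion counts under a binomial mixture: a read is labeled
  with probability `q_new = 1-(1-c)^k` if new, `q_old = 1-(1-b)^k`
  otherwise, giving the closed-form MLE
  `f = (p_obs - q_old)/(q_new - q_old)` clamped to [0,1].
* **Temporal rescue classification** — per-gene NB Wald tests (moderated
  dispersions, BH-adjusted) at 4 h and 24 h against baseline, then explicit
  rules: *rescued* = significantly down early AND recovered (or rebounded)
  late; *redundant* = down at both with no rebound; *induced* = up late;
  *unchanged* otherwise.
* **Chromatin compensation** — per-region differential binding
  `log2((mean_treated + pc)/(mean_control + pc))`, the compensation score
  `Δ(gained factor) − Δ(lost factor)`, nearest-TSS annotation, top-fraction
  site selection and a permutation test for cross-model concordance.
* **ZIP synergy** — zero-interaction-potency scoring of dose matrices:
  expected combination response `yA + yB − yA·yB` from monotherapy 4PL
  fits, observed response from potency-shifted logistic refits, summary
  delta in percentage points with the conventional ±10 synergy/antagonism
  calls, across BETi-first / concomitant / p300i-first scheduling modes.
* **Resistance trajectories** — Ward clustering of the most variable genes
  across the four resistance stages (untreated, 72 h, IC50-resistant,
  IC90-resistant) and correlation-based assignment to named temporal
  archetypes (evolution, degression, stress, inflammation, interferon),
  plus rank tests for gene-set blunting.
* **Synthetic data with planted truth** — seeded generators for every input
  type, so sensitivity, FDR and calibration of each stage are measurable
  without any external download.

## Worked example

```r
library(betrescue)

sim <- simulate_timecourse_counts(sim_config(seed = 1))
sim$counts
#> conversion_counts: 5000 genes x 9 samples (with labeled counts)

d4  <- differential_timepoint(sim$counts, 4)   # 4 h vs baseline
d24 <- differential_timepoint(sim$counts, 24)  # 24 h vs baseline
cls <- classify_rescue(d4, d24)
table(cls$class)
#>   induced redundant   rescued unchanged
#>       119       702       529      3650
```

The generator planted 10% rescued genes (nascent rate down 4-fold at 4 h,
back to baseline at 24 h); 98.9% of them are recovered by the
classification:

```r
m <- merge(cls, sim$truth, by = "gene_id")
sum(m$class == "rescued" & m$true_class == "rescued") /
  sum(m$true_class == "rescued")
#> [1] 0.989
```

Scoring a dose matrix with a planted +20-point Bliss deviation:

```r
z <- zip_delta(simulate_dose_matrix(interaction_delta = 20,
                                    mode = "BETi_first", noise_sd = 0))
c(z$mean_delta, z$call)
#> ZIP mean delta: 21.7 (synergistic)
```

A synthetic resistance course assigned to temporal archetypes:

```r
rc <- simulate_resistance_course(seed = 1)
table(assign_archetypes(rc$profiles)$archetype)
#> degression  evolution  flat  inflammation  interferon  stress
#>        118        118    18            84          67      95
```

The full pipeline (simulate → quantify → rescue → chromatin → synergy →
trajectory → report) runs from one seeded config and writes TSV/JSON
outputs plus a checksum manifest:

```r
manifest <- run_pipeline(run_config(seed = 1), "my_run")
```

or from the shell via `inst/cli/run_pipeline.R`.

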