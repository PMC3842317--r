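# hsp90flux

Analysis pipeline for quantitative proteomics studies of chaperone (Hsp90)
inhibition, built for datasets that combine three measurement layers:

* **stSILAC** — standard SILAC heavy/light ratios (treated/control) at two
  treatment time points across biological replicates, quantifying net
  changes in protein abundance;
* **pcSILAC** — pulse-chase SILAC time courses that separate the
  pre-existing protein pool (the "chase", which decays) from the newly
  synthesized pool (the "pulse", which accumulates), so that changes in net
  abundance can be decomposed into decay and synthesis components;
* **NanoString nCounter** — digital transcript counts for a target panel,
  with negative/positive control probes and candidate reference genes.

The package is aimed at proteomics bioinformaticians who need the full
chain — quality filtering, significance calling, temporal clustering,
kinetic decomposition, transcript normalization, dataset alignment — as
tested, scriptable functions, plus a synthetic-data generator with known
ground truth so every stage can be validated without any external download.

## Models and statistics

**Quality filtering.** Protein-group tables are cleaned by a fixed cascade:
database contaminants and reverse hits, a lab contaminant list, ratios
backed by a single evidence, time points quantified in fewer than 2
replicates, and fold-spread outliers — protein groups whose replicate
ratios at any single time point differ by more than a factor 1.41
(equivalently ~0.5 log2 units between some pair of replicates).

**Significance and clustering.** Per time point, replicate log2 ratios are
tested against 0 with a one-sample t-test (t = m / (s/√n), df = n−1,
two-tailed) and Benjamini–Hochberg adjusted; proteins significant at ≥1
time point are assigned to the temporal template (from the fixed set of 12
change patterns such as [0,1,2], [0,0,−1], …, evaluated after prepending a
(t=0, 0) reference) with maximal Pearson correlation. Non-significant
proteins form cluster 13, single-time-point proteins cluster 14.

**Turnover kinetics.** First-order turnover per protein and condition:

    dP_old/dt = −k_d · P_old        →  H(t) = H0 · exp(−k_d t)
    dP_new/dt = V_s − k_d · P_new   →  N(t) = (V_s/k_d) · (1 − exp(−k_d t))

k_d is estimated as minus the OLS slope of ln H(t) versus t (clamped at 0),
V_s by the closed-form linear least-squares solution given k_d, and
half-life as T½ = ln2 / k_d. Treated/control ratios of k_d, V_s, T½ and
steady-state abundance (V_s/k_d) are reported raw and after subtracting the
dataset-wide median log2 ratio ("adjusted for global proteome changes").

**nCounter processing.** Background subtraction (mean + 2 sd of negative
controls, floored at 1), a positive-control QC gate (max/min of per-sample
positive-control means < 3), geNorm selection of the most stable reference
genes (stability M = average sd of pairwise log2 ratios, iterative
elimination), normalization by the geometric mean of the selected
references, and log2 fold-changes of condition geometric means.

## Worked example

```r
library(hsp90flux)

cfg <- silac_sim_config(n_proteins = 300, effect_size_log2 = 1,
                        noise_sd_log2 = 0.08, seed = 42)
sim <- generate_stsilac_table(cfg)
tab <- orient_ratios(sim$table, cfg$swapped_replicates)  # fix label swap
fq  <- filter_quality(tab)
print(fq$report)
#> protein-group quality filter
#>   input rows:              312
#>   contaminants removed:    6
#>   reverse hits removed:    6
#>   lab-list removed:        0
#>   single-evidence cells:   88 (blanked)
#>   under-replicated tps:    6 (blanked)
#>   fold-spread outliers:    6
#>   emptied rows removed:    0
#>   retained:                294

tests <- test_differential(filter_occurrence(fq$table))
cl <- assign_clusters(tests)
sum(tests$significant_any)        # 48 of 292 proteins change significantly
table(cl$cluster[tests$significant_any])
#>  2  6  7 10 11 14
#> 16 10 11  1  8  2
```

The planted mixture is dominated by patterns 2 ([0,1,2], rising), 6/7
(late-only change) and 11 ([0,−1,−2], falling); the cluster table above
recovers those proportions, and 92% of significant proteins land in their
planted cluster at this noise level.

```r
preset <- pcsilac_preset(category_overrides = pcsilac_categories(), seed = 42)
pc   <- generate_pcsilac_series(preset)
fits <- fit_kinetics(pc$series)
m <- function(x) median(x[!is.na(x)])
sprintf("median kd ratio %.2f, Vs ratio %.2f, T1/2 %.1f -> %.1f h",
        m(fits$kd_ratio), m(fits$vs_ratio),
        m(fits$thalf_control), m(fits$thalf_treated))
#> "median kd ratio 1.82, Vs ratio 0.55, T1/2 51.9 -> 32.3 h"
```

Read: drug treatment nearly doubles decay rates (median ratio ~1.8), halves
synthesis (~0.55) and drops the median half-life from ~52 h to ~32 h —
the global proteostatic shift the preset is calibrated to (true preset
medians: 1.73, 0.57, 55.9 h → ~32 h).

## Command line

A thin CLI over the same functions is installed at
`system.file("cli/hsp90flux.R", package = "hsp90flux")` with subcommands
`simulate`, `filter`, `cluster`, `kinetics`, `nanostring`, `align` and
`report` (end-to-end pipeline; see `run_pipeline()`).
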