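# pupilratio

Simulation and analysis of a ratio-based pupillary biomarker of brainstem
injury for neurocritical care: the **DADA index** (Dangerous Alarming Diameter
Assessment, also called the pupil index value), the ratio of the annular iris
surface to the pupil surface,

```
DADA = (IRr^2 - Pr^2) / Pr^2
```

with `IRr` the iris radius and `Pr` the pupil radius (µm). Unlike raw pupil
diameter, the index is invariant to eye size; it falls towards 0 as the pupil
dilates (failure of the parasympathetic Edinger–Westphal nucleus, EWN — the
pattern after subarachnoid haemorrhage) and rises with miosis (spinal
sympathetic failure). The package is aimed at methodologists who want to
study, stress-test or extend this biomarker without animal data.

It provides, as separately usable pieces:

- **`generate_cohort()`** — a seeded synthetic-cohort generator emulating a
  three-group experiment (control n = 5, sham n = 5, study/SAH n = 12) via a
  latent-severity model: per group, truncated-normal degenerated-neuron
  densities drive monotone maps onto the published pupil-diameter and DADA
  ranges, plus a histological degeneration percentage with a configurable
  count of study subjects beyond the 80 % death threshold (default 8 of 12).
- **`mann_whitney_u()`, `kruskal_wallis()`, `spearman_rho()`, `bonferroni()`**
  — from-scratch small-sample nonparametric tests: exact tie-aware
  Mann–Whitney p by complete enumeration of label assignments, tie-corrected
  Kruskal–Wallis, Spearman with exact permutation p for n ≤ 8, all verified
  against brute-force oracles in the test suite.
- **`classify_fixed_dilated()` vs `classify_dada()`** — the head-to-head
  deceased/viable classification: a fixed-and-dilated pupil-diameter
  threshold against a DADA criterion that routes the index through a
  monotone (pool-adjacent-violators) calibration onto degeneration
  percentage, deceased only when the prediction strictly exceeds 80 %.
- **`run_pipeline()` / `render_report()`** — end-to-end orchestration with
  Kruskal–Wallis-gated Bonferroni post-hocs, study-group Spearman
  correlations, both classifications, and deterministic JSON/CSV/markdown
  reports. A thin CLI lives at `inst/scripts/pupilratio`
  (`generate | analyze | report`).

## Worked example

```r
library(pupilratio)

ch <- generate_cohort(seed = 7)   # 22 subjects: 5 control, 5 sham, 12 study
head(as.data.frame(ch), 3)
#>           id   group pupil_radius dada_index degen_density degen_pct
#> 1 control_01 control       3292.5     1.7857        4.1548    2.8534
#> 2 control_02 control       2906.6     2.4042        2.8054   10.1515
#> 3 control_03 control       2711.2     2.7156        2.1836    8.3762

rep <- run_pipeline(seed = 7)

# group comparisons (one Kruskal-Wallis per variable, then gated post hocs)
rep$kruskal_wallis$dada_index
#> asymptotic (dada_index, two-sided): H = 16.194, p = 0.0003046

# study-group correlations (N = 12)
for (cr in rep$correlations) cat(sprintf("%s: rho = %.3f\n", cr$pair, cr$rho))
#> dada_index vs pupil_diameter: rho = -0.993
#> dada_index vs degen_density: rho = -1.000
#> pupil_diameter vs degen_density: rho = 0.993

# the classification contrast
rep$classifications$pupil_diameter
#> Classification by pupil_diameter (threshold 8000): 12 deceased, 10 viable
rep$classifications$dada_index
#> Classification by dada_index (threshold 80): 8 deceased, 14 viable

interpret_dada_change(baseline_dada = 2.32, current_dada = 1.06)
#> [1] "cranial_parasympathetic_failure"
```

Reading the numbers: every one of the 12 study subjects has a fixed, dilated
pupil above the 8000 µm threshold and would be called deceased on diameter
alone, but only 8 of them sit in the > 80 % EWN-degeneration regime that the
calibrated DADA criterion flags — the other 4 remain viable despite their
pupil size. The strong negative study-group correlations of the index with
pupil diameter and with degenerated neuron density (−0.97 to −1.0 across
seeds) are the regime the biomarker's claim rests on. A halving of the index
against baseline is read as cranial parasympathetic failure; a rise would
indicate spinal sympathetic failure.

## Vignette

`vignettes/pupilratio-methods.Rmd` documents the model and its assumptions:
the latent-severity construction, the implied-iris inconsistency in the
published summaries and the table-faithful versus fixed-iris modes, exact
test conventions, calibration behaviour at the 80 % boundary, and known
limitations of the synthetic cohorts.
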