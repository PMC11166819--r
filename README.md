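# mplung

Functional lung MRI without contrast agents or breathing manoeuvres:
`mplung` decomposes free-breathing dynamic MRI series voxel-by-voxel with
the **matrix-pencil method** into amplitude components at the respiratory
and cardiac frequencies, turning a plain time-resolved acquisition into
**fractional-ventilation** and **relative-perfusion** maps. On top of the
maps it quantifies regional impairment — ventilation and perfusion defect
percentages (VDP, QDP), matched V/Q defects (VQD_match) and a defect
distribution (clustering) index (DDI), whole-lung and per lung side — and
ships the cohort statistics stage used to compare patient groups. The
package targets researchers following up conditions with one-sided lung
involvement (the motivating case is congenital diaphragmatic hernia in
school-aged children), where side-specific numbers matter and
conventional spirometry cannot provide them.

## The model

A registered lung voxel's series is modelled as a sum of damped
sinusoids,

    y_n ≈ Σ_k c_k z_k^n ,   z_k = exp((d_k + 2πi f_k)/f_s),

with poles from the SVD-truncated Hankel pencil and amplitudes by least
squares. Fractional ventilation is the respiratory-frequency amplitude
over the voxel's temporal mean; perfusion is the cardiac-frequency
amplitude. A voxel is *defective* when its map value falls below 0.70 of
the median over the lung area of its own coronal slice; VDP/QDP are the
defective shares of lung volume, and side-specific values use the
whole-lung denominator so both sides sum exactly to the whole-lung
value. Everything is validated against a synthetic phantom generator
(realistic acquisition geometry, plantable defects, ground truth), so no
patient data are needed to test or demonstrate the pipeline. See the
methods vignette (`vignettes/mp-lung-mri.Rmd`) for the full design.

## Worked example

Simulate a subject with a left-sided defect covering 20% of the left
lung, analyse it, and look at the metrics:

```r
library(mplung)

cfg <- phantom_config(defect_side = "left", defect_fraction = 0.2, seed = 7)
ph  <- generate_phantom_series(cfg)
res <- run_subject(ph$series, ph$mask, meta = list(hernia_side = "left"))

res$freqs
#> cardinal frequencies: f_resp = 0.3000 Hz, f_card = 1.2500 Hz
res$metrics
#> VDP 15.82%  QDP 18.31%  VQD_match 8.26%
#> DDI_V 9.950  DDI_Q 6.241 (radius 3)
#> VDP by side: affected 11.76%, non_affected 4.07% (whole-lung denominator)
```

The planted frequencies (0.30 and 1.25 Hz) are recovered exactly, and
the defect shows up where it was planted: the affected (left) side
carries 11.76 of the 15.82 VDP percentage points. The ~4% on the healthy
side is the expected background rate of a relative-median threshold over
a heterogeneous amplitude field — healthy controls show nonzero VDP for
the same reason.

Group statistics run from raw per-subject tables or directly from
printed group summaries. Reproducing a published contrast (VDP,
large-defect patients vs controls, Games-Howell):

```r
s  <- subset(reference_cohort_summaries("overall"), outcome == "vdp_pct")
gs <- group_summary(s$group, s$mean, s$sd, s$n)
posthoc_from_summary(gs, c("control", "large_CDH"), "games_howell")
#>    group1    group2 mean_difference  ci_low  ci_high  p_adjusted       method
#> 1 control large_CDH            8.59 3.57776 13.60224 0.001574296 games_howell
```

i.e. a mean difference of 8.59 percentage points with adjusted CI
(3.58, 13.60) — matching the published interval to the rounding of the
two-decimal inputs.

A thin CLI wraps the same functions: `inst/cli/mplung
<simulate|analyze|cohort-stats> [options]`.

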