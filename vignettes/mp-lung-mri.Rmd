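---
title: "Matrix-pencil mapping of lung ventilation and perfusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrix-pencil mapping of lung ventilation and perfusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mplung)
```

## The measurement model

During free tidal breathing, the signal of a lung parenchyma voxel in a
rapid dynamic MRI series is modulated periodically at two cardinal
frequencies: the respiratory rate (air content changes the proton density
per voxel) and the heart rate (pulsatile blood volume). `mplung` models a
registered voxel time series as a sum of exponentially damped sinusoids,

$$ y_n \approx \sum_k c_k z_k^{\,n}, \qquad z_k = e^{(d_k + 2\pi i f_k)/f_s}, $$

and estimates the poles $z_k$ with the matrix-pencil method: the Hankel
data matrix of the series is reduced by an SVD truncated to the dominant
singular values, the poles are eigenvalues of the shifted
right-singular-vector pencil, and the complex amplitudes $c_k$ follow by
linear least squares against the pole Vandermonde system. Conjugate pole
pairs merge into one real component with amplitude $2|c_k|$ (a real pole
contributes $|c_k|$). On noiseless sums of bin-aligned tones this
reproduces the single-bin DFT amplitude to machine precision, which is
exactly the cross-check run by the test suite (`dft_amplitude_oracle()`).

From the per-voxel decomposition we keep two numbers: the amplitude at
the respiratory frequency and the amplitude at the cardiac frequency,
each taken from the component nearest the globally estimated frequency
within ±`freq_tol` (default 0.1 Hz; exact ties resolve toward the lower
frequency so degenerate spectra stay deterministic). **Fractional
ventilation** is the respiratory amplitude divided by the voxel's
temporal mean signal — "fractional" read as modulation relative to
baseline. **Relative perfusion** is kept as the raw cardiac-frequency
amplitude, because the defect rule below compares voxels only within a
slice and is invariant to any per-slice scaling; a baseline-normalized
variant would change nothing downstream. Neither map measures absolute
air or blood flow; only impairment relative to the rest of the lung is
detected.

The cardinal frequencies themselves are estimated once per subject from
the whole-lung mean series (respiratory band, default [0.1, 0.6) Hz) and
from the heart-region mean when the mask labels one (cardiac band,
default [0.6, 3.0] Hz). The bands cover pediatric tidal breathing and
heart rates and are configurable; a band whose best component does not
rise 3-fold above the residual noise floor is reported as a failure
rather than silently producing a map. Whether per-voxel frequencies
should be fitted freely or locked to the global estimates is not
determinable from published descriptions of the method; this package
locks them to the global values with ±`freq_tol` matching, which is the
more robust choice at the SNR of individual voxels.

## Defect quantification

A lung voxel is called defective when its map value falls **strictly
below 0.70 of the median** over the segmented lung area of its own
coronal slice. Strict inequality matters: a slice with identical values
has no defects, the only behaviour consistent with healthy lungs not
being wholly defective. The median includes the candidate voxel itself —
the literal reading of "all pixels inside the region of interest". The
ventilation defect percentage (VDP) and perfusion defect percentage
(QDP) are the defective shares of whole-lung volume; VQD~match~ is the
share defective in both.

Side-specific VDP/QDP relate each side's defect count to the **whole
lung's** voxel count, so the two sides sum exactly to the whole-lung
value. This convention is verifiable from the published group tables:
the control side means 8.62 + 6.91 reproduce the whole-lung 15.53
exactly (similarly 4.68 + 19.44 = 24.12 and 6.79 + 7.74 = 14.53). The
per-side VQD~match~ and clustering indices instead use the side's own
voxels as reference region — the published side VQD values do not sum to
the whole-lung value, but their mean matches it, which is what a
per-side denominator produces.

The **defect distribution index** (DDI) quantifies how clustered the
defects are. Published descriptions are qualitative (denser and closer
defect voxels give higher values), so this package defines a concrete
instantiation: per slice, each defect voxel gets a local density
$\rho_i$ — the occupied fraction of its radius-$R$ Euclidean disc
(centre excluded, $R$ = 3 voxels by default) — weighted by
$\sqrt{c_i}$, the size of its 8-connected in-plane component; the slice
score is the mean, and slices combine weighted by defect count. The
index is 0 exactly when no defect voxel has a neighbour within $R$,
grows when clusters aggregate, and is computed in-plane because the
acquisition is multi-slice 2D with 12 mm slices against 3.3 mm in-plane
voxels. Values are in arbitrary units and are **not** claimed comparable
in magnitude to other implementations of a clustering index; the test
suite therefore checks order properties (aggregation never decreases the
index, solid blocks rank above scattered voxels, translation and slice
order leave it unchanged), not magnitudes.

## Preprocessing

Motion compensation is per-slice integer translation to a baseline
frame: the frame whose whole-lung mean intensity is closest to the
temporal median (the mid-respiratory state, ties to the earliest frame),
with shifts estimated by FFT cross-correlation and exposed voxels filled
by edge replication. Deformable registration is deliberately out of
scope: the spectral stage needs only approximate voxel correspondence at
the scale of the synthetic data this package is validated on, and a
frame whose correlation peak is weak (normalized correlation < 0.3) is
left unshifted and flagged instead of being dragged to a spurious
optimum. An estimated shift above a quarter of the grid is treated as
registration failure. Side labels (right/left lung, heart) always come
from the mask file; the package never infers anatomical side from image
orientation, avoiding radiological-vs-anatomical convention bugs. A
fallback Otsu-threshold segmentation exists for mask-less input but is a
convenience, not a validated segmenter.

## The synthetic phantom

Because no patient data ship with the package, every downstream stage is
validated on a synthetic generator that emulates the acquisition
geometry: ~150 frames per slice at 3.3 frames/s (about 45 s of free
breathing), 8–14 coronal slices (default 10), 3.3 × 3.3 × 12 mm voxels.
Two tapering lung ellipses with a cardiac notch carry the signal model
$S_v(t) = S_0 (1 + a_v \sin(2\pi f_\mathrm{resp} t + \varphi) + b_v
\sin(2\pi f_\mathrm{card} t + \psi)) + \varepsilon(t)$; a heart region
carries cardiac-only modulation; surrounding body tissue is static.
Defaults: $f_\mathrm{resp}$ = 0.30 Hz, $f_\mathrm{card}$ = 1.25 Hz
(plausible school-age respiratory and heart rates), mean fractional
amplitudes 0.12 (respiratory) and 0.03 (cardiac), additive noise 2% of
baseline. The amplitude fields $a_v, b_v$ are Gaussian-blurred white
noise (kernel 4 voxels) rescaled to a target mean and coefficient of
variation (default 0.25) — spatial heterogeneity is essential, since a
relative-median threshold over a homogeneous lung would yield zero VDP,
whereas healthy controls show nonzero values. Published maps do not
report amplitude distributions, so these are plausibility choices, fixed
once, not calibrated to any cohort. Defects are contiguous blobs (the
target fraction of affected-side voxels nearest a random seed voxel, in
mm) whose amplitudes are attenuated multiplicatively (default 0.4);
ventilation and perfusion defects are co-located unless decoupled.
Phases are shared across voxels — the defect rule uses amplitudes only —
and are drawn before defect placement so a defect-free twin with the
same seed shares geometry, fields and phases, which is what the recovery
tests compare against.

What the phantom does **not** emulate: realistic anatomy, deformable
breathing motion, k-space physics, B1/coil shading, or perfusion-
specific temporal waveforms. Passing tests therefore demonstrate that
the numerical chain recovers what the signal model plants, not that the
method is clinically validated.

## Numerical choices

* Pencil parameter `L` defaults to ⌊N/3⌋ (standard practice; accepted
  range [N/3, N/2]).
* Model order is chosen automatically as the number of singular values
  ≥ `sv_tol` × the largest, capped at `max_order`. The defaults
  (`sv_tol` = 10⁻³, `max_order` = 16) are set by the weakest signal the
  method must resolve: cardiac modulations are a few percent of the
  baseline signal, so a 10⁻² cutoff relative to the DC-dominated leading
  singular value would discard them; the cap bounds the number of noise
  poles admitted per voxel and keeps the per-voxel cost flat.
* Damped poles are retained and amplitudes are read at the first sample;
  restricting to undamped poles would be an extra assumption the model
  does not need.
* All randomness flows from explicit integer seeds; generators restore
  the caller's RNG state, and identical inputs + config produce
  byte-identical metrics files.

## Cohort statistics

The statistics stage reproduces the analysis design used with this kind
of cohort: one-way ANOVA across control / small-CDH / large-CDH with
post-hoc pairwise contrasts — Tukey-Kramer (studentized range, pooled
MSE) for most outcomes, Games-Howell (per-pair variances, Welch df) for
outcomes with markedly unequal group variances (FEV₁/FVC ratio, VDP),
and Benjamini-Hochberg-adjusted Welch contrasts for the clustering
indices; a mixed (split-plot) repeated-measures ANOVA with
group × lung-side interaction for the per-side outcomes, followed by
Bonferroni-adjusted paired side contrasts per group; and a
Spearman/Benjamini-Hochberg correlation screen. Every between-group
routine accepts either raw per-subject values or printed group summaries
(mean, SD, n) — the two modes agree to 10⁻¹⁰ by construction, and
summary mode lets published tables be re-analysed without subject-level
data. Missing outcomes are handled complete-case per outcome; α = 0.05
throughout. The exact confidence-interval construction used by any
particular original software cannot be pinned down from a published
table alone, so agreement with printed intervals is asserted to the
rounding tolerance that two-decimal inputs propagate (±0.06), and the
bundled reference summaries reproduce printed bounds well within that.

The cohort simulator draws whole-lung outcomes from group-specific
normals and the two side values from a bivariate normal with a
configurable within-subject correlation (default 0.3, a moderate
positive coupling; the published tables do not report it). Its default
means/SDs/n are the bundled reference summaries themselves, so power and
calibration checks run at realistic effect sizes: group sizes 13/7/6,
with one right-sided hernia per patient group and the rest left-sided.

## Problem sizes used in the checks

The test suite validates modules on quarter-size phantoms (48 × 48 × 4,
100 frames) and runs the recovery check at full acquisition scale
(96 × 96 × 10, 150 frames, ~18,000 lung voxels) over 10 seeds; the
statistics calibration uses 500 replicates for the interaction-null
uniformity check and 1000 for the family type-I error of the ANOVA gate
plus post hoc (observed ≤ 0.06 at nominal 0.05). The acceptance script
analyses 3 full-size phantoms per run. These sizes were chosen so a
complete validation runs in minutes on one CPU while still exercising
the method at acquisition dimensions.

## Known limitations

* Translation-only registration cannot follow tissue deformation; with
  real free-breathing data, residual in-plane deformation blurs voxel
  spectra and biases amplitudes low near edges.
* The DDI is one concrete member of a family of clustering indices;
  magnitudes are not transferable between implementations.
* The fallback segmentation assumes lungs are the two largest
  low-intensity components — adequate for the phantom, naive for
  pathology (large bullae, effusions).
* Summary-mode Games-Howell inherits the printed table's rounding;
  intervals are reproducible only to that precision.
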