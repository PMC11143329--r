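---
title: "Symptom-specific network mapping and stimulation tuning for DBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom-specific network mapping and stimulation tuning for DBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Subthalamic deep brain stimulation (DBS) improves tremor, bradykinesia,
rigidity and axial symptoms of Parkinson's disease, but the white-matter
pathways whose stimulation drives each symptom's improvement appear to be
partially segregated. fibertune implements the analysis stack that maps
these symptom-response pathways from a treated cohort and then exploits the
map to tune stimulation parameters for individual patients.

The core statistic is *fiber filtering*. For every streamline $s$ of a
pathway atlas and every stimulation field $E_j$ (one per implanted
hemisphere, in V/mm), the peak magnitude the streamline receives,
$P_{sj} = \max_{x \in s} |E_j(x)|$, is recorded. Across the cohort,
$P_{s\cdot}$ is rank-correlated (Spearman) with the per-symptom percent
improvements, so each streamline is tagged with one correlation coefficient
$R_s$ per symptom domain (plus one for global motor improvement). The
mass-univariate p values are controlled by Benjamini–Hochberg FDR within
each symptom's family of screened streamlines.

Downstream, the *fiber score* of a field against a symptom's model is the
rank correlation between the selected streamlines' $R$ values and the peaks
the field produces along them; a linear map fitted on training patients
converts scores to percent improvements, and *network blending* averages
the per-symptom estimates with weights proportional to the patient's
baseline symptom severities. The *Cleartune* optimizer searches per-contact
cathodic currents $I_c \le 0$ minimizing

$$F = S_{ff} + (A - A_o)^2 \lambda,$$

where $S_{ff}$ is the negative weighted fiber score of the candidate,
$A = \sum_c |I_c|$ the total amplitude, $A_o = 3$ mA the reference
amplitude and $\lambda = 0.02$; the quadratic term penalizes settings far
from the reference amplitude in either direction.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| screening intensity threshold | 1.5 | V/mm | a streamline must see at least this peak ... |
| screening field fraction | 0.005 | – | ... in strictly more than this fraction of fields |
| selection quotas | 1500 / 500 | fibers | top positive / top negative fibers per symptom |
| FDR level | 0.05 | – | per-symptom family of screened streamlines |
| folds $k$ | 10 | – | cross-validation (5 and 7 behave similarly) |
| conductivity $\sigma$ | 0.2 | S/m | homogeneous-medium field model |
| grid spacing / extent | 0.5 / 15 | mm | simulated field grids |
| jitter FWHM | 2.0 | mm | robustness analysis, $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ |
| caps | 4 / 5 | mA | per-contact / total current magnitude |
| $A_o$, $\lambda$ | 3 mA, 0.02 | | penalty reference and factor |
| contact floor | 10 % | of total | contacts below it are zeroed |

Both screening thresholds are read as strict inequalities; the screening is
deliberately permissive (its role is only to drop streamlines never
strongly modulated by any field, whose correlations would be driven by
sub-threshold noise) and results are insensitive to moderate changes.

## The electric-field model

The finite-element stage of clinical pipelines is out of scope here; the
package models each active contact as a point current source in an infinite
homogeneous medium,

$$E(x) = \sum_c \frac{I_c\,(x - p_c)}{4 \pi \sigma\, |x - p_c|^3},$$

storing the magnitude in V/mm on a regular grid. This is a declared
simplification: the downstream statistics consume only suprathreshold field
geometry and are agnostic to field provenance — externally computed NIfTI
magnitude grids can be supplied instead at every entry point. Values within
0.1 mm of a source are clamped to the value at that radius (near-contact
physics does not drive the statistics). Directional segments are modeled as
sources displaced radially by 0.65 mm, which preserves the segment-to-tract
proximity ranking that the monopolar-review validation needs. Spatial
jitter translates a grid rather than resampling it, which matches the idea
of displacing a stimulation volume and is exactly invertible.

## Mirroring and the correlation sample

Each patient contributes two hemisphere fields that code for the same
improvement values, and every field is additionally mirrored across the
mid-sagittal plane so that both hemispheres inform one model. For the
per-streamline correlation, fields whose peak along the streamline is zero
(no spatial overlap — typically the contralateral fields) carry no dose
information for that streamline and are deleted pairwise, so a unilateral
streamline's sample is the roughly $2N$ fields folded into its hemisphere.
Keeping those zero-peak rows as data would pair half of each sample with an
unrelated improvement value and demonstrably collapses the statistic (on a
noiseless synthetic cohort the generating bundle's $R$ drops from about 0.6
to below 0.2). Screening, in contrast, counts all native and mirrored
columns as distinct fields. A streamline needs at least 10 covered fields
for its correlation to be computed.

Cross-validation re-fits everything — screening, correlations, FDR,
selection, linear maps — inside each training fold; the test suite verifies
bitwise that corrupting a patient's improvements cannot change their own
out-of-fold estimate.

## Design choices where the design was open

* **Fiber-score correlation type.** Spearman, consistent with every other
  correlation in the stack; Pearson is available via `method =`. Zero-peak
  streamlines are *retained* in the fiber score (rank information at the
  bottom of the scale), with `dropZero` exposed.
* **FDR before selection.** The candidate pool for top-fiber selection is
  the screened *and* FDR-significant set by default
  (`significantOnly = FALSE` restores the permissive reading).
* **Bilateral combination.** At prediction time the two hemisphere fields'
  fiber scores are averaged per symptom before the linear map, mirroring
  the training-time convention of patient-level averaging.
* **Estimates are clipped** to $[-50, 100]$ percent after the linear map to
  stay on the improvement scale.
* **$S_{ff}$ in the objective** is the negative *weighted fiber score* (a
  quantity in $[-1, 1]$), not the mapped percent improvement: the penalty
  values (0.08 at 5 mA) are only commensurate with a score-scale term. The
  mapped per-symptom and blended percent estimates are reported alongside
  each solution.
* **Optimizer.** A seeded derivative-free global search (monopolar and
  contact-pair coarse grids, Latin-hypercube exploration, Nelder–Mead
  refinement) over sanitized candidates; it matches exhaustive enumeration
  on 0.5 mA-step monopolar/pair problems to within 5 % in the test suite.
  Every evaluated candidate is first made feasible by clipping to the
  per-contact cap, zeroing contacts below 10 % of the total, and rescaling
  to the total cap; this sanitization is idempotent.
* **"3rd contact" start** is interpreted as the third ring counted from the
  tip (1-based index 3) at $-3$ mA, configurable.
* **Hemispheres are optimized independently**, one solution per electrode.
* **Tremor exclusions.** Patients with baseline tremor below 2 points or
  exactly 100 % tremor improvement are excluded from tremor analyses only.
  Missing subscores drop a patient per-symptom, never cohort-wide; missing
  values are never imputed.

## The synthetic study

Because patient imaging cannot be shared, every stage is exercised on a
ground-truth-known synthetic study. The generator emulates: a five-bundle
pathway atlas (tremor, bradykinesia, axial, rigidity, plus a non-responsive
distractor) whose spines are stacked 1.5 mm apart along the lead axis near
a nominal subthalamic target at $(\pm 12, -13, -6)$ mm, mirrored into both
hemispheres, with parallel streamlines scattered at $\sigma = 0.8$ mm;
bilateral four-contact leads placed with 1 mm Gaussian jitter; monopolar
cathodic settings with amplitudes uniform in 1–4 mA; and improvements
generated as a saturating dose response
$\mathrm{imp}_s = \mathrm{clip}(\beta_s \cdot \mathrm{act}_s + \varepsilon,
-20, 100)$ with $\beta_s = 70$ %, activation the mean of
$\min(\mathrm{peak}/0.2\ \mathrm{V/mm},\ 1)$ over the bundle's ipsilateral
streamlines averaged across the two fields, and
$\varepsilon \sim N(0, 10)$ points. Baselines are truncated normals with a
shared severity factor (loading half of each SD), calibrated so the summed
global baseline is about $44.6 \pm 14.3$ points; the tremor component uses
a mean of 3.9 under the hood because flooring at zero truncates a large
left tail (realized tremor mean about 4.6, SD about 4). Slightly negative
improvements (clip at $-20$) model the worsening that the negative-fiber
selection expects. The default problem size is $n = 120$ patients and
$5 \times 200 \times 2 = 2000$ streamlines; the test suite uses a
24-patient, 400-streamline version for unit-level checks and the full
default for the end-to-end properties, with 50 jitter repeats, 20
cross-validation repeats and 200 permutations as its standard analysis
sizes.

What passing tests show — and what they do not: the generator produces
rank-monotone dose-response with additive Gaussian noise and a geometrically
clean bundle stack. Real cohorts add registration error, electrode
localization error, heterogeneous tissue, center effects, medication
changes and non-monotone dose effects, none of which are modeled; recovery
on this generator is a necessary, not sufficient, indication.

### Known limitation: neighboring-bundle contamination

With 1.5 mm bundle spacing, an activation radius of 1.4–2.8 mm and a shared
per-field amplitude, the activations of adjacent bundles correlate at
0.6–0.7 across patients, so streamlines of a neighboring bundle genuinely
rank among a symptom's strongest correlates. Consequently the top-500
positive set contains 55–71 % true-bundle fibers (and the top-500 of a
400-fiber bundle can never exceed 80 %); the non-responsive distractor,
which sits adjacent to rigidity at the rostral end of the bundle stack,
contributes up to a third of rigidity's elite set. The cross-validated blended estimates and
the symptom-specificity validations are robust to this contamination, as
the test suite verifies.

## Numerical choices

Streamlines are resampled at 0.5 mm arc length before any sampling; grid
values are interpolated trilinearly and points outside a grid contribute
zero. Spearman p values are exact (full enumeration) for $n \le 9$ and use
the t approximation otherwise. Ties take average ranks everywhere;
selection ties at a quota cutoff break by streamline index. Degenerate
cases are explicit: zero-variance vectors flag a streamline as dropped, a
constant-score training set yields a flagged constant map, an all-zero
candidate is an invalid solution with an infinite objective, and an
all-zero stimulation setting simulates to a zero field with a warning.
Every stochastic stage (atlas, cohort, folds, permutations, jitter,
optimizer) draws a named sub-seed from one master seed, so stages are
independently reproducible.
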