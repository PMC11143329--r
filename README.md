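# fibertune

Symptom-specific fiber filtering, network blending and stimulation tuning
for deep brain stimulation (DBS).

Subthalamic DBS improves tremor, bradykinesia, rigidity and axial symptoms
of Parkinson's disease, but the white-matter pathways driving each
symptom's improvement are partially segregated. fibertune maps these
symptom-response pathways from a treated cohort and uses the map to
estimate outcomes for unseen patients and to suggest stimulation settings
tailored to a patient's symptom profile. It is aimed at researchers in
neuromodulation connectomics who work with tractography atlases,
stimulation-field models and motor outcome scores.

## The method

**Fiber filtering.** For every atlas streamline *s* and every stimulation
field *E<sub>j</sub>* (two per patient, plus mirrored copies so both
hemispheres inform one model), the peak field magnitude along the
streamline, *P<sub>sj</sub> = max<sub>x∈s</sub> |E<sub>j</sub>(x)|* (V/mm),
is recorded. Streamlines must exceed 1.5 V/mm in more than 0.5 % of fields
to enter the model. Each screened streamline is then tagged with Spearman
rank correlations between its peaks and the cohort's percent improvements —
one *R* per symptom (tremor, bradykinesia, rigidity, axial) and one for
global motor improvement — thresholded at FDR-corrected *p* < 0.05.

**Network blending.** The fiber score of a field against a symptom model
is the rank correlation between the selected streamlines' *R* values (top
1500 positive, top 500 negative) and the peaks the field produces along
them. Scores are mapped to percent improvements by a linear model fitted on
training patients and averaged with weights proportional to the patient's
baseline symptom severities:

    est = Σ_s w_s · est_s,   w_s = baseline_s / Σ baseline_s

**Cleartune.** Per-contact cathodic currents *I<sub>c</sub>* ≤ 0 are
searched (derivative-free, seeded) to minimize

    Fval = S_ff + (A − A_o)² · λ

with *S<sub>ff</sub>* the negative weighted fiber score, *A* = Σ|I<sub>c</sub>|,
*A<sub>o</sub>* = 3 mA and λ = 0.02, under a 4 mA per-contact cap, a 5 mA
total cap, and zeroing of contacts below 10 % of the total current.

Stimulation fields are simulated with an analytic point-source conductor
model (σ = 0.2 S/m) or loaded from NIfTI magnitude grids; tractograms are
read and written as TRK, TCK or a plain-text JSON dialect. A ground-truth
synthetic study (atlas, cohort, improvements) makes every stage testable
without patient data. See the vignette
(`vignettes/symptom-network-mapping.Rmd`) for the model details and design
decisions.

## Worked example

```r
library(fibertune)

# a ground-truth-known synthetic study: 5-bundle atlas, 60 patients
cfg    <- synthConfig(nPatients = 60)
atlas  <- generateAtlas(cfg, seed = 42)
cohort <- generateCohort(atlas$tractogram, atlas$truth, cfg, seed = 42)

# symptom-network library: screen, correlate, FDR-correct, select
model <- buildTractModel(cohort, atlas$tractogram)
model
#> TractModel over 2000 streamlines
#>   tremor           screened  1948  significant  1572  selected  1268
#>   bradykinesia     screened  1948  significant  1508  selected  1468
#>   axial            screened  1948  significant  1324  selected  1324
#>   rigidity         screened  1948  significant  1626  selected  1626
#>   global           screened  1948  significant  1320  selected  1320

# 10-fold cross-validated estimation of global improvement
cv <- crossvalidate(cohort, atlas$tractogram, cv = cvConfig(k = 10, seed = 1))
round(cv$summary[, c("R", "p", "Rsingle")], 3)
#>       R     p Rsingle
#> 1 0.352 0.006   0.349

# suggest stimulation currents for patient 1, weighted by their baselines
maps <- fitCohortMaps(cohort, model)
bl <- unlist(patients(cohort)[1, paste0("baseline_", symptomNames(cohort))])
names(bl) <- symptomNames(cohort)
sol <- suggestSettings(cohort@electrodes[1:2], model, maps, baselines = bl)
sol[[1]]
#> CleartuneSolution
#>   currents (mA): -3.00, -0.00, -0.00, -0.00
#>   Fval -0.1464 = S_ff -0.1464 + penalty 0.0000 (A = 3.00 mA)
#>   blended estimate: 53.2%
```

Reading the output: of the 2000 atlas streamlines, 1948 pass the intensity
screen and 1300–1600 per symptom survive FDR correction. Out-of-fold
blended estimates rank-correlate with the simulated global improvements at
R = 0.35 (p = 0.006) on this 60-patient cohort, slightly above the
single-tract model trained directly on global improvement (R = 0.35). For
patient 1, the optimizer proposes −3 mA on the deepest contact — the one
abutting this patient's dominant (tremor) bundle — at the penalty-free
reference amplitude, with an estimated blended improvement of 53 %.

A thin command-line wrapper over the same pipeline is installed with the
package (`inst/scripts/fibertune`), e.g.
`Rscript inst/scripts/fibertune synth --seed 1 --out out/`.

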