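# amyquant

Regional quantification of amyloid PET imaging, and the statistics used
to compare quantification strategies. The package is aimed at PET
methodologists and trialists who need to ask: *which reference region,
with or without partial volume correction, static SUVR or full kinetic
modeling — and what does each choice buy in statistical power?* Every
estimator can be exercised on synthetic phantoms and simulated kinetics
with known ground truth.

## What it computes

- **SUV / SUVR** — standardized uptake values
  (activity ÷ dose/weight, unitless at 1 g/mL tissue density) and
  target-to-reference ratios over a configurable evaluation window
  (default 40–70 min post-injection), under FreeSurfer-based
  reference-region schemes: cerebellar cortex (`cer`), brainstem
  (`bs`), core white matter (`cw`), total white matter (`tw`), plus a
  configurable mean-cortical composite (`mc`).
- **RSF/GTM partial volume correction** — blur each region's indicator
  with the scanner PSF to form regional spread functions, build the
  mixing matrix ω (observed ← source), and solve ωT = t by least
  squares for true regional means, per frame for dynamic data. The same
  discrete blur drives the digital phantom generator, so matched-PSF
  correction is exact on noise-free phantoms.
- **Logan graphical analysis** — the late-time slope of
  ∫C_T/C_T vs ∫C_R/C_T estimates DVR (BP_ND = DVR − 1) with a
  reference-tissue input (optional C_R/k₂′ term), or V_T with an
  arterial plasma input after parent-fraction (metabolite) correction.
- **Longitudinal statistics** — per visit pair: delta, delta%, annual
  rate; cohort summaries with paired t-tests, Cohen's d =
  mean(rate)/SD(rate), test–retest variability
  TRT% = (|M1 − M2|/M1) × 100%, Pearson agreement between methods, and
  per-arm clinical-trial sample sizes for detecting a 25% or 50%
  reduction in accumulation rate (two-tailed α = 0.05, 80% power,
  exact noncentral-t iteration).
- **Synthetic data** — Feng-type input functions, one-/two-tissue
  compartment TACs with known V_T/BP_ND, box/ellipsoid label phantoms
  with PSF blur and seeded Gaussian noise, and longitudinal cohorts
  with a stated rate distribution.

## Worked example

Simulate 70-minute one-tissue kinetics where the target's true DVR
against the reference is 2.0 (same K1, half the k2), fit Logan both
ways, then summarize a simulated longitudinal cohort:

```r
library(amyquant)

sched <- default_frame_schedule()              # 33 frames, 70 min
aif   <- simulate_input_function()
cer   <- simulate_tissue_tac(compartment_spec("one_tissue", K1 = 0.2, k2 = 0.2), aif, sched)
ctx   <- simulate_tissue_tac(compartment_spec("one_tissue", K1 = 0.2, k2 = 0.1), aif, sched)

logan_reference(ctx, cer, tstar = 30)
#> Logan reference-tissue fit: DVR = 1.9998 (BP_ND = 0.9998)
#>   t* = 30 min, 8 points, intercept -5.387 min, R^2 = 0.999999

logan_plasma(ctx, aif, tstar = 30)
#> Logan plasma-input fit: V_T = 2.0003
#>   t* = 30 min, 8 points, intercept -10.04 min, R^2 = 1.000000

cohort <- simulate_longitudinal_cohort(sim_cohort_spec(seed = 42))
change_metrics(cohort)
#> Longitudinal change summary (n = 59)
#>   delta  : 0.0378 +/- 0.0699
#>   delta% : 4.14 +/- 7.84
#>   rate   : 0.0248 +/- 0.0387 per year
#>   paired t = 4.162, p = 0.000106
#>   Cohen's d (rate) = 0.641

sample_size_per_arm(0.04, 0.04, power_spec(reduction = 0.5))
#> [1] 64
```

The DVR and V_T recover the simulated truth (2.0) to a fraction of a
percent; the cohort's mean annual rate (0.0248/yr) and effect size are
what the generator's rate distribution (0.02 ± 0.04/yr) implies; 64
subjects per arm suffice to detect a halving of a 0.04 ± 0.04/yr
accumulation rate at 80% power.

A command-line front end covering the same pipeline (SUVR tables, Logan
fits, longitudinal summaries, sample sizes, simulation) is installed at
`inst/cli/amyquant`:

```sh
Rscript inst/cli/amyquant suvr --pet pet.nii.gz --timing timing.csv \
    --seg aseg.nii.gz --scheme default --ref cer --pvc rsf --psf-fwhm 6 -o out.csv
```

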