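---
title: "Methods: amyloid PET quantification in amyquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amyloid PET quantification in amyquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyquant)
```

# Scope and model

`amyquant` quantifies amyloid burden from PET images of tracers such as
[^11^C]-PiB, and compares quantification strategies on synthetic data
with known ground truth. The measurement chain is:

1. **Regional means.** A FreeSurfer-style label volume assigns each voxel
   to a named region; a regional time–activity curve (TAC) is the
   unweighted per-frame mean over the region's voxels. Static uptake is
   summarized by a duration-weighted mean of the frames fully contained
   in an evaluation window (default 40–70 minutes post-injection, the
   standard PiB uptake window).
2. **SUV and SUVR.** SUV normalizes activity by injected dose per body
   weight (tissue density taken as 1 g/mL, so SUV is unitless). SUVR is
   the ratio of a target region's windowed mean to that of a reference
   region assumed free of specific binding. Four reference composites
   are built in: cerebellar cortex (`cer`, labels 8/47), brainstem
   (`bs`, label 16, a pontine surrogate), core white matter (`cw`,
   corpus callosum 251–255 plus unsegmented white matter 5001/5002) and
   total cerebral white matter (`tw`, 2/41 plus the `cw` labels). The
   mean cortical composite `mc` defaults to seven bilateral aparc region
   pairs (precuneus, superior frontal, rostral middle frontal, lateral
   and medial orbitofrontal, superior and middle temporal); the exact
   membership of published mean-cortical composites varies between
   pipelines, so this list is a configurable default, not a claim of
   equivalence to any particular one.
3. **Partial volume correction (RSF/GTM).** Scanner resolution mixes
   activity between neighboring structures. The geometric transfer
   matrix model treats each observed regional mean as a weighted sum of
   true regional means: blur each region's binary indicator with the
   scanner point spread function (PSF) to get its regional spread
   function, average it over every observed region to form the mixing
   matrix $\omega$, and solve $\omega T = t$ for the true means $T$ by
   least squares. With the background (label 0) included as a region,
   the blurred indicators partition unity, so each row of $\omega$ sums
   to at most one.
4. **Kinetic modeling (Logan graphical analysis).** For reversible
   tracers, plotting $\int_0^t C_T/C_T(t)$ against
   $[\int_0^t C_R + C_R(t)/k_2']/C_T(t)$ becomes linear at late times;
   the slope is the distribution volume ratio (DVR), and
   $BP_{ND} = DVR - 1$. With an arterial plasma input the abscissa uses
   $\int_0^t C_p/C_T(t)$ and the slope is the total volume of
   distribution $V_T$. A population parent-fraction curve can be applied
   to the plasma input to correct for radiolabelled metabolites before
   the fit.
5. **Longitudinal statistics.** Per visit pair: absolute change
   $\Delta = M_2 - M_1$, percent change $100\,\Delta/M_1$, annual rate
   $\Delta/\text{interval}$. Cohort summaries report mean ± SD of each,
   a paired t-test of follow-up versus baseline, and Cohen's d for the
   longitudinal change defined as mean(rate)/SD(rate). Test–retest
   variability is $TRT\% = (|M_1 - M_2|/M_1)\times 100\%$, interpretable
   as reproducibility when applied to a cohort in which no true change
   is expected. Trial planning finds the smallest per-arm n for which a
   two-tailed t-test detects a stated fractional reduction of the
   accumulation rate with target power, computed exactly from the
   noncentral t distribution and iterated over n.

# Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Evaluation window | 40–70 | min | Standard PiB uptake window for windowed-static quantification. |
| PSF FWHM | 6 | mm | Typical effective resolution of the whole-body PET systems used for amyloid imaging; always a parameter, never a constant, because the effective resolution is scanner- and reconstruction-specific. |
| GTM condition limit | 1e4 | – | Refuses corrections from near-singular mixing matrices (e.g. duplicated or heavily overlapping spread functions) rather than amplifying noise. |
| Logan `tstar` | 30 | min | Start of the linear fit window for 70-minute scans; late enough for the plot to linearize for PiB-like kinetics, early enough to keep ≥ 8 frames. |
| Logan `k2prime` | omitted | 1/min | The reference-tissue ordinate's $C_R/k_2'$ term is omitted by default (common PiB practice; the term decays relative to $\int C_R$); supplying `k2prime` enables the full ordinate. |
| OLS weighting | unweighted | – | Frame-duration weighting is available but off by default; on noise-free frames it changes nothing and the package takes the simpler estimator as baseline. |
| Trial design | two-sample | – | Matches a placebo-controlled randomized trial with equal arms; a one-sample variant is provided because published power analyses do not always state the design. |
| alpha / power / reduction | 0.05 / 0.80 / 0.25 or 0.50 | – | The conventional two-tailed level, power target and treatment-effect scenarios for anti-amyloid trial sizing. |

# Numerical choices

- **Matched discrete blur.** The Gaussian blur is a separable,
  box-discretized (erf-difference) kernel per axis, truncated at 4
  sigma, renormalized, zero-padded at the field-of-view edge, and
  applied as an explicit convolution matrix per axis. The phantom
  generator and `build_gtm()` share this single operator, so for a
  noise-free phantom blurred with the matched PSF the GTM correction is
  exact up to solver precision — the validation suite checks recovery to
  1e-6 relative on a 64^3 grid. An FWHM of exactly 0 denotes a delta
  PSF (identity), giving an identity mixing matrix.
- **Least-squares solve.** `apply_gtm()` uses a QR solve, never an
  explicit inverse; the condition number (ratio of extreme singular
  values) is computed at build time and checked against the limit at
  solve time.
- **Logan ordinates.** `cumulative_integral()` is a running trapezoid
  through (0, 0) and the frame (mid-time, value) points. The anchored
  first segment makes the integral of a constant TAC $c\,t - c\,t_1/2$
  rather than $c\,t$; this does not affect slopes of proportional
  curves (still exact with $r^2 = 1$) and its late-time effect is
  absorbed by the intercept. The plasma integral is trapezoidal on the
  input's native grid, then the cumulative values are interpolated
  linearly to frame mid-times.
- **Window containment.** Frames only partially overlapping the
  evaluation window are excluded, not fractionally weighted; with
  conventional schedules the window boundaries coincide with frame
  boundaries, so nothing is lost in the standard configuration.
- **Compartment simulation.** Tissue TACs solve the one- or two-tissue
  ODEs by exponential-kernel convolution with a piecewise-linear input
  on a 0.01-minute grid — exact for the interpolated input, and verified
  against an independent stiff ODE solver to 0.1% of peak. Frame values
  are fine-grid averages over each frame interval, mirroring what a
  scanner reconstructs.
- **Degenerate inputs.** Identical groups give t = 0, p = 1; a
  zero-variance nonzero paired difference is an unbounded t (error in
  `paired_test()`, reported as ±Inf with p = 0 inside cohort sweeps); a
  zero-SD rate yields Cohen's d = 0 with an explicit degenerate flag so
  parameter sweeps do not abort.

# Design decisions

- **Composite aggregation is ROI-volume-weighted.** Published pipelines
  differ on whether mean-cortical values pool member regions voxel-wise
  or average per-region values; volume weighting reproduces voxel-level
  pooling exactly for plain means and approximates it after PVC. An
  unweighted mean is available (`weighted = FALSE`).
- **Background is modeled but discarded.** `build_gtm()` includes
  label-0 voxels as a source/observed region by default (without it,
  spill-in from unlabelled tissue is misattributed); its corrected value
  is dropped from `correct_dynamic()` outputs.
- **Reference-region schemes are data, not code.** A YAML/JSON config
  overrides any region or composite of the default scheme per entry;
  regions absent from a given segmentation are dropped (with a message)
  by the SUVR pipeline, because partial configs retain default regions a
  study may lack.
- **Sample size by direct noncentral-t iteration.** The smallest integer
  n with exact power ≥ target, rather than a rounded z-formula;
  `stats::power.t.test` serves as an independent cross-check in the test
  suite, and a vectorized Monte-Carlo trial simulation confirms the
  empirical rejection rate at the returned n sits at the target power.

# What the synthetic data does and does not emulate

The generators produce: Feng-type peaked tri-exponential input functions
(zero before an appearance delay, single early peak, tri-exponential
decay); one- and two-tissue TACs with known $V_T$ and $BP_{ND}$ on the
default 33-frame, 70-minute schedule (4×15 s, 8×30 s, 9×60 s, 2×180 s,
10×300 s); box/ellipsoid label phantoms painted with known activities,
degraded by the PSF and seeded Gaussian voxel noise; and longitudinal
cohorts drawing true baselines and annual rates from stated normals. The
cohort defaults (n = 59 pairs, baseline 1.08 ± 0.31, rate 0.02 ± 0.04
per year, interval 1.7 ± 0.8 years truncated above 0.1) emulate a
longitudinal mutation-carrier cohort quantified with a white-matter
referenced cortical SUVR; the per-visit measurement noise SD of 0.02 is
chosen so that the null cohort's test–retest variability lands in the
few-percent range reported for amyloid SUVR.

Not emulated: scanner-realistic Poisson sinogram noise and
reconstruction (noise is Gaussian in image space), scatter, attenuation,
motion, spatially varying PSFs, segmentation error, and between-scanner
calibration differences. Passing tests therefore demonstrate estimator
correctness under the stated degradation model — matched-PSF GTM
exactness, Logan convergence on noise-free kinetics, calibrated power —
not robustness to every real-world nuisance. In particular, on real data
the PSF is never known exactly, so GTM correction is approximate and its
noise amplification grows with the condition number.

# Validation problem sizes

The test suite and the acceptance script validate at desk scale: 64^3
phantom grids (2 mm voxels) for GTM exactness, 48^3 two-visit phantoms
for the atrophy experiment (true cortical activity +10% with a ~5%
volume loss: the uncorrected SUVR change is attenuated below 10% while
the corrected change recovers 10%), 33-frame kinetic simulations for
DVR ∈ {1, 1.5, 2, 3} and $V_T$ ∈ {1, 2, 5}, 10,000 Monte-Carlo trials
for power calibration, and 100 random instances per statistic against
brute-force formula oracles at 1e-10.

# Known limitations

- Logan graphical analysis is bias-prone under noise (the $1/C_T$
  ordinate correlates noise into the regressor); the package validates
  on noise-free kinetics and does not implement noise-robust variants
  (e.g. multilinear reformulations).
- The Logan DVR bias is not monotone in `tstar` pointwise: where the
  estimate crosses the truth the error can dip near zero early. The
  worst-case error over a DVR grid does shrink as `tstar` grows, which
  is the property the validation asserts.
- No image registration or resampling: PET and label volumes must share
  one grid. No voxelwise SUVR maps, no centiloid conversion, no
  SRTM/MRTM estimators, and no extraction of image-derived input
  functions — plasma inputs are consumed as tables.
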