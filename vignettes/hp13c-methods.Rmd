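---
title: "Quantifying hyperpolarised [1-13C]pyruvate MRI: models, estimators and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hyperpolarised [1-13C]pyruvate MRI: models, estimators and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hp13c)
```

## Scope

Hyperpolarised [1-13C]pyruvate MRI observes the exchange of the
hyperpolarised 13C label from injected pyruvate to lactate, catalysed by
lactate dehydrogenase (LDH). In prostate cancer the lactate signal is driven
by tumour-epithelial metabolism, so imaging metrics (lactate SNR, the
apparent exchange constant kPL) can be correlated with pathology
(percent Gleason pattern 4), diffusion MRI (ADC), and compartmentalised
tissue markers (MCT1/MCT4 staining, LDHA/LDHB/PDHA1 transcript counts).

`hp13c` implements that quantification chain end to end, with a synthetic
data layer in place of patient data, so that every stage - simulation,
noise, SNR mapping, kinetic fitting, histology metrics, cohort statistics -
runs and is testable at desk scale. The packaged 13-tumour reference table
(`reference_cohort()`) is the one piece of real data; everything else is
generated.

## The forward model

Each lesion voxel follows an "inputless" two-site exchange system for the
longitudinal magnetisations of pyruvate ($M_P$) and lactate ($M_L$):

$$
\frac{dM_P}{dt} = b(t) - \left(\tfrac{1}{T_{1P}} + k_{PL}\right) M_P,
\qquad
\frac{dM_L}{dt} = k_{PL}\, M_P - \tfrac{1}{T_{1L}} M_L ,
$$

with $b(t)$ a gamma-variate bolus (arrival 8 s, shape 2.5, scale 4 s by
default - a plausible human input function; nothing downstream depends on
these defaults). Defaults $T_{1P} = 30$ s and $T_{1L} = 25$ s are typical
in-vivo values at 3 T. Radio-frequency consumption is applied discretely:
after each frame is sampled, both pools are multiplied by
$\cos(\theta)^{n_\mathrm{exc}}$, the standard per-frame approximation when
only flip angles, not the pulse-by-pulse timing, are modelled. The measured
signal is $\sin(\theta)\,M$ at the frame time.

The default acquisition schedule is 20 frames at 4 s on a 32 x 32 grid.
Two excitation modes exist: an IDEAL-like mode (both metabolites at 15 deg)
and a spectral-spatial mode (15 deg pyruvate / 40 deg lactate). The
effective number of excitations consuming magnetisation per frame is not
fixed by the acquisition description alone - a multi-echo readout shares
excited magnetisation across echoes - so it is a configurable parameter,
default 2 per frame for both modes.

Integration uses trapezoidal accumulation of the exact decay convolution on
a fine internal grid (0.01 s), vectorised with `stats::filter()`. The test
suite checks it against an independent fixed-step RK4 integration of the
same system (relative tolerance 1e-4) and, for the forward lactate
solution, against `deSolve::lsoda`. Voxels are spatially independent: no
point-spread or coil model is simulated, because no point-spread
information is available for the emulated acquisition.

Noise is always Rician: each voxel value $v$ becomes
$|(v + g_1) + i\,g_2|$ with $g_1, g_2 \sim N(0, \sigma^2)$. Background
voxels therefore follow a Rayleigh distribution with mean
$\sigma\sqrt{\pi/2}$ and standard deviation $\sigma\sqrt{2 - \pi/2}$, which
is what makes the $\sqrt{2}$ factor in the SNR definition self-consistent.
Gaussian noise on magnitudes is never used.

## SNR, total carbon, ADC

The metabolite SNR of a region is

$$
\mathrm{SNR} = \frac{\mathrm{mean}(SI_\mathrm{ROI}) -
\mathrm{mean}(SI_\mathrm{noise})}{\sqrt{2}\,\mathrm{SD}(SI_\mathrm{noise})},
$$

with noise statistics from a background-only region (the package fixes a
rectangular edge strip, recorded in every sidecar, for reproducibility) and
the sample standard deviation (n-1). Because the expression is linear in
the ROI signal, the ROI mean of the voxelwise SNR map equals the SNR of the
ROI-mean signal; both views coincide exactly and the package returns the
common value. Signals are summed over frames per voxel *before* any ROI
statistic.

Total carbon maps sum all metabolite channels and frames per voxel; their
noise statistics come from the final-frame pyruvate image restricted to the
noise region, the time point at which hyperpolarised signal has decayed.
Note the scale consequence: a single-frame noise estimate is smaller than
the summed-map noise level by roughly $\sqrt{n_\mathrm{frames}}$, so
total-carbon SNR values are not commensurate with the per-metabolite SNR
values computed from summed maps. The package keeps the two definitions as
stated rather than harmonising them.

ADC fitting is deliberately log-linear ordinary least squares of
$\log S = \log S_0 - b\cdot \mathrm{ADC}$ over the five-b-value protocol
(150-1400 s/mm2; a separate b = 2000 acquisition is excluded by
convention), matching deterministic scanner-generated maps. Monte-Carlo
tests put the median recovery error under 2% Rician noise well inside 5%.

## kPL estimation

The estimation model lumps lactate T1 decay and RF consumption into one
effective loss rate $\rho_\mathrm{eff}$, giving
$L(t) = k_{PL}\int_0^t P(\tau)\,e^{-\rho_\mathrm{eff}(t-\tau)}d\tau$ with
the measured pyruvate curve as input - the standard identifiable choice for
constant-flip acquisitions.

The primary estimator works in the frequency domain: with discrete Fourier
transforms $\hat P$, $\hat L$ on the uniform frame grid, the model
linearises to

$$
i\omega\,\hat L(\omega) = k_{PL}\,\hat P(\omega)
  - \rho_\mathrm{eff}\,\hat L(\omega),
$$

solved by ordinary least squares with real and imaginary parts stacked as
separate equations and equal weight per frequency (optional weights are
exposed). Negative solutions are clipped to zero and flagged. A time-domain
nonlinear least-squares estimator (bounded L-BFGS-B on the forward
solution) serves as the cross-check; both agree to well under 1% as the
frame interval shrinks.

Numerical behaviour, measured by the test suite:

* On model-consistent noiseless 20-frame/4-s inputs the frequency-domain
  discretisation bias is below 2.5% across the 0.003-0.018 1/s range; the
  time-domain fit recovers rates to better than 0.1%.
* On fully simulated series the lumped model is only approximate - discrete
  RF consumption is not an exponential within a frame, and the DFT assumes
  periodicity while the lactate curve has not fully decayed by the last
  frame. At the default schedule this biases the frequency-domain estimate
  by 4-7% (bounded at 10% in the tests); at a 40 deg lactate flip the
  mismatch reaches ~13%. The time-domain estimator stays within 5%
  end-to-end.
* Under heavy noise the frequency-domain least squares is attenuated
  (the noisy $\hat L$ appears in the design matrix, a classical
  errors-in-variables effect): at peak-pyruvate SNR 30 with low lactate
  SNR the median attenuation is 20-30%. The time-domain estimator keeps
  its median within 15% of truth there, and is the recommended choice for
  noisy single curves. Voxelwise maps mitigate the magnitude-noise pedestal
  by the standard second-moment correction
  $\sqrt{\max(S^2 - 2\hat\sigma^2, 0)}$, with $\hat\sigma$ estimated from
  the Rayleigh background of the final pyruvate frame.

Per-tumour "mean kPL" is the average of voxelwise estimates over the ROI
(the ROI-mean-curve alternative is available via `voxelwise = FALSE`).
Before fitting, each metabolite is divided by $\sin(\theta)$ so unequal
flip angles do not bias the rate.

## The synthetic histology and cohort layer

`generate_cell_table()` draws per-cell records: a compartment (epithelial /
stromal), staining categories (negative / weak / moderate / strong,
multinomial given a positivity probability) for MCT1, MCT4 and nuclear
HIF-1alpha, and negative-binomial transcript counts for LDHA, LDHB and
PDHA1 (RNAscope-style counts are overdispersed; Poisson is the
infinite-dispersion limit). The defaults encode only the qualitative
pattern reported for prostate cancer - MCT1 mostly epithelial, MCT4 mostly
stromal, LDHA up / LDHB down / PDHA1 down and nuclear HIF-1alpha up with
increasing aggressiveness, SLC16A1 flat between Gleason patterns 3 and 4 -
and never unpublished group means, which are not printed anywhere. All
defaults live in one `effect_config()` object.

`generate_cohort()` links histology to imaging. A per-lesion latent
aggressiveness variable (tied to the lesion's %GP4 with weight 0.5) drives,
through a Gaussian copula with coupling `corr`, five lesion-level latents:
ground-truth kPL (mapped into 0.003-0.018 1/s), bolus amplitude
(perfusion), epithelial cell count, epithelial LDHA+LDHB copy means, and
epithelial MCT4 positivity. At `corr = 0` the metrics are independent
(used for null calibration); at `corr = 0.9` the realized lactate SNR and
combined epithelial LDH reach a median Spearman correlation of about 0.8 at
n = 13. Making the amplitude itself copula-driven (rather than independent
noise) is what lets the knob govern the *realized* imaging metric, not just
the ground truth.

With `imaging = TRUE` each lesion is simulated as a 32 x 32 phantom, noised
(sigma scaled so the time-summed pyruvate SNR is near the cohort's printed
scale), and quantified end-to-end; the mean fitted kPL is measured, not
copied. The `imaging = FALSE` fast path replaces the voxel pipeline with
the analytic noiseless ROI curves plus sampling noise; it exists for
large-replicate calibration studies (500-seed type-I error rates run in
about two minutes at 13 lesions). Problem sizes in the tests - 13-lesion
cohorts, 100-lesion null checks over 40-500 seeds, 500-cell glands,
197/250-sample expression tables - were chosen to match the emulated study
sizes while keeping each check to seconds or a few minutes.

What passing the synthetic checks does and does not show: the generator
reproduces the *statistical structure* the analysis assumes (directions of
group effects, rank correlations, calibrated nulls, overdispersed counts),
not real tissue. It has no spatial cell architecture, no classifier error
in compartment labels (synthetic cells carry ground-truth labels, where
real pipelines rely on a trained tissue classifier), no optical-density
thresholding, and voxelwise imaging has no partial-volume mixing. Passing
tests therefore validates the estimators and statistics, not biological
claims.

## Cohort statistics

Spearman correlations use midranks for ties and the t approximation for
two-sided p-values. Censored "<5" percent-GP4 entries map to a common value
strictly inside (0, 5) - default 2.5 - so they tie with each other and rank
between exact 0 and exact 5; any value in that interval produces identical
ranks, so the choice is rank-safe. Gleason 3+3 lesions carry %GP4 = 0
exactly.

Mann-Whitney comparisons are two-sided, with exact enumeration for combined
n at or below 12 without ties and the tie-corrected normal approximation
otherwise (either can be forced). The exact mode is verified against an
exhaustive labeling enumeration in the tests.

The %GP4 grouping splits ISUP grade 2-3 lesions at 10% with the boundary
assigned to the low group; that convention, together with the packaged
exclusion flags, reproduces the reference 6/4 split. No multiplicity
correction is applied by default (Benjamini-Hochberg is available as an
option), mirroring the exploratory character of the emulated analysis.

RSEM expression values are transformed as log2(value + 1) by default. The
literal "log2(value - 1)" variant is retained as a documented option
because it appears in some descriptions; it is undefined below 1 and is
almost certainly a typo for the +1 form, so it is never the default.

## Choices made where the design was open

* **Correlation exclusions.** The packaged table flags one lesion as
  excluded from correlation analysis and two (the androgen-deprivation
  patient's lesions) from histology-linked analyses. The correlation flag
  was placed on the lesion whose exclusion reproduces the reference
  correlation values (-0.70 / 0.66 / -0.62 at n = 12); default correlation
  runs keep all 13 lesions for imaging-only pairs and drop the flagged
  lesion for %GP4 pairs, with an all-pairs exclusion run available.
* **Total-carbon vs per-metabolite noise scales** are left incommensurate,
  as defined (see above).
* **The frequency-domain weighting** is equal across frequencies; weighting
  is exposed but not defaulted, because no published weighting scheme is
  identified for the emulated analysis.
* **Known limitation.** The correlation between total-carbon and pyruvate
  SNR computed from the packaged (integer-rounded) table is 0.93-0.95
  depending on the lesion convention; the unrounded maps behind the
  reference value are not available, so an exact reproduction of that one
  coefficient is not achievable from printed data. The acceptance suite
  reports the computed values as-is.

## Reproducing the analyses

`reproduce_paper(seed)` runs every stage (cohort correlations under both
conventions, the group split, a noiseless kPL recovery sweep, the SNR null
calibration, and a full synthetic cohort) and prints pass/fail flags;
`scripts/acceptance.R --seed <int> --out <path>` recomputes the same
quantities from scratch and writes them as JSON. Both are deterministic
given the seed.
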