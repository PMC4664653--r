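---
title: "Methods: targeted GM1 species-ratio quantification from MALDI IMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted GM1 species-ratio quantification from MALDI IMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

This package quantifies the regional expression ratio of two GM1
ganglioside species that differ in their sphingosine long-chain base —
GM1 d18:1 and GM1 d20:1 — from MALDI imaging mass spectrometry data, and
ships a synthetic-data generator that emulates such studies with known
ground truth. The measurand is, per region of interest (ROI),

$$ R = \frac{\mathrm{AUC}_{\,\mathrm{d18:1}}}{\mathrm{AUC}_{\,\mathrm{d20:1}}}, $$

the ratio of the areas under the *highest* (monoisotopic) peak of each
species in the ROI-averaged, locally baseline-corrected spectrum. Ratios
within one spectrum cancel the per-pixel and per-section intensity scale
(matrix deposition, tissue preparation, detector response), which is why
the pipeline never attempts absolute quantification; the package asserts
this as an exact invariance (scaling all intensities by any $c>0$ leaves
every ROI ratio unchanged).

Integrating only the first isotope peak is a deliberate choice: for both
species the monoisotopic peak is the most abundant envelope member (the
package verifies this from the computed envelopes), and its area is
proportional to the species' total signal, so the first-peak ratio equals
the total-signal ratio up to a constant near one.

## Species chemistry

The species are modeled as the stearoyl (18:0 fatty acid) compositions
C73H131N3O31 (d18:1) and C75H135N3O31 (d20:1). These formulas are the
standard compositions consistent with the targeted deprotonated ions near
m/z 1544.87 and 1572.90 — two CH2 groups (28.06 Da) apart — and the 18:0
acyl assumption is a documented convention of this package, not a
measurement.

Ion m/z is computed as the neutral monoisotopic mass minus one proton mass
(1.00728 Da). The electron mass (~0.00055 Da) is ignored; the error is an
order of magnitude below the two-decimal precision at which the anchors
are stated.

Isotope envelopes are aggregated by nucleon number (unit-mass envelopes,
peaks ~1.0034 Da apart, fine structure collapsed to the abundance-weighted
mean mass per nucleon count). Reflectron TOF data at m/z > 1500 cannot
resolve fine structure, so this is the appropriate resolution regime. The
per-element distributions are convolved by binary exponentiation, and the
implementation is tested against exhaustive isotopologue enumeration for
small formulas (agreement to 1e-9).

## The synthetic-data generator

`simulate_study()` emulates the design of a regional ratio study:

* a phantom (`region_map`) defines one hemisphere; the tissue grid is the
  phantom plus its mirror image, and one ROI is produced per region,
  hemisphere and section. Two sections × two hemispheres give the standard
  four measurements per animal per region; four sections give eight, as
  used for corpus callosum and cortical-layer sampling;
* per pixel, intensity is `gain × signal + baseline + noise`, clipped at
  zero, on a shared m/z axis (continuous-mode layout). The signal is the
  sum over both species of abundance-weighted Gaussian peaks at the
  [M−H]⁻ envelope masses;
* `gain` is lognormal per pixel (median 1), `noise` additive Gaussian, and
  `baseline` is constant + linear slope + one broad Gaussian bump — the
  simplest family that exercises constant, linear and gently curved
  baselines under the removal stage.

**Ratio parameterization.** A region's two species abundances are derived
from its target ratio $r$ so that the *expected highest-peak AUC ratio* —
the measurand — equals $r$ exactly, not the total-abundance ratio: with
monoisotopic envelope fractions $f_{18}, f_{20}$ and
$\rho = r f_{20}/f_{18}$, the abundances are
$A_{18} = T\rho/(1+\rho)$ and $A_{20} = T/(1+\rho)$ for region total $T$.

**Between-animal variability.** Real groups of animals show a per-animal
spread of regional ratios (reported group SEMs correspond to
coefficients of variation of roughly 4–15% across regions). The generator
therefore draws one lognormal multiplier (mean 1, CV `animal_cv`, default
0.10 — mid-range of the observed spread) per animal and region and applies
it to the region's true ratio. Without this term a recovered SEM would
shrink toward the numerical floor and "mean within k SEM" checks would be
meaningless.

**Defaults** (all overridable in `sim_config()`):

| parameter | default | rationale |
|---|---|---|
| `mz_range` | 1000–2000 Da | the acquired range of the emulated experiment |
| `mz_bin` | 0.02 Da | ~7 samples per peak sigma |
| `peak_sigma` | 0.15 Da | baseline-resolved isotope peaks, near-Gaussian reflectron TOF shape |
| baseline | 2 + (−0.001/Da) slope + bump (amp 3, sd 60 Da) | exercises the removal stage; keeps baseline+noise above the clip |
| `gain_sdlog` | 0.25 | pixel-to-pixel matrix/detector variability |
| `noise_sd` | 0.5 | modest white noise per pixel; signal-to-noise low but quantifiable at white-matter totals |
| `animal_cv` | 0.10 | biological between-animal ratio spread |
| region `total` | 100 (grey), 30 (white matter) | white-matter GM1 signal is several-fold lower than grey |

No peak-width or noise figures are available for the emulated instrument;
these defaults are chosen for plausibility, not fidelity, and are labeled
as such. The generator does **not** model TOF calibration drift, detector
saturation, matrix crystal heterogeneity beyond the lognormal gain,
spatial correlation of noise, or other ganglioside classes. Passing
recovery tests therefore demonstrates correctness of the analysis chain
under the stated noise model, not robustness to every artifact of real
acquisitions.

**Seeding.** One master seed drives everything: per-animal ratio
multipliers and ROI-drop decisions come from the master stream, and each
animal-section dataset gets a deterministically derived child seed, so a
fixed seed reproduces a study bit-identically and subsets can be
regenerated.

## Quantification chain and numerical choices

1. **ROI mean spectrum** — unweighted per-bin mean over member pixels
   (continuous-mode shared axis). Baseline removal operates on this
   average, not per pixel, matching a workflow in which averaged ROI
   spectra are exported and corrected.
2. **Local baseline removal** — straight line through the
   minimum-intensity points of two 1.0 Da flanking windows placed just
   outside the analysis window (predicted m/z ± 0.9 Da), subtracted and
   clipped at zero. The estimator is deterministic, parameter-light,
   exactly removes constant and linear baselines, and is idempotent. A
   morphological top-hat alternative is available behind
   `baseline.method` for sensitivity analysis. Because the flank
   *minimum* sits below the true baseline by about two noise standard
   deviations of the averaged spectrum, both species' AUCs inherit a
   small positive offset; the ratio consequently carries a small negative
   bias that grows as the denominator AUC shrinks — about −0.5% at
   grey-matter conditions and −2 to −4% at the low-signal white-matter
   settings with 200-pixel ROIs (roughly one recovered SEM at the
   emulated group sizes). This is a property of the prescribed estimator
   under noise, reported here rather than corrected.
3. **Apex search** — the maximum-intensity local maximum within
   predicted m/z ± 0.5 Da (half an isotope spacing, so the monoisotopic
   peak is always selected). Ties break toward the candidate nearest the
   prediction, then toward lower m/z. A detection floor of 3 × MAD of the
   corrected flanks guards against quantifying noise; in the statistics
   context a missing peak invalidates the record (with a logged reason),
   in the imaging context it renders as zero.
4. **AUC** — trapezoidal integral over apex ± 0.4 Da (within one isotope
   spacing, so only the highest peak is integrated). At sigma 0.15 this
   captures 99.2% of the peak and matches the closed-form Gaussian area
   within 1%. Because apexes are grid points and the two species' peak
   centers sit at different phases of the 0.02 Da grid, a symmetric
   noise-free ratio-1 simulation quantifies to 1 within about 3e-5 rather
   than exactly; this bin-quantization floor is far below every tolerance
   used in the analysis. Widening the integration half-width from 0.3 to
   0.45 Da moves ratios by less than 1% (peaks are baseline-resolved).
5. **Averaging** — per-ROI ratios are grouped by animal and region;
   groups with fewer than two valid measurements are dropped (logged).
   Region summaries use the sample (n−1) SD over per-animal means, SEM =
   sd/√n; a single-animal region reports SEM 0 and is flagged by n = 1.
   The animal is the unit of analysis throughout; no mixed-effects
   modeling of section/hemisphere structure is attempted because the
   design averages over them.

## Statistics

Groups are first gated for consistency with a Gaussian distribution at
α = 0.05. The default gate is the D'Agostino–Pearson omnibus test
(skewness + kurtosis), the convention of the interactive graphing
software this workflow emulates; it is implemented from the standard
z-transforms and cross-checked against an independent implementation to
1e-9. Shapiro–Wilk is selectable, and is the automatic fallback for
3 ≤ n < 8 where the omnibus approximations are unreliable; n < 3 or
constant groups fail closed to the nonparametric path with a warning.

Two groups: unpaired two-sided t-test (equal variances) when both pass,
else two-sided Mann–Whitney — exact for combined n ≤ 20 without ties,
normal approximation with continuity and tie correction otherwise. Three
or more groups: one-way ANOVA with Tukey HSD when all pass, else
Kruskal–Wallis. The post hoc after Kruskal–Wallis is not uniquely
determined by convention; this package declares Dunn's test with Holm
adjustment and documents it as an interpretation. All tests are
two-sided with α fixed at 0.05.

## Problem sizes used in the shipped checks

Recovery studies run at 200 pixels per ROI (48 for the small hippocampal
ROIs) on a simulated acquisition window of m/z 1500–1620. The targeted
chain reads no bins outside the two peak clusters and their flanks
(~1535–1582), so restricting the simulated range leaves every recovered
quantity distributionally identical while keeping run time proportional
to bins simulated; the generator's default range remains 1000–2000 for
realistic full datasets. The 100-replicate significance checks
(white-matter contrast by Mann–Whitney; superficial-vs-deep cortical
contrast by Tukey) run at 16 pixels per ROI and two sections per animal:
with ~10% between-animal CV and the emulated effect sizes, group
separation at the printed group sizes is insensitive to the within-ROI
pixel budget.

## Known limitations

* The d18:1/d20:1 species formulas assume a stearoyl fatty acid on both
  ceramides; other acyl chains would shift both anchors equally but are
  not modeled.
* Only the deprotonated ion is supported; no MS2, no deisotoping, no
  untargeted peak picking.
* The baseline estimator's small noise-dependent bias (above) is
  inherent to flank-minimum interpolation; workflows needing unbiased
  low-signal AUCs should increase ROI pixel counts or use the top-hat
  option and compare.
* Ion images are normalized per image and are therefore comparable only
  within an image, never across images.
* Sialic-acid breakdown from polysialylated gangliosides, which can
  inflate GM1 signal in real acquisitions, is outside the simulation's
  scope.
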