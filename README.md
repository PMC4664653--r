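# gm1ims

Targeted quantification of GM1 ganglioside species ratios from MALDI
imaging mass spectrometry (IMS) data, with a fully seeded synthetic-data
generator for validating the analysis end to end.

## The problem

GM1 gangliosides occur in the brain with different sphingosine long-chain
bases; the two dominant species carry 18 (GM1 d18:1) or 20 (GM1 d20:1)
carbons. In negative-ion MALDI IMS of brain sections these appear as
isotope-resolved peak clusters at the deprotonated monoisotopic masses

```
[M - H]-  m/z 1544.87   GM1 d18:1 (stearoyl species, C73H131N3O31)
[M - H]-  m/z 1572.90   GM1 d20:1 (stearoyl species, C75H135N3O31)
```

Absolute IMS intensities are not comparable across pixels or sections
(matrix, tissue and instrument variability), but the *ratio* of the two
species' signals within one spectrum cancels those factors. The measurand
of this package is therefore, per region of interest (ROI):

```
R = AUC(highest GM1 d18:1 peak) / AUC(highest GM1 d20:1 peak)
```

where AUC is the trapezoidal area under the baseline-corrected highest
(monoisotopic) peak of each species in the ROI-averaged spectrum. Per-ROI
ratios are averaged per animal (animal-regions with fewer than two usable
measurements are excluded), and regions are summarized as mean ± SEM over
per-animal means, the animal being the unit of analysis. Two regions are
compared with a normality-gated t-test / Mann–Whitney test; three or more
with one-way ANOVA + Tukey HSD or Kruskal–Wallis + Dunn (Holm), at
α = 0.05.

## What the package provides

- `monoisotopic_mz()`, `isotope_envelope()` — formula arithmetic,
  [M−H]⁻ m/z prediction and unit-mass isotope envelopes (bundled IUPAC
  mass/abundance table).
- `sim_config()`, `build_phantom()`, `simulate_study()` — seeded synthetic
  studies: multi-region phantoms with region-specific true ratios,
  isotope-resolved Gaussian peaks, additive baseline, lognormal per-pixel
  gain, additive noise, and between-animal ratio variability; ground truth
  stored alongside every dataset.
- `read_imzml()`, `write_imzml()`, `read_rois()` — imzML 1.1 (continuous
  and processed) plus a versioned JSON ROI sidecar.
- `remove_local_baseline()`, `find_highest_peak()`, `integrate_auc()`,
  `roi_ratio()`, `quantify_rois()` — the targeted quantification chain.
- `animal_averages()`, `region_summaries()`, `compare_two()`,
  `compare_many()` — averaging, exclusion rule and gated statistics.
- `render_ion_image()`, `composite_image()` — per-species ion images and
  two-channel (green = d18:1, red = d20:1) composites.
- `cmd_simulate()` … `run_pipeline()` and a command-line driver
  (`inst/scripts/gm1ims.R`) orchestrating the whole loop from a YAML
  configuration (see `inst/extdata/example_config.yaml`).

## Worked example

Simulate a corpus-callosum-like study (6 animals, 8 ROIs per animal at low
white-matter signal, generating ratio 5.506) and recover the ratio:

```r
library(gm1ims)

res <- run_recovery_study(
  regions = list(CC = list(total = 30, ratio = 5.506)),
  n_animals = 6, sections_per_animal = 4, px_per_roi = 64, seed = 42)

res$summaries
#>  region     mean      sem n_animals
#>      CC 5.462116 0.142939         6

head(res$ratios[, c("animal_id", "section_id", "hemisphere", "ratio")], 4)
#>   animal_id section_id hemisphere    ratio
#> 1       A01         S1       left 6.070092
#> 2       A01         S1      right 6.006605
#> 3       A01         S2       left 6.120985
#> 4       A01         S2      right 5.922537
```

The per-ROI ratios scatter around the animal's own ratio (animal A01 drew a
high biological multiplier here); the group mean 5.46 ± 0.14 recovers the
generating value 5.506 well within one SEM. The same loop is available from
the shell:

```sh
Rscript inst/scripts/gm1ims.R all \
  --config inst/extdata/example_config.yaml --outdir out --seed 42
```

which writes imzML datasets, ROI/ground-truth JSON, per-ROI ratio and
summary CSV tables, the comparison statistics and composite PNG images.

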