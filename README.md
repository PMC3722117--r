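# btvseg — automated biological target volume delineation from FDG-PET/CT

`btvseg` is an R package for radiotherapy planning research. It delineates
*biological target volumes* (BTV) automatically from SUV-calibrated FDG-PET,
back-projects them onto the planning-CT grid, and quantifies their agreement
with the manually contoured *gross tumour volume* (GTV) at cohort level. It
is written for medical-physics and radiation-oncology groups who want a
reproducible, scriptable version of the classical threshold-segmentation
workflow, validated end to end on synthetic phantoms with known ground
truth.

## What it computes

**Segmentation** (on the native PET grid, region growing from the SUVmax
seed with inclusive thresholds and configurable 6/18/26-connectivity):

- fixed percentage-of-SUVmax thresholds — BTV(p) is the connected component
  of { v : SUV(v) ≥ p · SUVmax } containing the SUVmax voxel, for
  p ∈ {0.38, 0.42, 0.47, 0.50};
- a PERCIST-style background-adaptive threshold
  T = μ_liver + 3 σ_liver, with liver statistics measured in a 15 ml
  spherical VOI in the right hepatic lobe (multiplier configurable; lesions
  with SUVmax < T are flagged PET-negative and return an empty mask).

**Agreement** (on the CT grid after nearest-neighbour back-projection):

- conformity index CI = 100 · |GTV ∩ BTV| / |GTV ∪ BTV| (Jaccard, %);
- both inclusion ratios 100 · |∩|/|BTV| and 100 · |∩|/|GTV|, always
  reported separately.

**Cohort statistics**: per-algorithm and per-site (lung / oesophageal /
pelvic) medians plus the paired two-sided Wilcoxon signed-rank test of BTV
vs GTV volume (exact small-sample p by full enumeration of sign
assignments, ties handled with average ranks; α = 0.05, no multiplicity
correction).

**Synthetic phantoms**: seeded PET/CT pairs with ellipsoidal lesions
(peak SUV ~ log-normal, median 9.2, range 3.1–18.2), Gaussian PSF blur
(FWHM 7 mm), additive noise, a hepatic background compartment, and
simulated manual GTVs with a controllable contour-error model.

Structures are exchanged as NIfTI masks or DICOM RT structure sets.

## Worked example

The `analysis/` scripts run the whole study on a simulated 20-patient
cohort (8 lung, 5 oesophageal, 7 pelvic):

```sh
Rscript analysis/01_simulate_cohort.R   # phantoms -> scratch/
Rscript analysis/02_segment_btv.R       # five BTVs per patient (+ RTSTRUCT export)
Rscript analysis/03_overlap_metrics.R   # overlap metrics -> results/cohort_records.csv
Rscript analysis/04_cohort_table.R      # summary table -> results/table_cohort_summary.*
```

The final step prints (abridged):

```
Volume     | cohort [ml]   p(GTV)   CI [%] |  lung [ml]   p(GTV)   CI [%] | ...
-------------------------------------------------------------------------------
GTV        |       33.4       --       -- |       31.0       --       -- |
SUV38      |       29.4     0.00     71.3 |       27.0     0.20     76.3 |
SUV42      |       26.8   <0.001     67.8 |       24.6     0.04     73.8 |
SUV47      |       25.8   <0.001     64.6 |       23.1     0.02     72.2 |
SUV50      |       25.6   <0.001     63.6 |       22.7     0.02     71.8 |
PERCIST    |       24.0     0.00     71.1 |       24.0     0.08     71.7 |

5 of 5 algorithms differ significantly from the GTV volume
```

Read: the median manual GTV (33.4 ml) exceeds every automatic volume, the
percentage-threshold volumes shrink monotonically from 38 % to 50 % of
SUVmax, and the paired Wilcoxon test flags each deficit as significant.
The conformity indices are higher than on patient data because the
phantoms' only contouring error is the simulated manual-GTV perturbation.

Programmatic use:

```r
library(btvseg)
ph  <- generate_phantom(phantom_spec(seed = 7))
run <- run_btv_pipeline(ph)       # five algorithms + back-projection
run$reports$SUV42
#> overlap GTV vs BTV_SUV42:
#>   volumes 20.1 / 20.2 ml, intersection 20.1 ml, union 20.2 ml
#>   conformity index 99.4%; GTV-in-BTV_SUV42 100.0%, BTV_SUV42-in-GTV 99.4%
```

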