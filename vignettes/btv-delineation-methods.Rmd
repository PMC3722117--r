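---
title: "Methods: automated BTV delineation and GTV agreement analysis"
author: "btvseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated BTV delineation and GTV agreement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btvseg)
```

## The problem

In radiotherapy planning the gross tumour volume (GTV) is contoured manually
on the planning CT, informed by FDG-PET. Threshold-based algorithms promise
an observer-independent alternative: a *biological target volume* (BTV)
delineated automatically from the PET signal. `btvseg` implements the five
classical recipes — fixed thresholds at 38 %, 42 %, 47 % and 50 % of the
lesion SUV~max~, and a PERCIST-style background-adaptive threshold — together
with the machinery needed to compare BTVs against a reference GTV at cohort
level: back-projection onto the CT grid, conformity and inclusion metrics,
and paired nonparametric statistics. Because clinical scans cannot ship with
a package, a seeded synthetic phantom generator provides PET/CT pairs with
known ground truth on which every pipeline stage is validated.

## Segmentation model

All segmentation operates on the native PET grid in SUV units (body-weight
convention, `suv_from_activity()`: SUV = activity [kBq/ml] × weight [kg] /
dose [MBq]; lean-body-mass and BSA variants are deliberately out of scope).
A lesion is specified by a user-supplied *search region* — a generous
bounding box or mask around the tumour, mirroring the interactive VOI
placement of clinical consoles. An unguided whole-image search would latch
onto brain or bladder uptake, so the region is a required input.

For a percentage recipe with fraction $p$, the candidate set is
$\{v : \mathrm{SUV}(v) \ge p \cdot \mathrm{SUV}_{max}\}$ with SUV~max~ taken
over the search region (lesion-wise, not image-wide). The BTV is the
connected component of the candidates containing the SUV~max~ voxel (region
growing from the maximum). Three conventions are fixed and documented
because they silently change voxel counts:

* **Inclusive comparison** (≥), so the seed always qualifies and the mask is
  never empty.
* **26-connectivity** by default (6/18 available via the `connectivity`
  argument); 26 avoids fragmenting thin diagonal structures such as
  oesophageal lesions.
* **Tie-break at SUV~max~**: the lexicographically smallest voxel index wins,
  making the seed — and hence the grown component — deterministic.

The PERCIST-style recipe replaces the relative level with an absolute one:
$T = \mu_{liver} + k\,\sigma_{liver}$, with $\mu,\sigma$ the mean and sample
SD (n−1) of the SUV in a spherical hepatic reference VOI of 15 ml
(radius $(3V/4\pi)^{1/3} \approx 15.3$ mm) and $k = 3$ by default. Published
PERCIST uses $1.5\,\mu + 2\,\sigma$; the $\mu + 3\sigma$ form is the
delineation protocol reproduced here and $k$ is configurable — the package
does not silently "correct" one to the other. A lesion whose SUV~max~ falls
below $T$ is PET-negative for this criterion: the result is an empty mask
carrying the flag `"lesion not above background"`, never an error. The VOI
shape is fixed to a sphere of the prescribed volume, the PERCIST convention,
since only the volume is specified by the protocol.

After segmentation the BTV is *back-projected* onto the planning-CT grid by
nearest-neighbour resampling of voxel centres (`resample_mask()`), which
preserves binarity; all overlap metrics are then computed on the CT grid.
A voxel is represented by its centre throughout (centre-in/centre-out, no
fractional voxels), world coordinates are mm in the LPS convention, and
volume is voxel count × voxel volume. For integer-ratio aligned grids (the
4 mm → 1–2 mm case) back-projection conserves volume to within one PET
voxel; for incommensurate grids the Voronoi sampling error can be larger,
which is why the phantom CT grid is an exact 2× refinement of the PET grid.

## Agreement metrics

For a GTV/BTV pair on a common grid, `compare_pair()` reports

* volumes, intersection and union (ml);
* the **conformity index** $CI = 100\,|A\cap B|/|A\cup B|$ — the Jaccard
  index as a percentage, 0 for both-empty pairs (flagged);
* **both inclusion ratios** $100\,|A\cap B|/|B|$ (BTV-in-GTV) and
  $100\,|A\cap B|/|A|$ (GTV-in-BTV). Reporting a single "inclusion ratio"
  is ambiguous — the two directions differ exactly when volumes differ — so
  both are always computed and named explicitly. Empty denominators yield a
  flagged `NA`, not NaN.

$CI \le \min(\text{inclusions}) \le \text{Dice}$ holds identically and is
enforced by property tests against a brute-force voxel-set oracle.

## Cohort statistics

`summarize_cohort()` reproduces the classical cohort report: per algorithm
and per tumour-site subgroup (lung / oesophageal / pelvic), median volumes,
median conformity indices, median inclusion ratios, and the paired two-sided
Wilcoxon signed-rank test of BTV vs GTV volume at α = 0.05 with **no**
multiple-comparison correction (deliberately, matching common practice in
small planning studies; with five algorithms per subgroup the family-wise
error is correspondingly inflated and readers should interpret borderline
p-values accordingly).

The signed-rank test is implemented in-package because its exact small-sample
path must handle tied absolute differences: zero differences are dropped
(classical reduction, not Pratt), |d| is ranked with average ranks, and for
$n_{eff} \le 25$ the null distribution of $W^+$ is built by dynamic
programming over the doubled ranks — arithmetically identical to enumerating
all $2^n$ sign assignments — giving $p = \min(1, 2\,P(W^+ \le W))$ with
$W = \min(W^+, W^-)$. Beyond 25 a normal approximation with tie-corrected
variance ($\sigma^2 = \sum r_i^2/4$) and 0.5 continuity correction takes
over; at the switch point the two differ by well under 0.02. Tests verify
exact agreement with literal $2^n$ enumeration for $n \le 12$, agreement
with `stats::wilcox.test(exact = TRUE)` on tie-free data, shift invariance,
swap antisymmetry, and a type-I error within [0.03, 0.07] over 2000
simulated null cohorts of n = 20. All-zero difference vectors are flagged
degenerate with p = 1.

## The synthetic phantom

`generate_phantom()` emulates the statistical structure of a planning
PET/CT study, not its physics. Defaults (chosen once, as study conditions):

| parameter | default | why |
|---|---|---|
| PET grid | 48³ @ 4 mm | typical whole-body PET voxel |
| CT grid | 96³ @ 2 mm | planning CT; exact 2× refinement of PET |
| background SUV | 1.0 | soft tissue |
| liver compartment | sphere r = 25 mm, μ = 2.0, σ = 0.3 | normal hepatic uptake; hosts the 15 ml VOI |
| lesion peak SUV | log-normal, median 9.2, clamped 3.1–18.2 | observed SUV~max~ range of such cohorts |
| PSF FWHM | 7 mm | clinical PET resolution; drives partial-volume effects |
| noise SD | 0.2 SUV | moderate reconstruction noise |
| GTV error | +U(1,4) mm offset, 2 mm warp | manual contours tend to be generous |

The generative order is: paint lesions (uniform peak SUV) and liver mean
over background → separable Gaussian blur of the stated FWHM → additive
Gaussian noise → clip at 0. The hepatic compartment is then assigned its
seeded Gaussian field directly, i.e. the model specifies the *measured*
liver statistics rather than pre-blur ones; with σ = 0 the compartment is
exactly constant and the PERCIST threshold equals μ exactly. The
ground-truth mask is the pre-blur lesion support on the PET grid.

The simulated manual GTV applies a signed offset (mm) plus a smooth
low-frequency random field (coarse Gaussian knots, trilinearly upsampled) to
the truth contour, using the voxel-centre distance to the boundary corrected
by half a voxel so sub-voxel offsets act on the right mm scale; the result
is back-projected to the CT grid. With zero error the GTV equals the
back-projected truth exactly, which is what makes the noiseless
recovery test exact across grids. Cohorts (`generate_cohort()`) allocate
sites by largest remainder (n = 20 at 0.40/0.25/0.35 gives exactly 8/5/7)
with per-site shape presets: lung = medium spheres, oesophageal = small
elongated ellipsoids, pelvic = large irregular ellipsoids. A single seed
fixes everything end-to-end; identical seeds give bit-identical cohorts.

What the phantom does **not** model: Poisson counting statistics and
reconstruction artefacts (noise is additive Gaussian on the blurred field),
respiratory motion, heterogeneous tracer uptake inside the lesion,
non-spherical liver anatomy, adjacent high-uptake organs, and
post-chemotherapy tissue changes. Passing tests therefore demonstrate the
correctness of the algorithms and the internal consistency of the pipeline
— not clinical segmentation accuracy on patient data, where manual-GTV
variability and these unmodelled effects dominate.

## Numerical and design choices

* **Resampling** is nearest-neighbour only for masks (binarity); half-up
  rounding (`floor(x + 0.5)`) avoids the instability of banker's rounding
  on exact half-integer continuous indices.
* **Blur** uses replicate-edge padding so border voxels keep unit kernel
  mass; with FWHM 0 the field is untouched.
* **Contours** follow voxel edges (the 0.5 iso-surface of the binary field
  under nearest-neighbour interpolation): a single voxel exports its square
  outline, outer loops are CCW in index space, holes are separate polygons
  under the even-odd rule (no keyhole convention). Under these conventions
  mask → contours → mask round trips are exact, and contour-derived volume
  equals voxel-counting volume. At corners where two voxels touch
  diagonally the tracer takes the left turn, keeping every polygon simple.
* **RTSTRUCT dialect**: one ROI per structure, CLOSED_PLANAR, implicit-VR
  little-endian dataset, vertices written to 10^-4^ mm. Interoperability is
  asserted against the package's own reader; the NIfTI path (`RNifti`)
  carries geometry in sform/qform with the LPS↔RAS sign flip handled
  internally.
* **Degenerate inputs** fail loudly and specifically: empty search regions,
  hepatic VOIs covering < 2 voxels, mismatched geometries (with the
  instruction to resample first), lesions outside the grid or overlapping
  the liver. The one deliberate non-error is the PET-negative lesion under
  PERCIST, which is a valid clinical finding.

## Problem sizes

The validation suite runs entirely on generated data: the exactness and
end-to-end checks use the default 48³/96³ grids, the repeated-phantom
properties (threshold nestedness over 50 seeded phantoms) use a compact
32³ PET grid, overlap-metric oracles use 6³ grids with 100 random pairs,
and the Wilcoxon calibration uses 2000 null cohorts of n = 20. These sizes
were chosen so the whole suite exercises every code path at full fidelity
in a couple of minutes on a single core.

## A worked example

```{r example, eval = FALSE}
spec <- phantom_spec(seed = 7)
ph <- generate_phantom(spec)
run <- run_btv_pipeline(ph)
run$reports$SUV42
#> overlap GTV vs BTV_SUV42:
#>   volumes 20.1 / 20.2 ml, intersection 20.1 ml, union 20.2 ml
#>   conformity index 99.4%; GTV-in-BTV_SUV42 100.0%, BTV_SUV42-in-GTV 99.4%
```

(The default GTV error here is zero offset; the cohort generator adds the
manual-contour error, which is what pushes conformity indices down into the
clinically reported range.)

## Known limitations

Rigid/deformable registration, attenuation correction and scanner
calibration are out of scope — PET and CT are assumed co-registered, as on
a combined scanner. Gradient-based, watershed or iteratively
background-corrected segmentation methods are not implemented. Automatic
liver localisation is not attempted; the hepatic VOI centre is supplied by
the user or the phantom. Surface-distance metrics (Hausdorff, mean surface
distance) are intentionally absent from the agreement report.
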