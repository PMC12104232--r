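---
title: "From contour variability to dosimetry and prognosis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From contour variability to dosimetry and prognosis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contourvar)
```

## The problem

When several radiation oncologists delineate the same target volume and
organs at risk (OARs) on the same planning CT, their contours differ —
inter-observer variability (IOV). Because an IMRT optimiser conforms the
dose tightly to whatever target it is given, a plan built on one observer's
target can under-dose the anatomy another observer (or a consensus gold
standard) would consider tumour. `contourvar` quantifies this chain in
three linked layers:

1. **Geometry** — how different are the contours? Signed volume difference
   ΔV = V~M~ − V~S~ (observer minus standard), max-to-min volume ratio
   MMR, coefficient of variation CV of observer volumes, Dice similarity
   coefficient DSC, and the 95th-percentile Hausdorff distance HD95.
2. **Dosimetry** — what does each observer's plan deliver to the
   *gold-standard* structures? Prescription dose coverage
   PDC = 100 · |PTV voxels with dose ≥ prescription| / |PTV voxels| for
   targets; Dmax / Dmean / D1cc summaries for serial / parallel OARs; the
   relative difference ΔD~diff~ = 100 · (D~M~ − D~S~) / D~S~ against the
   standard plan.
3. **Prognosis** — radiobiological endpoints. The target dose distribution
   is reduced to an equivalent uniform dose
   EUD = (Σ~i~ v~i~ d~i~^a^)^1/a^ with a cold-spot-sensitive exponent
   (a = −8 by default), fed into a logistic tumour control probability
   TCP = 1 / (1 + (TCD~50~/EUD)^4γ50^); OAR summary doses feed a modified
   linear-quadratic NTCP = exp[−N~0~ V^−k^ exp(−α D Γ)].

The statistical layer then asks which *geometric* metric predicts the
*dosimetric/prognostic* loss: Spearman rank correlations of each geometric
metric against ΔPDC and ΔTCP over all (patient, observer) pairs, with a
metric designated a delineation-risk predictor when p < 0.05 **and**
|r| > 0.4.

## Coordinate conventions

All masks and dose grids live on a `voxel_grid`: a regular lattice with
anisotropic spacing, voxel-centre sampling, 0-based indices, and
physical position = origin + index × spacing. Masks are binary occupancy
arrays and are never interpolated (a trilinearly interpolated binary mask
would create ambiguous partial volumes); dose is interpolated trilinearly
when its grid differs from the mask grid, and the structure voxelization
always defines the integration domain. Margin expansion (GTV → PTV,
OAR → PRV) uses an exact Euclidean distance transform that respects
anisotropic spacing — CT slice spacing is rarely equal to in-plane
spacing, so structuring-element dilation would be wrong in mm terms.

## Geometric metrics: the choices that matter

* **CV** uses the sample standard deviation (n − 1). With a handful of
  observers this is the defensible small-sample convention.
* **HD95** is reported as the symmetric maximum of the two directed
  95th-percentile distances; both directed values are exposed
  (`hd95_directed()`) so either convention can be recovered. Distances are
  measured between boundary-voxel centres (boundary = occupied voxel with
  an unoccupied 6-neighbour, or touching the volume edge) via the exact
  distance transform of the opposing boundary; the percentile uses linear
  interpolation between order statistics (R quantile type 7), which makes
  tie-breaking deterministic. The test suite checks exact agreement with a
  brute-force all-pairs oracle on hundreds of random anisotropic masks.
* **MMR/CV** are computed over observer volumes only, excluding the gold
  standard, which is reported as its own column.

## STAPLE consensus

The consensus gold standard for a validation cohort is built with STAPLE:
an EM algorithm on the binary performance model, estimating per-observer
sensitivity p and specificity q together with the hidden true
segmentation. The E-step computes the per-voxel posterior of the true
label under a global foreground prior (default: the mean observer
foreground fraction, recorded in the run manifest); the M-step
re-estimates (p, q), clamped to [10^−6^, 1 − 10^−6^] so degenerate
observers (e.g. an all-empty mask, whose sensitivity is unidentifiable)
produce a warning rather than NaNs. The consensus is the posterior ≥ 0.5
set.

`shared = TRUE` selects the constrained "equally reliable observers"
model: one fixed symmetric performance level for everyone and no
estimation. Under that model the posterior is a monotone function of the
per-voxel vote count, so with a uniform prior the consensus is *exactly*
the majority vote — the suite verifies this on an exhaustive family of
2×2×2 label patterns, degenerate all-empty/all-full patterns included.
The unconstrained EM can legitimately deviate from majority voting (that
is its point: it down-weights unreliable observers), which is why the
reduction is stated for the constrained model only.

## Dose metrics

* **D1cc** (minimum dose to the hottest 1 cm³) is computed from the
  exactly sorted voxel doses with linear interpolation at the 1 cc
  boundary, not from a binned DVH, removing bin-width sensitivity from a
  serial-organ metric. Structures smaller than 1 cc report D1cc = Dmin
  with a warning. The binned cumulative DVH (default bin 0.01 Gy) is
  retained alongside the exact voxel doses; the suite checks the two
  agree within one bin width.
* **PDC** reads "receives 100% of the prescription" literally as
  dose ≥ prescription on whole voxels — no tolerance band, no
  partial-volume weighting — so results are bit-stable and consistent
  with the DVH: PDC at the prescription equals the cumulative DVH
  fraction there, which is asserted as an invariant.

## Radiobiological models

Target TCP uses the logistic form with the published nasopharynx
parameters as defaults: TCD~50~ = 61.69 Gy, γ~50~ = 3.38, EUD exponent
a = −8, 33 fractions. The exponent is implemented exactly as 4γ~50~; no
re-parametrisation. TCP(EUD = TCD~50~) = 0.5 holds to machine precision
independent of the slope — that identity is the package's machine-checkable
anchor. EUD is evaluated on exact voxel doses (not the binned DVH); doses
below 0.01 Gy are clamped to 0.01 Gy when a < 0, since d^a^ diverges at
zero — the clamp is configurable and logged in the function's
documentation contract.

The NTCP fractionation factor is printed ambiguously in compact notations
of this model family; the package uses the standard per-fraction
linear-quadratic correction Γ = 1 + d~f~/(α/β) with d~f~ = D/n~fractions~
as the default, and offers `gamma_mode = "total_dose"` (Γ = 1 + D/(α/β))
as a switch. V is the relative irradiated volume; the default
"uniform-summary" convention uses V = 1 with D the organ-class summary
dose (serial → Dmax or D1cc, parallel → Dmean or D1cc). N~0~ = 0 would
force NTCP = 1 at any dose and is rejected by validation. The per-organ
NTCP parameters shipped in `radiobio_params()` are a **synthetic
placeholder set** with plausible serial/parallel behaviour — published
organ-specific fits should replace them for any real analysis.

## Statistics

The paired observer-vs-standard comparisons choose between the paired
t-test and the Wilcoxon signed-rank test by a Shapiro–Wilk test on the
paired differences at α = 0.05; the chosen test is reported per row so
either convention can be audited, and all-zero differences are flagged
with p = 1 by convention. Spearman correlations use average ranks for
ties, an exact permutation p for n ≤ 10 and the t-approximation above.
Correlations pool all (patient, observer) pairs into one vector per
metric — the only pooling consistent with cohort × observer scatter
plots — with a stratified per-observer mode available. No multiple-testing
correction is applied to the predictor screen (the |r| > 0.4 gate plus raw
p < 0.05 is the designed rule); the suite verifies by simulation that the
two-gate rule fires in well under 5% of independent nulls at n = 48.

## The synthetic cohort

Real multi-observer clinical data cannot ship with the package, so the
generator produces the *statistical structure* the analysis assumes:

* **Anatomy** (`make_phantom`): an ellipsoidal primary target (~30 cc), a
  tubular serial organ (spinal cord), paired parallel organs (parotids,
  ~20 cc) and paired small serial organs (optic nerves, ~0.2 cc — the
  scale at which observer variability is known to be largest). Default
  grid 128 × 128 × 96 at 1 × 1 × 2.5 mm, matching CT-like in-plane
  resolution and a 2.5 mm dose-grid slice scale. Organ centres are
  jittered ±2 mm per seed so patients differ; the target never overlaps
  the cord.
* **Observers** (`simulate_observer`): each structure is perturbed in the
  signed-distance domain — a rigid shift (per-axis SD `shift_mm`), a
  systematic surface offset `volume_bias_mm` (negative = under-contouring)
  and a spatially smooth Gaussian random field (correlation length
  ~10 mm, SD `surface_noise_mm`) — then re-thresholded. Smooth
  displacement fields produce anatomically plausible contours; per-voxel
  label flips would not. Two numerical details: a half-voxel surface
  correction aligns the discrete signed distance with the continuous
  boundary (so an erosion of exactly one voxel spacing actually removes a
  voxel layer), and eroding offsets saturate at half the structure's
  interior depth — an observer under-contours a thin organ but does not
  delete it. Defaults (noise 1.5 mm, shift 0.5 mm) were chosen to produce
  Dice/HD95/CV spreads on the scale reported for human observers in
  nasopharyngeal delineation studies; they are fixed study conditions,
  not tuning knobs.
* **Dose** (`synthesize_dose`): an analytic conformal surrogate — full
  prescription inside the planned target, Gaussian falloff
  rx · exp(−d²/2σ²) outside (σ = 3 mm default), plus optional background.
  This is deliberately *not* a planned IMRT dose; it provides the one
  property the analysis needs with a single interpretable parameter: dose
  conformal to the **planned** target with a finite gradient, so
  under-contouring produces cold spots on the gold-standard target while
  over-contouring preserves its coverage.

What passing tests on this cohort do and do not show: they demonstrate
that the pipeline recovers a designed direction of effect — ΔV of the
target correlates positively with ΔTCP and is selected by the predictor
rule, under-contourers lose coverage, over-contourers do not — with
effect sizes much larger than clinical ones (the surrogate dose gradient
is steeper and the observer biases more systematic than reality). They do
not validate the clinical magnitudes of any correlation, nor the realism
of IMRT dose distributions, image registration, or human contouring
behaviour.

## Reproducibility and problem sizes

All randomness flows from a single master seed through documented
per-patient/per-observer stream derivations (`derive_seed`), so cohorts
regenerate bit-identically; the manifest records every derived seed.
`run_study()` streams patients — generate, analyse, discard — so cohort
size is bounded by time, not memory, and is verified to reproduce
`run_pipeline(generate_cohort(...))` exactly. The shipped test suite runs
the full 12-patient × 4-observer cohort on the default grid; unit tests
use a coarse 64 × 64 × 48 grid at 2 × 2 × 5 mm that preserves all the
phantom's physical dimensions.

## Known limitations

* The dose surrogate has no beam structure, no scatter tails, no plan
  optimiser trade-offs; OAR dose differences between observers arise only
  through target geometry, so OAR-side ΔD~diff~/ΔNTCP spreads are milder
  than clinical tables suggest.
* Voxel quantization means a sub-voxel erosion can leave a small organ's
  mask unchanged (ΔV = 0); invariants are therefore stated as ≤ for small
  organs and strict for large ones.
* The HD95 directed-vs-symmetric convention and the DVH bin width are
  configurable because the field has no single standard; defaults are
  stated above and in the function documentation.
* DICOM-RT polygon import is out of scope; masks enter as volumetric
  images (NIfTI).
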