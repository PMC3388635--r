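---
title: "Quantitative lung aeration CT and reference-slice extrapolation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative lung aeration CT and reference-slice extrapolation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungqct)
```

# The measurement model

A CT voxel's attenuation in Hounsfield units is, to good approximation, a
linear function of its physical density: −1000 HU is gas, 0 HU is water.
Lung parenchyma is a gas/tissue mixture, so a voxel at attenuation $h$
inside the analyzable window $[-1000, +100]$ HU is decomposed as

$$\rho(h) = \frac{h + 1000}{1000}\ \mathrm{g/ml}, \qquad
  f_{gas}(h) = \max\!\left(0, -\frac{h}{1000}\right),$$

where $\rho$ is tissue density and $f_{gas}$ the gas volume fraction.
Summing voxel volume, volume$\times\rho$ and volume$\times f_{gas}$ over
all mask voxels yields total lung volume $V_{total}$ (ml), mass
$M_{total}$ (g) and gas volume $V_{gas}$ (ml). Voxels are further
classified into four aeration compartments by closed integer HU ranges
that exactly tile the window: nonaerated $[-100, +100]$, poorly aerated
$[-500, -101]$, normally aerated $[-900, -501]$ and hyperaerated
$[-1000, -901]$. Compartment volumes and masses are reported as
percentages of the totals, computed from the *summed absolute*
quantities, never by averaging per-slice percentages.

Assumptions worth making explicit:

* **Masks are inputs.** Segmentation (with major vessels, trachea and
  main bronchi excluded) happens upstream; the package never segments.
* **Density above water.** Voxels in $(0, +100]$ HU get
  $\rho(h) = (h+1000)/1000 > 1$ g/ml by the same linear model. The
  alternative convention (clamping density at 1.0) is defensible; the
  choice is isolated in `tissueDensity()` and matters only for lungs with
  appreciable supra-water attenuation.
* **Out-of-window voxels are excluded, not clipped.** A mask voxel whose
  rounded attenuation falls outside $[-1000, +100]$ contributes to no
  quantity; it is counted per slice in `nExcluded` so heavy exclusion is
  visible.
* **Integer classification.** Attenuation is rounded to the nearest
  integer before compartment lookup — the printed ranges are only
  disjoint on integers. Ties round away from zero, so $-100.5$ HU is
  poorly aerated and $-100.4$ HU nonaerated. The density and gas models
  use the unrounded value.

# The extrapolation estimator

Whole-lung analysis needs every slice; the extrapolation method needs
$N$ *reference slices*: the most cranial and most caudal lung-bearing
slices, plus $N-2$ equidistant interior slices,
$\mathrm{index}_k = \mathrm{first} + \mathrm{round}(k\,(\mathrm{last}-\mathrm{first})/(N-1))$.
Rounding is to the nearest index with ties toward the caudal end — any
fixed tie direction works; a fixed one keeps selections deterministic and
gap sizes within one slice of each other. For each absolute per-slice
quantity $Q$ (volume, mass, gas volume, every compartment's volume and
mass) the whole-lung estimate is

$$\hat Q = \sum_{i=1}^{N-1} \frac{Q_i + Q_{i+1}}{2}
  \cdot \frac{z_{i+1} - z_i}{t} \;+\; \frac{Q_1 + Q_N}{2},$$

with slice centers $z_i = \mathrm{index}_i \cdot t$ for contiguous
acquisitions of nominal thickness $t$, so the interval weight reduces to
the integer index gap and $t$ cancels. Percentages are then derived from
the extrapolated absolutes exactly as in whole-lung analysis.

**Why the end-cap correction $(Q_1 + Q_N)/2$.** The trapezoid sum covers
the span between the first and last reference slice *centers*; the outer
half of each end slice is not covered. Adding half of each end slice's
quantity is the unique constant correction that makes the estimator

1. exact when every slice is selected ($\hat Q$ telescopes to
   $\sum_i Q_i$),
2. exact for uniform profiles at any $N$, and
3. exact for profiles affine in slice index for any endpoint-containing
   selection (trapezoids integrate affine functions exactly).

All three properties fail without it, and all three are enforced in the
test suite. Two further structural properties follow: the estimator is
invariant to the nominal thickness (it cancels), and interior slices with
zero lung volume are legal reference slices — the extent simply spans the
first to last lung-bearing slice.

# Agreement analysis

Method comparison follows Bland and Altman: for $n$ scans measured by
both methods, bias $= \overline{d}$ and 95% limits of agreement
$\overline{d} \pm 1.96\,s_d$, where $d$ = whole-lung − extrapolated and
$s_d$ is the sample standard deviation ($n-1$). The classic 1.96
multiplier is used without a small-sample $t$ correction. Positive bias
therefore means extrapolation underestimates. Relative deviations are
reported as median (min to max) of $100\,|d|/\mathrm{reference}$ —
absolute values, since reported ranges start at 0. For consecutive-CT
comparisons, the per-scan *change* between two time points is computed
for each method and the deltas are compared the same way; at least 3
pairs are required (limits of agreement are meaningless below that).

# The phantom generator

The phantoms stand in for whole-lung CT scans of mechanically ventilated
sheep and pigs. Each is a pair of ellipsoidal lung fields inside a
water-equivalent (0 HU) thorax on a grid with 0.7 mm default in-plane
spacing (an artifact choice; animal in-plane spacing is not prescribed)
and nominal slice thickness 5, 6, 7.5 or 10 mm. The cranio-caudal extent
spans $\lceil H/t \rceil$ lung-bearing slices flanked by two empty slices
per side; per-slice cross sections are evaluated at the midpoint of the
slab's overlap with the lung span, so a partial caudal slab still shows
lung. Aerated voxels draw HU from
$\mathcal{N}(\mathrm{base}, \sigma^2)$ plus a ventro-dorsal gradient;
dependent atelectasis is modeled by reassigning the most dorsal (and,
for opacified presets, caudally weighted) fraction of lung voxels to
$\mathcal{N}(0, 20^2)$ HU clipped to $[-100, +100]$.

Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| base aeration | −700 HU | centers the bulk of voxels in the normally aerated band (~94% in normal presets), with gas fraction near 70% as in healthy ventilated animals |
| noise SD | 50 HU | spreads attenuation over a few hundred HU without leaking aerated voxels into the nonaerated band |
| ventro-dorsal gradient | +1 HU/mm | denser dorsally, the dependent-density pattern of supine ventilated lungs |
| atelectasis HU | $\mathcal{N}(0, 20^2)$, clipped $[-100, 100]$ | collapsed lung is near water density |
| preset ranges | per species/condition | total volume, nonaerated share and lung height are sampled within published whole-lung ranges for normal/opacified sheep and pigs (e.g. ovine normal $V_{total}$ 2245–5638 ml, height 222–320 mm, nonaerated ≤ 0.8%) |

Cohort draws use the central 90% of each preset range: voxelization
changes a realized volume by up to a few percent, and the margin keeps
every realized phantom inside its nominal range. Each phantom's seed is
derived from the cohort master seed by counter, so cohorts are
reproducible end to end and any member can be regenerated alone; the
generator restores the caller's RNG state. Recruitment pairs share all
geometry parameters and the seed; the post scan re-aerates a stated
fraction of the atelectatic volume and inflates the volume target by a
stated factor, giving known ground-truth deltas.

The elliptical axial profile is deliberately *non-affine*: its per-slice
area varies quadratically, so extrapolation error is nonzero and shrinks
as reference slices are added — without this, the slice-count sweep would
be vacuous. The ground-truth summary is computed constructively during
generation (one flat pass over the assigned voxel values, no slice
bucketing), which makes it an independent oracle for the analysis
pipeline.

**What the phantoms do not emulate** — and hence what passing tests do
not show about real data: airway/vascular anatomy (and imperfect manual
exclusion of it), scanner physics (quantum noise, beam hardening,
reconstruction-filter correlations), patchy or non-dependent opacification
patterns, and irregular lung outlines. Phantom axial profiles are smooth,
so absolute agreement measured here (limits of agreement of roughly
±15 ml on a ~2800 ml lung at 10 slices) is tighter than reported on real
animal scans (roughly ±70 ml); the *structure* of the results — near-zero
bias at 10 slices, limits widening sharply below 10, insensitivity to
slice thickness, faithful consecutive-CT deltas — is the validated claim.

# Numerical and design choices

* **Indexing.** Slices are 1-based everywhere, matching both R and
  radiological slice numbering; slice 1 is the most cranial.
* **NIfTI only.** No installed DICOM reader fits this package's
  dependency footprint, and the conversion (dcm2niix) is standard
  practice; `readVolume()` fails with a pointer when handed a DICOM
  directory. NIfTI intensities are taken as already in HU. Uniform axial
  spacing is a file-format guarantee here (one `pixdim` per volume); the
  extrapolation arithmetic presumes it.
* **Volumes are written as float64**, so write/read round-trips are
  exact; masks as uint8 with any nonzero label counting as lung.
* **Degenerate inputs.** Empty masks, all-zero profiles and
  zero-tissue-mass lungs are hard errors (`"empty lung"`); a slice with no
  lung is an all-zero row, not an error. Selections need $N \ge 2$ and at
  most the available slice count.
* **Validation study sizes.** The shipped validation study uses a
  30-phantom opacified-sheep cohort for single-scan agreement and 58
  recruitment pairs for delta agreement, the cohort sizes that make the
  reported tables comparable to a typical large-animal qCT study; the
  whole study runs in about a minute at default resolution. Phantoms are
  generated, analyzed and discarded one at a time, so memory stays flat
  in cohort size.

# Known limitations

* Whole-lung metrics only; no ventro-dorsal or lobar regionalization.
* No proportional-bias (regression) extension of Bland–Altman, and no
  confidence intervals on the limits of agreement.
* Single nominal slice thickness per scan; variable-thickness
  acquisitions are rejected by design.
* The linear density model above 0 HU and the end-cap correction are
  reconstructions of standard qCT conventions; both are isolated in
  single functions (`tissueDensity()`, `extrapolate()`) should a user
  need a different convention.
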