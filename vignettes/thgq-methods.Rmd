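---
title: "Quantifying brain-tissue cellularity in THG microscopy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying brain-tissue cellularity in THG microscopy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Third harmonic generation (THG) microscopy images fresh, unstained brain
tissue at subcellular resolution: lipid-rich neuropil (axons, dendritic
processes) appears as bright, fibrous signal, cell bodies appear as dark
holes in that background, nuclei occasionally as bright blobs inside the
holes, and lipofuscin granules as small bright specks. Because diffuse
gliomas infiltrate by raising the local cell density, quantifying how much
of an image is occupied by cells and nuclei converts THG contrast into a
tumor-margin readout usable during surgery.

`thgq` implements that quantification as a fixed pipeline:

1. **enhance** — histogram truncation + local histogram equalization;
2. **denoise** — salience-weighted anisotropic diffusion;
3. **segment_three_phase** — dark holes / bright objects / background;
4. **rescue_nuclei_hough** — gradient-directed circular Hough transform on
   the background phase, recovering faint round nuclei;
5. **object analysis** — hole filling, watershed splitting, size filters,
   sphericity sorting, cytoplasm–nucleus assembly;
6. **quantify + classify** — percentage-of-space (PoS) features and the
   two-threshold normal/tumor rule.

The pipeline order is fixed; each stage consumes the output of the
previous one.

## Density features and the classifier

The density of a feature class is its *percentage of space*: the number of
pixels in the union of its object masks divided by the image area. PoS
deliberately conflates object count and size — in hypercellular tumor
cores, clumped cells cannot be separated reliably, but the space they
occupy can still be measured. Neuropil density is the summed perimeter of
all neuropil objects divided by 100: the neuropil is a thin web whose
boundary length, not area, tracks fiber abundance.

An image (or tile) is called **tumor** when cell PoS > 0.17 **or** nucleus
PoS > 0.03, both strictly; otherwise **normal**. The first clause captures
the elevated cell density of low-grade infiltration, the second the dense
atypical nuclei of high-grade disease. The thresholds are fixed package
defaults (they were established on clinical mosaics; this package treats
them as given constants) and are config-exposed, with
`tune_thresholds()` provided for recalibration on labeled data via
Youden's J. Images with a field of view of at least 500 µm are split into
four equal parts; each part is classified on its own and the tile-level
features are the arithmetic means of the four parts.

## Stage design and parameters

**Enhancement.** Intensities are truncated at the 0.5th/99.5th percentiles
(hot pixels, dark outliers) and rescaled, then equalized. With
`tile_grid = c(1, 1)` the package uses exact rank-based global
equalization, which is idempotent; the default is contrast-limited
adaptive equalization (CLAHE) on an 8×8 tile grid with clip limit 2
(in multiples of the uniform bin height, the convention of the underlying
implementation). CLAHE's tile-interpolated mappings are not a projection,
so only bounded stability — not exact idempotency — can hold for the local
path; the global path is tested for exact idempotency instead.

**Denoising.** Perona–Malik-type diffusion with conductance
`g(d) = 1/(1 + (d/k)^2)`, `k = 0.1` intensity units, 15 iterations at time
step 0.2 (the explicit scheme is stable up to 0.25). The conductance is
additionally multiplied by `1 − w·S`, `w = 0.5`, where `S` is the
normalized structure-tensor coherence: smoothing is suppressed on coherent
(salient) edges, which keeps fiber and cell boundaries sharp while flat
regions are averaged. Fluxes are evaluated per 4-neighbor edge with a
symmetric conductance and reflected borders, so the scheme conserves the
image mean exactly and obeys a maximum principle (the output range never
leaves the input range).

**Three-phase segmentation.** The image is partitioned into three
piecewise-constant phases by minimizing
`sum (I - c_phase)^2 + mu * boundary length` with `mu = 0.15`, using
deterministic iterated-conditional-modes sweeps in a red–black
(checkerboard) order, which makes the Potts energy non-increasing and the
result reproducible. The dark and bright phase means are softly anchored
(weight 0.5) to the image's 2nd and 98th intensity percentiles — the
"prior extremes" — which stabilizes the two minority phases against the
dominant mid-intensity background. Convergence is declared when fewer than
1 in 10^4 pixels change label in a sweep (cap 500 sweeps; typical images
converge in well under 10). Phase identity is assigned *after*
convergence by ordering the three means, so any internal relabeling is
immaterial. Images with fewer than three distinct gray levels return an
all-background map with a warning. Ties in the per-pixel assignment break
by intensity proximity to the phase mean, then by lowest label.

**Hough nucleus rescue.** Nuclei whose contrast is too weak for the bright
phase survive only as faint round rims in the background. On
background-phase pixels with gradient magnitude above 0.03, votes are cast
along each pixel's gradient direction (both orientations) at radii
4–25 px. Votes are pooled over a 3×3 spatial window and adjacent radii
(the point-spread function and rounding scatter a rim's votes by about a
pixel), normalized by the circumference, and peaks above 1.0 become
candidates (a complete 2-px rim scores around 5). Each candidate is then
verified: its center is refined by an iterated least-squares (Kåsa) circle
fit on the radially aligned supporting edge pixels, the supporting pixels
must cover at least 8 of 12 angular sectors, the interior must be brighter
than the surrounding annulus by at least 0.05 (nuclei are bright blobs;
rims of dark inter-fiber gaps fail this polarity check), and detections
overlapping the bright phase by more than 30% are discarded (detections
overlapping existing bright objects by more than half are always
discarded). Moderately elliptical rims are accepted by fitting minor/major
radii within ±20% of the peak radius. These verification stages are what
makes directional voting usable on fibrous backgrounds, where stray edges
otherwise accumulate circle-like coincidences.

**Object analysis.** Dark-phase components are hole-filled (a bright
nucleus inside a dark cytoplasm leaves a hole), split at necks by a
distance-transform watershed with 2-px seed suppression, and kept only at
area ≥ 1000 px (≈ 6 µm × 6 µm at 0.3 µm/px — smaller dark specks are not
cell bodies). Bright components below 500 px are rejected (granules,
specks); of the rest, components with sphericity `4πA/P² < 0.1` are
neuropil; the remainder are split and children with sphericity > 0.5 and
area < 10000 px become nuclei. All gates are strict, exactly as stated.
Hough detections join the nucleus pool through the same 10000 px ceiling;
they bypass the 500 px floor by default (they are by construction faint
nuclei the bright phase missed — config flag `hough_bypass_size_floor`).
The 10000 px ceiling is applied after splitting. Perimeter is measured as
the length of the 8-connected outer boundary chain (straight steps 1,
diagonal steps √2, floor 4 for degenerate objects); under this convention
a digital disc scores ≈ 0.9, a square π/4 and a 3-px fiber ≪ 0.1, so the
0.1/0.5 gates behave as intended. Nuclei merge into a cell body when their
centroid lies inside or within 2 px of the body mask; each nucleus merges
at most once (nearest body, ties to the lower id), and unmatched nuclei
stand alone as nucleus-only cells — they still occupy cell space. Cell PoS
is computed over the union of the assembled cell masks (cytoplasm ∪
nucleus); nucleus PoS over nucleus masks only.

**Fluorescence validation.** Hoechst (HOE) images are quantified with the
same bright-object path (the stained nuclei are the bright phase), and
`correlate_densities()` computes the Pearson correlation between THG cell
PoS and HOE nucleus PoS across paired regions, with a leave-one-out table
for exclusion analyses: a region with uneven dye uptake depresses the
correlation, and excluding it should restore it. Paired regions can be any
co-registered fields; the validation experiments in this package use
independently seeded phantom fields of varying density as regions.

**Stitching.** Mosaics are assembled at the fixed 20% overlap of the
acquisition protocol: tiles are placed at `(1 − overlap) · tile` spacing
and blended with linear feather ramps whose paired weights sum to one, so
tiles cut from a common field restitch exactly. An optional ±n px
cross-correlation refinement (`refine_px`) is available for stages with
positioning error; it is off by default because fixed offsets are exact
and deterministic for phantom data.

## The phantom generator

No public THG dataset of fresh brain tissue exists, so the package ships a
synthetic phantom generator that emulates exactly the features the
pipeline measures — not the nonlinear optics. A `phantom_spec()` describes
a ~300 × 300 µm field at 0.3 µm/px (1000 × 1000 px): neuropil fibers as
smoothed random-walk polylines 2–5 px wide at intensity 0.85 on a 0.45
background; dark elliptical cells (interior 0.12, equivalent radius
20–30 px ≈ 6–9 µm, aspect ≤ 1.6, disjoint by default) each carrying a
nucleus at 70% of the cell axes, rendered bright (0.8) with probability
`nucleus_visibility = 0.5`; bright granules of 2–5 px radius, below the
500 px filter by construction; Gaussian PSF blur (σ = 1 px); Poisson shot
noise (400 expected photons at unit intensity) plus Gaussian read noise
(σ = 0.01) — a contrast-to-noise ratio comfortably above 5. *Faint cells*
model the known failure mode that motivates the Hough rescue: their
bodies sit only 0.04 below the background (invisible to the dark phase)
and their circular nuclei (radius 8–12 px) only 0.05 above it (invisible
to the bright phase). Faint nuclei are placed where fibers cover less
than 20% of the nucleus area, since a rim buried under fibers is not
recoverable by any detector operating on the background phase.

Ground truth is exact: per-class binary masks plus per-object records
whose areas sum to the mask pixel counts (cells are disjoint; fiber and
granule areas are counted incrementally, and fiber pixels displaced by
cells are removed from the neuropil truth). Everything is generated under
a private RNG stream, so identical spec + seed gives bit-identical images
and truth on any platform.

`generate_gradient_mosaic()` renders one large scene whose per-band cell
counts interpolate a target PoS gradient (emulating the gradient of
invasive tumor cells from normal brain into the tumor core) and cuts it
into tiles with genuine 20% overlap margins; `generate_paired_hoe()`
re-renders the identical scene geometry as a fluorescence channel where
each nucleus appears with probability `uptake_uniformity`, emulating
uneven dye uptake.

What the phantoms do **not** contain: real THG speckle statistics, vessel
shadows, macrophages, depth-dependent attenuation, stitching illumination
seams, or the morphological diversity of actual gliomas. Passing the
phantom suite therefore demonstrates that the implementation measures
what it claims to measure on scenes with known answers — not that the
fixed thresholds transfer to clinical data, which requires patient
images this package does not ship.

## Numerical choices and degenerate inputs

* Connectivity: 8-connectivity for objects, 4-connectivity for background
  and hole filling (the Jordan-consistent pairing).
* Single-pixel objects: perimeter floors at 4; sphericity is clipped to
  (0, 1.2] to absorb discretization overshoot.
* Watershed splitting intersects children with their 8-connected parents,
  so splitting never creates pixels and never merges distinct parents.
* Constant or two-level images: enhancement is a documented no-op and
  segmentation returns all-background with a warning.
* The diffusion time step is validated against the explicit-scheme
  stability bound (0.25) before iterating.
* All randomness (phantoms only — the pipeline itself is deterministic)
  runs in private RNG streams derived from the spec seed; the caller's
  RNG state is never touched.

## Problem sizes used in the validation experiments

The shipped experiments use 1000 × 1000 px phantoms with 20–40 cells plus
5 faint cells for planted-object recovery (20 phantoms in the test suite,
12 in the acceptance script); a 1 × 6 gradient mosaic of 600 × 600 px
tiles spanning PoS 0.05–0.30 for the transition experiment — rendered
with `nucleus_visibility = 0.2`, the low-grade "occasionally delineated
nuclei" phenotype, so that the normal→tumor transition probes the
cell-density clause rather than being pre-empted by the nucleus clause
(at visibility 0.5 the detected nucleus PoS, ≈ 0.25 × cell PoS, crosses
0.03 before cell PoS crosses 0.17); twelve
512 × 512 px regions of 4–30 cells for the THG–fluorescence correlation;
and 400 × 400 px phantoms for determinism and stitching round trips.
These sizes keep a full validation run in the minutes range on a single
core while preserving the 0.3 µm/px scale that the size thresholds
(1000/500/10000 px) assume.

## Known limitations

* The sphericity thresholds act on the boundary-chain perimeter
  convention described above; a different perimeter estimator (e.g.
  Crofton) would shift borderline objects and would need re-validated
  gates.
* The Hough rescue targets approximately circular rims; strongly
  elliptical faint nuclei (aspect beyond ~1.4) vote diffusely and may be
  missed — their normals do not pass near a common center.
* The region-competition segmentation assumes three roughly unimodal
  intensity populations; heavy illumination gradients should be corrected
  before quantification (flat-field correction is out of scope).
* The 0.17/0.03 thresholds are treated as constants of the method. On any
  new imaging protocol (different contrast, pixel size, or tissue
  handling) they require recalibration against reference labels.
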