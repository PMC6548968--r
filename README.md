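# thgq — quantitative cellularity mapping for THG microscopy of brain tissue

Third harmonic generation (THG) microscopy images fresh, unstained brain
tissue at subcellular resolution: neuropil appears as bright fibers, cell
bodies as dark holes, nuclei occasionally as bright blobs inside them, and
lipofuscin granules as small bright specks. Because diffuse gliomas
infiltrate by raising local cell density, measuring how much of a THG
image is occupied by cells and nuclei turns label-free contrast into a
tumor-margin readout. `thgq` is for groups building or evaluating such
label-free neurosurgical imaging pipelines: it implements the full
automated quantification workflow, plus a synthetic phantom generator
with exact ground truth so every stage is testable without patient data.

## The method

Each image is contrast-enhanced (histogram truncation + local histogram
equalization) and denoised (salience-weighted anisotropic diffusion),
then partitioned into **dark holes**, **bright objects** and
**background** by a three-phase piecewise-constant segmentation whose
dark/bright means are anchored to the image's intensity extremes. Faint
round nuclei missed by the bright phase are rescued from the background
by a circular Hough transform that votes only along each edge pixel's
gradient direction. Objects are then filtered and classified:

* dark components — hole-filled, watershed-split, kept at area ≥ 1000 px
  → **cell bodies**;
* bright components — area < 500 px rejected; sphericity
  `4πA/P² < 0.1` → **neuropil**; after splitting, sphericity > 0.5 and
  area < 10 000 px → **nuclei** (Hough detections join this pool);
* cell bodies and nuclei are merged into whole-cell detections.

Densities are **percentages of space** (PoS): the union pixel count of a
class divided by the image area; neuropil density is the summed neuropil
perimeter / 100. An image or tile is called

```
TUMOR  iff  cell PoS > 0.17  or  nucleus PoS > 0.03      (both strict)
```

and NORMAL otherwise. Tiles with a ≥ 500 µm field of view are split into
four equal parts whose features are averaged. Mosaics acquired with the
standard 20% tile overlap can be stitched (`stitch_mosaic()`), and paired
Hoechst fluorescence images quantified and correlated against THG cell
density (`quantify_hoe()`, `correlate_densities()`).

## Worked example

```r
library(thgq)

spec <- phantom_spec(image_shape = c(512L, 512L), n_cells = 14,
                     n_faint_cells = 2, rng_seed = 42)
phantom <- generate_phantom(spec)         # image + exact ground truth
res <- quantify_image(phantom$image)      # the full workflow

res$features[, c("cell_pos", "nucleus_pos", "neuropil_density",
                 "n_cells", "n_nuclei")]
#>   cell_pos nucleus_pos neuropil_density n_cells n_nuclei
#>  0.1137085   0.0286293         75.38245      17       10
res$classification$label                  # "NORMAL"  (no rule fired)
mean(phantom$truth$cell_mask)             # true cell PoS: 0.1141
```

The measured cell PoS (0.1137) reproduces the ground-truth density
(0.1141) to three decimals; 17 cell detections cover the 14 planted cells
plus 2 faint cells recovered via their Hough-detected nuclei (and one
split fragment); neither density exceeds its threshold, so the field is
called normal. Raising `n_cells` to ~40 pushes cell PoS past 0.17 and
flips the call to `"TUMOR"` via the cell-density rule.

A command-line interface wrapping the same functions ships in
`inst/cli/thgq.R` (verbs `phantom`, `preprocess`, `segment`, `quantify`,
`classify`, `stitch`, `validate-hoe`, `run`).

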