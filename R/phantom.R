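#' Specification of a synthetic THG brain-tissue phantom
#'
#' Describes a synthetic scene emulating the morphology the quantification
#' workflow measures: dark elliptical cell bodies punched into a bright
#' fibrous neuropil background, occasionally with a bright nucleus inside,
#' small bright lipofuscin-like granules, Gaussian PSF blur and
#' Poisson-plus-Gaussian noise, at ~0.3 um/px sampling of a ~300 x 300 um
#' field. Identical spec and seed produce bit-identical output.
#'
#' Faint cells model the paper-described failure mode of the bright phase:
#' cells whose body contrast is too weak for the dark phase and whose
#' nucleus is only a faint round rim in the background - the targets of
#' the Hough rescue. Their nuclei stay inside their (faint) cell masks, so
#' the truth invariant `nucleus_mask` within the dilated `cell_mask` holds.
#'
#' @param image_shape integer (rows, cols) in px (default `c(1000, 1000)`).
#' @param pixel_size um per px (default 0.3).
#' @param n_cells number of normal-contrast cells (default 25).
#' @param cell_radius_range equivalent-radius range in px (default
#'   `c(20, 30)`; area comfortably above the 1000 px retention filter).
#' @param cell_aspect_max maximal ellipse aspect ratio (default 1.6).
#' @param nucleus_visibility probability a cell's nucleus is rendered
#'   bright in the THG channel (default 0.5).
#' @param nucleus_brightness rendered nucleus intensity (default 0.8).
#' @param nucleus_radius_frac nucleus axes as a fraction of the cell axes
#'   (default 0.7, so nucleus areas clear the 500 px bright-object floor).
#' @param n_fibers number of neuropil fibers (default 40).
#' @param fiber_width_range fiber width range in px (default `c(2, 5)`).
#' @param fiber_intensity fiber intensity (default 0.85).
#' @param n_granules number of bright granules (default 30; granule areas
#'   sit below the 500 px filter by construction).
#' @param granule_radius_range granule radius range in px (default
#'   `c(2, 5)`).
#' @param granule_intensity granule intensity (default 0.9).
#' @param background_level neuropil background intensity (default 0.45).
#' @param cell_level dark-hole interior intensity (default 0.12).
#' @param n_faint_cells number of faint (sub-threshold) cells (default 0).
#' @param faint_cell_contrast how far the faint cell body sits below the
#'   background level (default 0.04, too weak for the dark phase).
#' @param faint_nucleus_contrast how far the faint nucleus sits above the
#'   background level (default 0.05, too weak for the bright phase).
#' @param faint_nucleus_radius_range faint nucleus radius in px (default
#'   `c(8, 12)`, within the default Hough radius range).
#' @param noise_model list with `poisson_scale` (expected photons at unit
#'   intensity; 0 disables shot noise; default 400) and `gaussian_sigma`
#'   (additive read noise sd; default 0.01).
#' @param psf_sigma Gaussian PSF sd in px (default 1).
#' @param max_overlap_frac maximal allowed overlap fraction between a new
#'   cell and already-placed cells (default 0: cells are disjoint and
#'   per-object areas sum exactly to mask pixel counts).
#' @param rng_seed integer seed controlling the entire phantom (default 1).
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(1000L, 1000L), pixel_size = 0.3,
                         n_cells = 25, cell_radius_range = c(20, 30),
                         cell_aspect_max = 1.6,
                         nucleus_visibility = 0.5, nucleus_brightness = 0.8,
                         nucleus_radius_frac = 0.7,
                         n_fibers = 40, fiber_width_range = c(2, 5),
                         fiber_intensity = 0.85,
                         n_granules = 30, granule_radius_range = c(2, 5),
                         granule_intensity = 0.9,
                         background_level = 0.45, cell_level = 0.12,
                         n_faint_cells = 0, faint_cell_contrast = 0.04,
                         faint_nucleus_contrast = 0.05,
                         faint_nucleus_radius_range = c(8, 12),
                         noise_model = list(poisson_scale = 400,
                                            gaussian_sigma = 0.01),
                         psf_sigma = 1, max_overlap_frac = 0,
                         rng_seed = 1L) {
  spec <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
               n_cells = n_cells, cell_radius_range = cell_radius_range,
               cell_aspect_max = cell_aspect_max,
               nucleus_visibility = nucleus_visibility,
               nucleus_brightness = nucleus_brightness,
               nucleus_radius_frac = nucleus_radius_frac,
               n_fibers = n_fibers, fiber_width_range = fiber_width_range,
               fiber_intensity = fiber_intensity, n_granules = n_granules,
               granule_radius_range = granule_radius_range,
               granule_intensity = granule_intensity,
               background_level = background_level, cell_level = cell_level,
               n_faint_cells = n_faint_cells,
               faint_cell_contrast = faint_cell_contrast,
               faint_nucleus_contrast = faint_nucleus_contrast,
               faint_nucleus_radius_range = faint_nucleus_radius_range,
               noise_model = noise_model, psf_sigma = psf_sigma,
               max_overlap_frac = max_overlap_frac,
               rng_seed = as.integer(rng_seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  counts <- c(s$n_cells, s$n_fibers, s$n_granules, s$n_faint_cells)
  if (any(counts < 0)) stop_thgq("counts must be >= 0")
  probs <- c(s$nucleus_visibility, s$max_overlap_frac)
  if (any(probs < 0 | probs > 1)) stop_thgq("probabilities must lie in [0,1]")
  radii <- c(s$cell_radius_range, s$granule_radius_range,
             s$faint_nucleus_radius_range, s$fiber_width_range)
  if (any(radii <= 0)) stop_thgq("radii and widths must be positive")
  if (s$pixel_size <= 0) stop_thgq("pixel_size must be positive")
  if (any(s$image_shape < 64L)) stop_thgq("image sides must be >= 64 px")
  invisible(s)
}

# ---------------------------------------------------------------------------
# Scene construction. Deterministic given spec$rng_seed: all placement draws
# happen here, in a fixed order, under a private RNG stream. `bands` is an
# optional data.frame(r0, r1, c0, c1, n_cells, n_faint) restricting cell
# centers bandwise (used by the gradient mosaic); NULL means one band over
# the whole canvas with spec counts.
phantom_scene <- function(spec, h = spec$image_shape[1],
                          w = spec$image_shape[2], bands = NULL) {
  if (is.null(bands))
    bands <- data.frame(r0 = 1, r1 = h, c0 = 1, c1 = w,
                        n_cells = spec$n_cells, n_faint = spec$n_faint_cells)
  with_seed(spec$rng_seed, {
    fiber_map <- matrix(0L, h, w)
    fibers <- list()
    n_fib <- round(spec$n_fibers * (h * w) / prod(spec$image_shape))
    for (i in seq_len(n_fib)) {
      fb <- sample_fiber(i, h, w, spec$fiber_width_range)
      px <- fb$pixels
      fiber_map[px[fiber_map[px] == 0L]] <- i
      fibers[[i]] <- fb
    }
    occupancy <- matrix(FALSE, h, w)
    cells <- list()
    for (b in seq_len(nrow(bands))) {
      bd <- bands[b, ]
      for (i in seq_len(bd$n_cells)) {
        cells <- c(cells, list(place_cell(spec, h, w, bd, occupancy,
                                          fiber_map, faint = FALSE)))
        occupancy[cells[[length(cells)]]$pixels] <- TRUE
      }
      for (i in seq_len(bd$n_faint)) {
        cells <- c(cells, list(place_cell(spec, h, w, bd, occupancy,
                                          fiber_map, faint = TRUE)))
        occupancy[cells[[length(cells)]]$pixels] <- TRUE
      }
    }
    granules <- list()
    gocc <- matrix(FALSE, h, w)
    n_gr <- round(spec$n_granules * (h * w) / prod(spec$image_shape))
    for (i in seq_len(n_gr)) {
      for (try in 1:50) {
        r <- runif(1, spec$granule_radius_range[1], spec$granule_radius_range[2])
        ctr <- c(runif(1, r + 1, h - r), runif(1, r + 1, w - r))
        px <- disc_pixels(ctr, r, h, w)
        lin <- (px[, 2] - 1L) * h + px[, 1]
        if (!any(gocc[lin])) {
          gocc[lin] <- TRUE
          granules[[length(granules) + 1L]] <- list(center = ctr, r = r,
                                                    pixels = lin)
          break
        }
      }
    }
    list(h = h, w = w, fibers = fibers, fiber_map = fiber_map,
         cells = cells, granules = granules)
  })
}

sample_fiber <- function(id, h, w, width_range) {
  n_steps <- round(runif(1, 0.25, 0.6) * min(h, w))
  width <- runif(1, width_range[1], width_range[2])
  pos <- c(runif(1, 1, h), runif(1, 1, w))
  ang <- runif(1, 0, 2 * pi)
  dang <- rnorm(n_steps, 0, 0.12)
  pts <- matrix(0, n_steps, 2)
  for (s in seq_len(n_steps)) {
    ang <- ang + dang[s]
    pos <- pos + c(sin(ang), cos(ang))
    if (pos[1] < 1 || pos[1] > h || pos[2] < 1 || pos[2] > w) {
      pts <- pts[seq_len(s - 1L), , drop = FALSE]
      break
    }
    pts[s, ] <- pos
  }
  if (nrow(pts) == 0L) pts <- matrix(c(clamp(pos[1], 1, h),
                                       clamp(pos[2], 1, w)), 1, 2)
  # thicken the polyline: disc-shaped stamp at each rounded path point
  rad <- width / 2
  dd <- expand.grid(dr = -ceiling(rad):ceiling(rad),
                    dc = -ceiling(rad):ceiling(rad))
  dd <- dd[dd$dr^2 + dd$dc^2 <= rad^2, ]
  rr <- as.vector(outer(round(pts[, 1]), dd$dr, `+`))
  cc <- as.vector(outer(round(pts[, 2]), dd$dc, `+`))
  ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  lin <- unique((cc[ok] - 1L) * h + rr[ok])
  list(id = id, width = width, points = pts, pixels = as.integer(lin))
}

place_cell <- function(spec, h, w, band, occupancy, fiber_map, faint) {
  if (faint) {
    nuc_r <- runif(1, spec$faint_nucleus_radius_range[1],
                   spec$faint_nucleus_radius_range[2])
    r <- nuc_r / spec$nucleus_radius_frac
  } else {
    r <- runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
  }
  # faint nuclei are the circular-rim targets of the Hough rescue; normal
  # cells get the full ellipse aspect range
  ar <- if (faint) 1 else runif(1, 1, spec$cell_aspect_max)
  a <- r * sqrt(ar); b <- r / sqrt(ar)
  theta <- runif(1, 0, pi)
  m <- max(a, b) + 2
  lo_r <- max(band$r0, m); hi_r <- min(band$r1, h - m)
  lo_c <- max(band$c0, m); hi_c <- min(band$c1, w - m)
  if (lo_r >= hi_r || lo_c >= hi_c)
    stop_thgq("infeasible placement: band too small for cell radius")
  for (try in 1:200) {
    ctr <- c(runif(1, lo_r, hi_r), runif(1, lo_c, hi_c))
    px <- ellipse_pixels(ctr, a, b, theta, h, w)
    lin <- (px[, 2] - 1L) * h + px[, 1]
    if (sum(occupancy[lin]) / length(lin) > spec$max_overlap_frac) next
    # nucleus: concentric ellipse, small random offset, same orientation
    frac <- spec$nucleus_radius_frac
    off_r <- runif(1, 0, 0.4 * (1 - frac) * b)
    off_a <- runif(1, 0, 2 * pi)
    nctr <- ctr + off_r * c(sin(off_a), cos(off_a))
    npx <- ellipse_pixels(nctr, frac * a, frac * b, theta, h, w)
    nlin <- (npx[, 2] - 1L) * h + npx[, 1]
    nlin <- nlin[nlin %in% lin]  # nucleus stays inside the cell body
    visible <- !faint && runif(1) < spec$nucleus_visibility
    if (faint && mean(fiber_map[nlin] > 0L) > 0.2) next  # nucleus under fibers
    return(list(center = ctr, a = a, b = b, theta = theta, faint = faint,
                visible_nucleus = visible, nucleus_center = nctr,
                pixels = lin, nucleus_pixels = nlin))
  }
  stop_thgq("infeasible placement: could not place cell after 200 tries")
}

# ---------------------------------------------------------------------------

render_noise <- function(img, spec, seed_offset) {
  nm <- spec$noise_model
  ps <- nm$poisson_scale %||% 0
  gs <- nm$gaussian_sigma %||% 0
  if (ps <= 0 && gs <= 0) return(img)
  with_seed(spec$rng_seed + seed_offset, {
    out <- img
    if (ps > 0) out <- matrix(rpois(length(out), out * ps) / ps,
                              nrow(out), ncol(out))
    if (gs > 0) out <- out + matrix(rnorm(length(out), 0, gs),
                                    nrow(out), ncol(out))
    clamp(out, 0, 1)
  })
}

phantom_truth_from_scene <- function(scene, spec) {
  h <- scene$h; w <- scene$w
  cell_mask <- matrix(FALSE, h, w)
  nucleus_mask <- matrix(FALSE, h, w)
  granule_mask <- matrix(FALSE, h, w)
  for (cl in scene$cells) cell_mask[cl$pixels] <- TRUE
  for (cl in scene$cells) nucleus_mask[cl$nucleus_pixels] <- TRUE
  for (g in scene$granules) granule_mask[g$pixels] <- TRUE
  fiber_map <- scene$fiber_map
  fiber_map[cell_mask] <- 0L  # cells displace neuropil
  recs <- list()
  add <- function(class, centroid, area, faint = FALSE, visible = NA) {
    recs[[length(recs) + 1L]] <<- data.frame(
      id = length(recs) + 1L, class = class,
      centroid_row = centroid[1] - 1, centroid_col = centroid[2] - 1,
      area = area, faint = faint, visible_thg = visible)
  }
  for (cl in scene$cells)
    add("cell", cl$center, length(cl$pixels), cl$faint, !cl$faint)
  for (cl in scene$cells)
    add("nucleus", cl$nucleus_center, length(cl$nucleus_pixels), cl$faint,
        cl$visible_nucleus || cl$faint)
  nfib <- length(scene$fibers)
  if (nfib > 0) {
    areas <- tabulate(fiber_map[fiber_map > 0L], nbins = nfib)
    for (f in scene$fibers)
      if (areas[f$id] > 0)
        add("fiber", colMeans(f$points), areas[f$id])
  }
  for (g in scene$granules) add("granule", g$center, length(g$pixels))
  structure(list(cell_mask = cell_mask, nucleus_mask = nucleus_mask,
                 neuropil_mask = fiber_map > 0L, granule_mask = granule_mask,
                 records = do.call(rbind, recs)),
            class = "phantom_truth")
}

render_thg_scene <- function(scene, spec) {
  h <- scene$h; w <- scene$w
  img <- matrix(spec$background_level, h, w)
  img[scene$fiber_map > 0L] <- spec$fiber_intensity
  for (cl in scene$cells) {
    img[cl$pixels] <- if (cl$faint)
      spec$background_level - spec$faint_cell_contrast else spec$cell_level
    if (cl$faint) {
      img[cl$nucleus_pixels] <- spec$background_level +
        spec$faint_nucleus_contrast
    } else if (cl$visible_nucleus) {
      img[cl$nucleus_pixels] <- spec$nucleus_brightness
    }
  }
  for (g in scene$granules) img[g$pixels] <- spec$granule_intensity
  img <- gaussian_blur(img, spec$psf_sigma)
  render_noise(img, spec, seed_offset = 1L)
}

#' Generate a synthetic THG phantom with exact ground truth
#'
#' Renders the scene described by a [phantom_spec()]: neuropil fibers as
#' smoothed random-walk polylines at `fiber_intensity`, dark elliptical
#' cells punched through them, bright nuclei inside a `nucleus_visibility`
#' fraction of cells, faint sub-threshold cells/nuclei, bright granules,
#' then Gaussian PSF blur and Poisson + Gaussian noise. Cell placement uses
#' rejection sampling against an overlap budget and raises an error when a
#' feasible placement cannot be found within the retry bound.
#'
#' @param spec a [phantom_spec()].
#' @return List with `image` (numeric matrix in \[0, 1\], attribute
#'   `pixel_size_um`), `truth` (a `phantom_truth`: binary `cell_mask`,
#'   `nucleus_mask`, `neuropil_mask`, `granule_mask` and per-object
#'   `records`), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  validate_phantom_spec(spec)
  scene <- phantom_scene(spec)
  img <- render_thg_scene(scene, spec)
  attr(img, "pixel_size_um") <- spec$pixel_size
  list(image = img, truth = phantom_truth_from_scene(scene, spec),
       spec = spec)
}

#' Generate the paired Hoechst-fluorescence phantom for a THG scene
#'
#' Re-creates the exact scene of `spec` (same seed, same geometry) and
#' renders the fluorescence channel: near-zero background with every
#' nucleus - visible or not in the THG channel - rendered bright with
#' probability `uptake_uniformity`, emulating uneven dye uptake. At
#' `uptake_uniformity = 1` every true nucleus is a bright blob; at 0 the
#' image is noise-only background.
#'
#' @param spec the [phantom_spec()] of the paired THG phantom.
#' @param uptake_uniformity probability in \[0, 1\] that a nucleus takes up
#'   dye and is rendered (default 1).
#' @return Numeric matrix in \[0, 1\] with attributes `pixel_size_um` and
#'   `rendered_nuclei` - a data.frame (cell id, centroid, rendered flag).
#' @export
generate_paired_hoe <- function(spec, uptake_uniformity = 1) {
  validate_phantom_spec(spec)
  if (uptake_uniformity < 0 || uptake_uniformity > 1)
    stop_thgq("uptake_uniformity must lie in [0,1]")
  scene <- phantom_scene(spec)
  h <- scene$h; w <- scene$w
  n <- length(scene$cells)
  rendered <- with_seed(spec$rng_seed + 2L,
                        runif(max(n, 1)) < uptake_uniformity)[seq_len(n)]
  img <- matrix(0.03, h, w)
  for (i in seq_len(n))
    if (rendered[i]) img[scene$cells[[i]]$nucleus_pixels] <- spec$nucleus_brightness
  img <- gaussian_blur(img, spec$psf_sigma)
  img <- render_noise(img, spec, seed_offset = 3L)
  attr(img, "pixel_size_um") <- spec$pixel_size
  attr(img, "rendered_nuclei") <- data.frame(
    cell = seq_len(n),
    centroid_row = vapply(scene$cells, function(cl) cl$nucleus_center[1] - 1,
                          numeric(1)),
    centroid_col = vapply(scene$cells, function(cl) cl$nucleus_center[2] - 1,
                          numeric(1)),
    rendered = rendered)
  img
}

#' Generate a mosaic of phantom tiles with a cell-density gradient
#'
#' Emulates the gradient of invasive tumor cells from normal brain toward
#' the tumor core: one large scene is rendered with per-band cell counts
#' chosen so the true cell PoS interpolates linearly from
#' `density_gradient[1]` (first tile, row-major) to `density_gradient[2]`
#' (last tile), then cut into tiles of `spec$image_shape` with
#' `overlap_fraction` overlap between adjacent tiles, so tiles share
#' consistent background statistics and carry genuine overlap margins for
#' stitching.
#'
#' @param spec a [phantom_spec()]; `image_shape` is the tile shape.
#' @param n_tiles integer (rows, cols) of the mosaic grid.
#' @param density_gradient numeric `(min_PoS, max_PoS)` of true cell PoS,
#'   `min < max` (or equal for a flat mosaic); max must stay below the
#'   packing limit 0.45.
#' @param overlap_fraction tile overlap (default 0.2).
#' @param label_threshold true cell PoS above which a tile's ground-truth
#'   label is `TUMOR` (default 0.17).
#' @return List of tiles, each with `image`, `truth` (cropped masks),
#'   `target_pos`, `true_pos` and `truth_label`; attributes `layout`,
#'   `overlap_fraction`, `canvas` (the full image) and `canvas_truth`.
#' @export
generate_gradient_mosaic <- function(spec, n_tiles, density_gradient,
                                     overlap_fraction = 0.2,
                                     label_threshold = 0.17) {
  validate_phantom_spec(spec)
  stopifnot(length(n_tiles) == 2, all(n_tiles >= 1))
  g <- density_gradient
  if (g[1] > g[2]) stop_thgq("need min_PoS <= max_PoS")
  if (g[2] > 0.45)
    stop_thgq("max_PoS %.2f exceeds the packing limit 0.45", g[2])
  th <- spec$image_shape[1]; tw <- spec$image_shape[2]
  ov_r <- round(overlap_fraction * th); ov_c <- round(overlap_fraction * tw)
  step_r <- th - ov_r; step_c <- tw - ov_c
  h <- th + (n_tiles[1] - 1L) * step_r
  w <- tw + (n_tiles[2] - 1L) * step_c
  k_total <- prod(n_tiles)
  target <- if (k_total == 1) mean(g) else
    g[1] + (seq_len(k_total) - 1) / (k_total - 1) * (g[2] - g[1])
  # per-band cell counts from the mean rendered ellipse area
  rr <- spec$cell_radius_range
  mean_area <- pi * (rr[1]^2 + rr[1] * rr[2] + rr[2]^2) / 3
  bands <- NULL
  band_r <- round(seq(0, h, length.out = n_tiles[1] + 1))
  band_c <- round(seq(0, w, length.out = n_tiles[2] + 1))
  k <- 0
  for (i in seq_len(n_tiles[1])) for (j in seq_len(n_tiles[2])) {
    k <- k + 1
    area_b <- (band_r[i + 1] - band_r[i]) * (band_c[j + 1] - band_c[j])
    bands <- rbind(bands, data.frame(
      r0 = band_r[i] + 1, r1 = band_r[i + 1],
      c0 = band_c[j] + 1, c1 = band_c[j + 1],
      n_cells = round(target[k] * area_b / mean_area),
      n_faint = spec$n_faint_cells))
  }
  scene <- phantom_scene(spec, h, w, bands)
  img <- render_thg_scene(scene, spec)
  truth <- phantom_truth_from_scene(scene, spec)
  tiles <- vector("list", k_total)
  k <- 0
  for (i in seq_len(n_tiles[1])) for (j in seq_len(n_tiles[2])) {
    k <- k + 1
    rs <- (i - 1L) * step_r + seq_len(th)
    cs <- (j - 1L) * step_c + seq_len(tw)
    timg <- img[rs, cs]
    attr(timg, "pixel_size_um") <- spec$pixel_size
    ttruth <- structure(list(cell_mask = truth$cell_mask[rs, cs],
                             nucleus_mask = truth$nucleus_mask[rs, cs],
                             neuropil_mask = truth$neuropil_mask[rs, cs],
                             granule_mask = truth$granule_mask[rs, cs],
                             records = NULL),
                        class = "phantom_truth")
    tp <- mean(ttruth$cell_mask)
    tiles[[k]] <- list(image = timg, truth = ttruth, target_pos = target[k],
                       true_pos = tp,
                       truth_label = if (tp > label_threshold) "TUMOR"
                                     else "NORMAL")
  }
  structure(tiles, layout = as.integer(n_tiles),
            overlap_fraction = overlap_fraction, canvas = img,
            canvas_truth = truth)
}
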