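noise_off <- list(poisson_scale = 0, gaussian_sigma = 0)

small_spec <- function(...) {
  args <- list(image_shape = c(300L, 300L), n_cells = 5, n_fibers = 6,
               n_granules = 5)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

test_that("empty scene renders a constant background with empty truth", {
  sp <- small_spec(n_cells = 0, n_fibers = 0, n_granules = 0,
                   noise_model = noise_off)
  ph <- generate_phantom(sp)
  expect_equal(diff(range(ph$image)), 0)
  expect_equal(as.vector(ph$image[1, 1]), sp$background_level)
  expect_false(any(ph$truth$cell_mask))
  expect_false(any(ph$truth$nucleus_mask))
  expect_false(any(ph$truth$neuropil_mask))
  expect_false(any(ph$truth$granule_mask))
})

test_that("identical spec and seed give bit-identical phantoms", {
  sp <- small_spec(n_cells = 10, rng_seed = 7)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- generate_phantom(small_spec(n_cells = 10, rng_seed = 8))
  expect_false(identical(a$image, c$image))
})

test_that("truth masks agree with brute-force pixel counts of the records", {
  sp <- phantom_spec(image_shape = c(500L, 500L), n_cells = 12,
                     n_faint_cells = 2, rng_seed = 3)
  ph <- generate_phantom(sp)
  rec <- ph$truth$records
  for (cls in c("cell", "nucleus", "granule", "fiber")) {
    mask <- switch(cls, cell = ph$truth$cell_mask,
                   nucleus = ph$truth$nucleus_mask,
                   granule = ph$truth$granule_mask,
                   fiber = ph$truth$neuropil_mask)
    expect_equal(sum(rec$area[rec$class == cls]), sum(mask),
                 info = cls)
  }
  # true cell PoS from the truth mask equals the brute-force pixel ratio
  expect_equal(mean(ph$truth$cell_mask),
               sum(ph$truth$cell_mask) / prod(dim(ph$truth$cell_mask)))
  # every placed structure has at least one truth pixel
  expect_true(all(rec$area >= 1))
})

test_that("nuclei stay inside their cells and cells are darker than fibers", {
  sp <- small_spec(n_cells = 8, n_faint_cells = 2, nucleus_visibility = 1,
                   noise_model = noise_off, rng_seed = 5)
  ph <- generate_phantom(sp)
  expect_true(all(ph$truth$cell_mask[ph$truth$nucleus_mask]))
  # radiometry (pre-noise, noise disabled): cell interiors darker than
  # neuropil; exclude bright nucleus interiors
  cellonly <- ph$truth$cell_mask & !ph$truth$nucleus_mask
  expect_lt(mean(ph$image[cellonly]), mean(ph$image[ph$truth$neuropil_mask]))
})

test_that("infeasible cell placement errors out", {
  sp <- phantom_spec(image_shape = c(128L, 128L), n_cells = 40,
                     cell_radius_range = c(20, 25))
  expect_error(generate_phantom(sp), "infeasible")
})

test_that("paired HOE phantom renders nuclei per the uptake probability", {
  sp <- phantom_spec(image_shape = c(700L, 700L), n_cells = 50,
                     n_fibers = 10, n_granules = 0, nucleus_visibility = 0.3,
                     rng_seed = 21)
  thg <- generate_phantom(sp)
  # full uptake: every true nucleus is bright in the HOE image
  hoe1 <- generate_paired_hoe(sp, uptake_uniformity = 1)
  rn <- attr(hoe1, "rendered_nuclei")
  expect_true(all(rn$rendered))
  nuc <- thg$truth$records[thg$truth$records$class == "nucleus", ]
  for (i in seq_len(nrow(nuc))) {
    r <- round(nuc$centroid_row[i]) + 1; c <- round(nuc$centroid_col[i]) + 1
    expect_gt(hoe1[r, c], 0.5)
  }
  # zero uptake: noise-only background
  hoe0 <- generate_paired_hoe(sp, uptake_uniformity = 0)
  expect_false(any(attr(hoe0, "rendered_nuclei")$rendered))
  expect_lt(max(hoe0), 0.2)
  # partial uptake: rendered fraction within the binomial 99% interval
  hoe <- generate_paired_hoe(sp, uptake_uniformity = 0.7)
  k <- sum(attr(hoe, "rendered_nuclei")$rendered)
  expect_gte(k, qbinom(0.005, 50, 0.7))
  expect_lte(k, qbinom(0.995, 50, 0.7))
  # same seed, same geometry: HOE nuclei colocate with THG truth
  expect_identical(dim(hoe1), dim(thg$image))
})

test_that("gradient mosaic interpolates true PoS and carries overlap", {
  sp <- phantom_spec(image_shape = c(250L, 250L), n_cells = 0,
                     cell_radius_range = c(10, 14), n_fibers = 10,
                     n_granules = 0, rng_seed = 9)
  # flat gradient: every tile close to the target
  flat <- generate_gradient_mosaic(sp, c(1, 3), c(0.05, 0.05))
  for (t in flat) expect_lt(abs(t$true_pos - 0.05), 0.02)
  # rising gradient: true PoS monotone non-decreasing left to right
  mos <- generate_gradient_mosaic(sp, c(1, 6), c(0.05, 0.30))
  tp <- vapply(mos, `[[`, numeric(1), "true_pos")
  expect_true(all(diff(tp) >= -0.005))
  expect_lt(tp[1], 0.1)
  expect_gt(tp[6], 0.22)
  # ground-truth labels flip exactly where true PoS crosses 0.17
  lab <- vapply(mos, `[[`, character(1), "truth_label")
  expect_identical(lab, ifelse(tp > 0.17, "TUMOR", "NORMAL"))
  # tiles are cut from one canvas: adjacent tiles agree on their overlap
  ov <- round(0.2 * 250)
  left <- mos[[1]]$image[, (250 - ov + 1):250]
  right <- mos[[2]]$image[, 1:ov]
  expect_identical(unclass(left), unclass(right))
})

test_that("gradient mosaic rejects an unreachable packing density", {
  sp <- small_spec()
  expect_error(generate_gradient_mosaic(sp, c(1, 3), c(0.1, 0.6)),
               "packing limit")
})
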