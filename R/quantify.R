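#' Percentage of space (PoS) occupied by a set of objects
#'
#' PoS is the density statistic of the workflow: the number of pixels in
#' the union of the given object masks divided by the image size in pixels.
#' It combines object count and object size, which keeps it meaningful in
#' hypercellular tumor areas where clumped cells cannot be separated.
#' Overlapping masks are counted once.
#'
#' @param objects list of `segmented_object`s or cell assemblies (anything
#'   with `mask` + `offset`).
#' @param image_shape integer (rows, cols) of the source image.
#' @return Fraction in \[0, 1\].
#' @export
compute_pos <- function(objects, image_shape) {
  area <- prod(image_shape)
  if (area <= 0) stop_thgq("image area must be positive")
  if (!length(objects)) return(0)
  sum(union_mask(objects, image_shape)) / area
}

#' Neuropil density: total neuropil perimeter / 100
#'
#' The density of fiber-like neuropil is quantified by the summed perimeter
#' (in pixels) of all detected neuropil objects, divided by 100. Perimeter
#' rather than area because neuropil forms a thin reticular web whose
#' boundary length tracks fiber abundance.
#'
#' @param neuropil list of `segmented_object`s of class `NEUROPIL`.
#' @return Non-negative density (unitless).
#' @export
compute_neuropil_density <- function(neuropil) {
  if (!length(neuropil)) return(0)
  sum(vapply(neuropil, `[[`, numeric(1), "perimeter")) / 100
}

#' Build a per-image feature record
#'
#' @param cell_assemblies from [assemble_cells()].
#' @param nuclei list of `NUCLEUS` objects.
#' @param neuropil list of `NEUROPIL` objects.
#' @param image_shape integer (rows, cols).
#' @param image_id,tile_index provenance tags.
#' @return A one-row data.frame: image_id, tile_index, cell_pos,
#'   nucleus_pos, neuropil_density, n_cells, n_nuclei, image_area_px.
#' @export
feature_record <- function(cell_assemblies, nuclei, neuropil, image_shape,
                           image_id = NA_character_, tile_index = NA_integer_) {
  data.frame(image_id = image_id, tile_index = tile_index,
             cell_pos = compute_pos(cell_assemblies, image_shape),
             nucleus_pos = compute_pos(nuclei, image_shape),
             neuropil_density = compute_neuropil_density(neuropil),
             n_cells = length(cell_assemblies), n_nuclei = length(nuclei),
             image_area_px = prod(image_shape))
}

#' Two-threshold normal/tumor classification of one image or tile
#'
#' An image is called tumor if the density (PoS) of brain cells exceeds
#' `cell_pos_threshold` or the nucleus density exceeds
#' `nucleus_pos_threshold`; otherwise it is normal. Both inequalities are
#' strict ("higher than"). The defaults 0.17 and 0.03 separate normal
#' brain from low-grade (cell density) and high-grade (nucleus density)
#' glioma infiltration respectively.
#'
#' @param features one-row data.frame with `cell_pos` and `nucleus_pos`
#'   (see [feature_record()]), or a list with those fields.
#' @param cell_pos_threshold cell-PoS threshold (default 0.17).
#' @param nucleus_pos_threshold nucleus-PoS threshold (default 0.03).
#' @return List of class `classification_result`: `label` (`"NORMAL"` or
#'   `"TUMOR"`), `triggered_rule` (`"CELL_POS"`, `"NUCLEUS_POS"`, `"BOTH"`,
#'   `"NONE"`), and the input `features`.
#' @export
classify_image <- function(features, cell_pos_threshold = 0.17,
                           nucleus_pos_threshold = 0.03) {
  cp <- features$cell_pos > cell_pos_threshold
  np <- features$nucleus_pos > nucleus_pos_threshold
  rule <- if (cp && np) "BOTH" else if (cp) "CELL_POS" else
    if (np) "NUCLEUS_POS" else "NONE"
  structure(list(label = if (rule == "NONE") "NORMAL" else "TUMOR",
                 triggered_rule = rule, features = features),
            class = "classification_result")
}

#' Quantify one THG image end to end
#'
#' Runs the full single-image workflow: enhance, denoise, three-phase
#' segmentation, Hough nucleus rescue from the background, dark-object
#' extraction, bright-object classification, cell assembly, and feature
#' computation.
#'
#' @param img raw intensity image (numeric matrix).
#' @param config configuration list from [default_config()].
#' @param image_id,tile_index provenance tags for the feature record.
#' @return List: `features` (one-row data.frame), `classification`
#'   ([classify_image()] result), `phases`, `objects` (all segmented
#'   objects), `assemblies`, `preprocessed`.
#' @export
quantify_image <- function(img, config = default_config(),
                           image_id = NA_character_,
                           tile_index = NA_integer_) {
  pre <- preprocess_image(img, config)
  s <- config$segmentation
  phases <- withCallingHandlers(
    segment_three_phase(pre, s$max_iterations, s$convergence_tol,
                        s$smoothness_mu, unlist(s$prior_extreme_percentiles),
                        s$anchor_weight, s$reinit_interval),
    warning = function(w) invokeRestart("muffleWarning"))
  hp <- config$hough
  hough <- rescue_nuclei_hough(pre, phases, unlist(hp$radius_range),
                               hp$edge_threshold,
                               hp$accumulator_peak_threshold,
                               hp$min_center_distance, hp$allow_elliptical,
                               hp$min_angular_coverage %||% 0.67,
                               hp$min_interior_contrast %||% 0.05,
                               hp$max_bright_interior %||% 0.3)
  ob <- config$objects
  cells <- extract_dark_objects(phases, ob$min_cell_area, ob$split_h)
  bright <- classify_bright_objects(phases, hough, ob$min_bright_area,
                                    ob$max_nucleus_area,
                                    ob$neuropil_sphericity_max,
                                    ob$nucleus_sphericity_min, ob$split_h,
                                    ob$hough_bypass_size_floor)
  nuclei <- Filter(function(o) o$object_class == "NUCLEUS", bright)
  neuropil <- Filter(function(o) o$object_class == "NEUROPIL", bright)
  assemblies <- assemble_cells(cells, nuclei, ob$merge_gap_px)
  feats <- feature_record(assemblies, nuclei, neuropil, dim(img),
                          image_id, tile_index)
  cl <- config$classifier
  list(features = feats,
       classification = classify_image(feats, cl$cell_pos_threshold,
                                       cl$nucleus_pos_threshold),
       phases = phases, objects = c(cells, bright), assemblies = assemblies,
       preprocessed = pre)
}

#' Classify a mosaic of image tiles, quartering large tiles
#'
#' Each tile is quantified with [quantify_image()]. Tiles whose field of
#' view is at least `large_tile_um` (given `pixel_size_um`) are split into
#' four equal parts; each part is quantified and classified separately and
#' the tile-level features are the arithmetic mean of the four parts, from
#' which the tile-level label is derived.
#'
#' @param tiles list of numeric matrices, all the same shape, row-major
#'   tile order.
#' @param layout integer (rows, cols) of the mosaic grid.
#' @param config configuration list from [default_config()].
#' @param pixel_size_um pixel size in micrometers per px (default 0.3).
#' @return List: `results` (per-tile `classification_result`s), `features`
#'   (per-tile data.frame), `quarters` (per-quarter feature data.frame or
#'   `NULL`), `grid` (rows x cols character label matrix).
#' @export
classify_mosaic <- function(tiles, layout, config = default_config(),
                            pixel_size_um = 0.3) {
  stopifnot(length(tiles) == prod(layout))
  shp <- dim(tiles[[1]])
  if (!all(vapply(tiles, function(t) all(dim(t) == shp), logical(1))))
    stop_thgq("tiles have mixed shapes")
  cl <- config$classifier
  fov_um <- min(shp) * pixel_size_um
  quarter <- isTRUE(cl$quarter_large_tiles) && fov_um >= cl$large_tile_um
  results <- vector("list", length(tiles))
  feats <- NULL; qfeats <- NULL
  for (i in seq_along(tiles)) {
    if (quarter) {
      qs <- quarter_tile(tiles[[i]])
      qf <- do.call(rbind, lapply(seq_along(qs), function(q)
        quantify_image(qs[[q]], config, image_id = sprintf("tile%03d_q%d", i, q),
                       tile_index = i)$features))
      qf$quarter <- seq_len(4)
      qf$label <- vapply(seq_len(4), function(q)
        classify_image(qf[q, ], cl$cell_pos_threshold,
                       cl$nucleus_pos_threshold)$label, character(1))
      qfeats <- rbind(qfeats, qf)
      f <- qf[1, c("image_id", "tile_index", "cell_pos", "nucleus_pos",
                   "neuropil_density", "n_cells", "n_nuclei", "image_area_px")]
      f$image_id <- sprintf("tile%03d", i)
      for (col in c("cell_pos", "nucleus_pos", "neuropil_density",
                    "n_cells", "n_nuclei"))
        f[[col]] <- mean(qf[[col]])
      f$image_area_px <- sum(qf$image_area_px)
    } else {
      f <- quantify_image(tiles[[i]], config, image_id = sprintf("tile%03d", i),
                          tile_index = i)$features
    }
    results[[i]] <- classify_image(f, cl$cell_pos_threshold,
                                   cl$nucleus_pos_threshold)
    feats <- rbind(feats, f)
  }
  grid <- matrix(vapply(results, `[[`, character(1), "label"),
                 nrow = layout[1], ncol = layout[2], byrow = TRUE)
  list(results = results, features = feats, quarters = qfeats, grid = grid)
}

# Four equal rectangles of a tile (row/col halves), row-major order.
quarter_tile <- function(img) {
  h <- nrow(img); w <- ncol(img)
  hr <- floor(h / 2); hc <- floor(w / 2)
  list(img[1:hr, 1:hc, drop = FALSE],
       img[1:hr, (hc + 1):w, drop = FALSE],
       img[(hr + 1):h, 1:hc, drop = FALSE],
       img[(hr + 1):h, (hc + 1):w, drop = FALSE])
}

#' Compare predicted labels against a reference
#'
#' Confusion-matrix summary with `TUMOR` as the positive class:
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
#' percent agreement = matches / total.
#'
#' @param predicted list of `classification_result`s or a character vector
#'   of `"NORMAL"`/`"TUMOR"` labels.
#' @param truth character vector of reference labels, same length.
#' @return Named list: sensitivity, specificity, percent_agreement, and
#'   the counts tp, fn, tn, fp.
#' @export
compare_with_reference <- function(predicted, truth) {
  if (is.list(predicted))
    predicted <- vapply(predicted, `[[`, character(1), "label")
  if (!length(predicted) || length(predicted) != length(truth))
    stop_thgq("predicted and truth must be equal-length, non-empty")
  tp <- sum(predicted == "TUMOR" & truth == "TUMOR")
  fn <- sum(predicted == "NORMAL" & truth == "TUMOR")
  tn <- sum(predicted == "NORMAL" & truth == "NORMAL")
  fp <- sum(predicted == "TUMOR" & truth == "NORMAL")
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       percent_agreement = (tp + tn) / length(truth),
       tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Re-tune the two classifier thresholds on labeled features
#'
#' Grid search maximizing Youden's J (sensitivity + specificity - 1) over
#' candidate (cell PoS, nucleus PoS) threshold pairs. Provided as a
#' utility for recalibration on labeled data; the package defaults (0.17,
#' 0.03) are not derived from this.
#'
#' @param features data.frame with `cell_pos` and `nucleus_pos`.
#' @param truth character vector of `"NORMAL"`/`"TUMOR"`.
#' @param cell_grid,nucleus_grid candidate thresholds.
#' @return List: cell_pos_threshold, nucleus_pos_threshold, youden_j.
#' @export
tune_thresholds <- function(features, truth,
                            cell_grid = seq(0.02, 0.5, by = 0.01),
                            nucleus_grid = seq(0.005, 0.2, by = 0.005)) {
  best <- list(cell_pos_threshold = NA_real_,
               nucleus_pos_threshold = NA_real_, youden_j = -Inf)
  for (ct in cell_grid) for (nt in nucleus_grid) {
    pred <- ifelse(features$cell_pos > ct | features$nucleus_pos > nt,
                   "TUMOR", "NORMAL")
    m <- compare_with_reference(pred, truth)
    j <- m$sensitivity + m$specificity - 1
    if (is.finite(j) && j > best$youden_j)
      best <- list(cell_pos_threshold = ct, nucleus_pos_threshold = nt,
                   youden_j = j)
  }
  best
}
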