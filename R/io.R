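#' Read a grayscale TIFF intensity image
#'
#' Reads an 8/16-bit (or float) grayscale TIFF as a numeric matrix scaled
#' to \[0, 1\]; multi-channel images are reduced to their first channel.
#'
#' @param path file path.
#' @param pixel_size_um pixel size to attach as metadata (default 0.3).
#' @return Numeric matrix with attribute `pixel_size_um`.
#' @export
read_image_tiff <- function(path, pixel_size_um = 0.3) {
  if (!file.exists(path)) stop_thgq("no such file: %s", path)
  x <- tiff::readTIFF(path)
  if (is.list(x)) x <- x[[1]]
  if (length(dim(x)) == 3) x <- x[, , 1]
  x <- as.matrix(x)
  attr(x, "pixel_size_um") <- pixel_size_um
  x
}

#' Write an intensity image as a 16-bit grayscale TIFF
#'
#' @param img numeric matrix; values are clamped to \[0, 1\].
#' @param path output path.
#' @export
write_image_tiff <- function(img, path) {
  tiff::writeTIFF(clamp(unclass(img), 0, 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a phase label map as an 8-bit TIFF (raw labels 0/1/2)
#'
#' @param phases phase label map from [segment_three_phase()].
#' @param path output path.
#' @export
write_label_tiff <- function(phases, path) {
  tiff::writeTIFF(unclass(phases) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an 8-bit label TIFF back to an integer matrix
#'
#' @param path file path.
#' @return Integer matrix of raw label values.
#' @export
read_label_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' Stitch mosaic tiles at a fixed overlap into one image
#'
#' Tiles are placed on a fixed grid with spacing
#' `(1 - overlap_fraction) * tile_shape` and blended with linear feather
#' ramps across the overlap zones (weights of adjacent tiles sum to one,
#' so tiles cut from a common image restitch exactly). The acquisition
#' protocol's overlap is fixed and known (20% by default), so no offset
#' search is needed for phantoms; `refine_px > 0` additionally searches
#' integer offsets up to that radius by cross-correlation against the
#' running mosaic, for real stages with small positioning error.
#'
#' @param tiles list of numeric matrices, identical shapes, row-major.
#' @param layout integer (rows, cols).
#' @param overlap_fraction overlap between adjacent tiles, in \[0, 0.5)
#'   (default 0.2).
#' @param refine_px cross-correlation refinement search radius in px
#'   (default 0 = fixed offsets).
#' @return Stitched numeric matrix of size
#'   `tile + (n - 1) * (1 - overlap) * tile` per axis (rounded).
#' @export
stitch_mosaic <- function(tiles, layout, overlap_fraction = 0.2,
                          refine_px = 0) {
  if (length(tiles) != prod(layout))
    stop_thgq("expected %d tiles, got %d", prod(layout), length(tiles))
  if (overlap_fraction < 0 || overlap_fraction >= 0.5)
    stop_thgq("overlap_fraction must lie in [0, 0.5)")
  th <- nrow(tiles[[1]]); tw <- ncol(tiles[[1]])
  if (!all(vapply(tiles, function(t) nrow(t) == th && ncol(t) == tw,
                  logical(1))))
    stop_thgq("tiles have inconsistent shapes")
  ov_r <- round(overlap_fraction * th); ov_c <- round(overlap_fraction * tw)
  step_r <- th - ov_r; step_c <- tw - ov_c
  h <- th + (layout[1] - 1L) * step_r
  w <- tw + (layout[2] - 1L) * step_c
  acc <- matrix(0, h, w); norm <- matrix(0, h, w)
  k <- 0
  for (i in seq_len(layout[1])) for (j in seq_len(layout[2])) {
    k <- k + 1
    tile <- unclass(tiles[[k]])
    r0 <- (i - 1L) * step_r; c0 <- (j - 1L) * step_c
    if (refine_px > 0 && k > 1) {
      off <- refine_offset(acc, norm, tile, r0, c0, refine_px)
      r0 <- off[1]; c0 <- off[2]
    }
    wr <- feather_weights(th, ov_r, i > 1, i < layout[1])
    wc <- feather_weights(tw, ov_c, j > 1, j < layout[2])
    wt <- outer(wr, wc)
    rs <- r0 + seq_len(th); cs <- c0 + seq_len(tw)
    acc[rs, cs] <- acc[rs, cs] + wt * tile
    norm[rs, cs] <- norm[rs, cs] + wt
  }
  acc / pmax(norm, .Machine$double.eps)
}

# Linear ramp over the overlap band on sides that have a neighbor; the
# ramps of the two tiles sharing a band sum to exactly 1.
feather_weights <- function(n, ov, ramp_start, ramp_end) {
  wgt <- rep(1, n)
  if (ov > 0) {
    ramp <- seq_len(ov) / (ov + 1)
    if (ramp_start) wgt[seq_len(ov)] <- ramp
    if (ramp_end) wgt[n - ov + seq_len(ov)] <- rev(ramp)
  }
  wgt
}

refine_offset <- function(acc, norm, tile, r0, c0, radius) {
  h <- nrow(acc); w <- ncol(acc)
  best <- c(r0, c0); best_score <- -Inf
  for (dr in -radius:radius) for (dc in -radius:radius) {
    rr0 <- r0 + dr; cc0 <- c0 + dc
    if (rr0 < 0 || cc0 < 0 || rr0 + nrow(tile) > h || cc0 + ncol(tile) > w)
      next
    rs <- rr0 + seq_len(nrow(tile)); cs <- cc0 + seq_len(ncol(tile))
    seen <- norm[rs, cs] > 0
    if (sum(seen) < 100) next
    a <- (acc[rs, cs] / pmax(norm[rs, cs], .Machine$double.eps))[seen]
    b <- tile[seen]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    score <- stats::cor(a, b)
    if (score > best_score) { best_score <- score; best <- c(rr0, cc0) }
  }
  best
}

#' Render a QC overlay of segmentation results on the raw image
#'
#' Draws class-colored object contours over the grayscale image: cell
#' bodies and assemblies blue, nuclei white, neuropil red (matching the
#' workflow's phase palette); rejected objects are not drawn. Colors are
#' fixed and deterministic.
#'
#' @param img background intensity image (rescaled to \[0, 1\]).
#' @param objects list of `segmented_object`s and/or cell assemblies.
#' @return `h x w x 3` RGB array in \[0, 1\].
#' @export
render_overlay <- function(img, objects = list()) {
  g <- unclass(img)
  rng <- range(g)
  if (diff(rng) > 0) g <- (g - rng[1]) / diff(rng)
  rgb <- array(rep(g, 3), c(nrow(g), ncol(g), 3))
  cols <- list(CELL_BODY = c(0, 0, 1), ASSEMBLY = c(0, 0, 1),
               NUCLEUS = c(1, 1, 1), NUCLEUS_CANDIDATE = c(1, 1, 1),
               NEUROPIL = c(1, 0, 0))
  for (o in objects) {
    cls <- if (inherits(o, "cell_assembly")) "ASSEMBLY" else o$object_class
    col <- cols[[cls]]
    if (is.null(col)) next
    b <- mask_boundary(o$mask)
    rc <- which(b, arr.ind = TRUE)
    if (!nrow(rc)) next
    rr <- rc[, 1] + o$offset[1] - 1L
    cc <- rc[, 2] + o$offset[2] - 1L
    for (ch in 1:3) rgb[cbind(rr, cc, ch)] <- col[ch]
  }
  rgb
}

# Boundary pixels of a mask: object pixels with a non-object 4-neighbor
# (pixels beyond the bounding box count as background).
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  er <- pad
  for (o in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L)))
    er <- er & shift_mat(pad, o[1], o[2])
  (pad & !er)[2:(h + 1), 2:(w + 1)]
}

#' Default configuration of the quantification workflow
#'
#' Nested list with one section per stage (`preprocess`, `segmentation`,
#' `hough`, `objects`, `classifier`, `phantom`) plus `rng_seed`. All values
#' are the package defaults documented on the stage functions.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(
    preprocess = list(truncate_low = 0.5, truncate_high = 99.5,
                      tile_grid = c(8L, 8L), clip_limit = 2,
                      n_iterations = 15, time_step = 0.2,
                      edge_scale_k = 0.1, salience_weight = 0.5),
    segmentation = list(max_iterations = 500, convergence_tol = 1e-4,
                        smoothness_mu = 0.15,
                        prior_extreme_percentiles = c(2, 98),
                        anchor_weight = 0.5, reinit_interval = 1),
    hough = list(radius_range = c(4L, 25L), edge_threshold = 0.03,
                 accumulator_peak_threshold = 1,
                 min_center_distance = 10, allow_elliptical = TRUE,
                 min_angular_coverage = 0.67, min_interior_contrast = 0.05,
                 max_bright_interior = 0.3),
    objects = list(min_cell_area = 1000, min_bright_area = 500,
                   max_nucleus_area = 10000, neuropil_sphericity_max = 0.1,
                   nucleus_sphericity_min = 0.5, split_h = 2,
                   merge_gap_px = 2, hough_bypass_size_floor = TRUE),
    classifier = list(cell_pos_threshold = 0.17, nucleus_pos_threshold = 0.03,
                      quarter_large_tiles = TRUE, large_tile_um = 500),
    phantom = unclass(phantom_spec()),
    rng_seed = 1L)
}

#' Read / write a workflow configuration (YAML)
#'
#' Configurations round-trip losslessly; unknown top-level sections or
#' unknown keys within a section are rejected.
#'
#' @param path YAML file path.
#' @return [read_config()]: the validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (sec in names(cfg)) {
    if (!sec %in% names(base)) stop_thgq("unknown config section: %s", sec)
    if (is.list(base[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), names(base[[sec]]))
      if (length(bad))
        stop_thgq("unknown key in section %s: %s", sec,
                  paste(bad, collapse = ", "))
      base[[sec]] <- modifyList(base[[sec]], cfg[[sec]])
    } else base[[sec]] <- cfg[[sec]]
  }
  base
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full quantification workflow over a batch of images
#'
#' For each input TIFF: enhance, denoise, three-phase segmentation, Hough
#' nucleus rescue, object extraction and classification, cell assembly,
#' feature computation and the two-threshold normal/tumor call. Writes per
#' image a phase label map (TIFF), a QC overlay (PNG), an object table
#' (CSV), plus batch-level `features.csv` and `report.json`. Files that
#' fail to read or process are recorded as errors and the batch continues.
#'
#' @param inputs character vector of TIFF paths.
#' @param out_dir output directory (created if missing).
#' @param config configuration list from [default_config()].
#' @param timestamp include a timestamp in the JSON report (default FALSE
#'   so reports are byte-reproducible).
#' @return Invisibly, a list with `features` (data.frame), `errors`
#'   (character), and `status` (0 if no file failed, 1 otherwise).
#' @export
run_pipeline <- function(inputs, out_dir, config = default_config(),
                         timestamp = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  features <- NULL; errors <- character(0); labels <- character(0)
  for (path in inputs) {
    res <- tryCatch({
      img <- read_image_tiff(path)
      q <- quantify_image(img, config, image_id = basename(path))
      stem <- sub("\\.[^.]+$", "", basename(path))
      write_label_tiff(q$phases, file.path(out_dir, paste0(stem, "_phases.tif")))
      png::writePNG(render_overlay(q$preprocessed,
                                   c(q$assemblies,
                                     Filter(function(o) o$object_class %in%
                                              c("NUCLEUS", "NEUROPIL"),
                                            q$objects))),
                    file.path(out_dir, paste0(stem, "_overlay.png")))
      write.csv(objects_table(q$objects),
                file.path(out_dir, paste0(stem, "_objects.csv")),
                row.names = FALSE)
      q
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("%s: %s", path, conditionMessage(res)))
    } else {
      f <- res$features
      f$label <- res$classification$label
      f$triggered_rule <- res$classification$triggered_rule
      features <- rbind(features, f)
      labels <- c(labels, res$classification$label)
    }
  }
  if (!is.null(features))
    write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
  report <- list(schema_version = "1.0",
                 n_images = length(inputs), n_failed = length(errors),
                 labels = labels, errors = errors)
  if (timestamp) report$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(features = features, errors = errors,
                 status = if (length(errors)) 1L else 0L))
}
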