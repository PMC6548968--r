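#' Segmented object
#'
#' A single connected component extracted from a phase label map (or from
#' the Hough rescue), carried around as a small list: a local binary mask
#' plus its top-left offset in the source image, the pixel area, the
#' boundary-chain perimeter, the isoperimetric sphericity, the centroid
#' (0-based row/col), the phase of origin (`"DARK_HOLE"`, `"BRIGHT"`,
#' `"HOUGH"`) and the assigned class (`"CELL_BODY"`, `"NUCLEUS"`,
#' `"NEUROPIL"`, `"GRANULE_OR_REJECTED"`, or `NA` before classification).
#'
#' @param id integer object id.
#' @param mask logical matrix, the object's pixels inside its bounding box.
#' @param offset integer (row, col), 1-based position of `mask[1,1]` in the
#'   source image.
#' @param area pixel count; defaults to `sum(mask)`.
#' @param perimeter boundary-chain length in px; computed from the mask when
#'   omitted.
#' @param centroid numeric (row, col), 0-based; computed when omitted.
#' @param phase_origin,object_class character tags, see above.
#' @return An object of class `segmented_object`.
#' @export
new_segmented_object <- function(id, mask, offset, area = NULL,
                                 perimeter = NULL, centroid = NULL,
                                 phase_origin = NA_character_,
                                 object_class = NA_character_) {
  stopifnot(is.matrix(mask), length(offset) == 2L)
  mask <- mask != 0
  if (is.null(area)) area <- sum(mask)
  if (is.null(perimeter)) {
    lab <- matrix(0L, nrow(mask), ncol(mask)); lab[mask] <- 1L
    perimeter <- perimeter_from_labels(lab)[1]
  }
  if (is.null(centroid)) {
    rc <- which(mask, arr.ind = TRUE)
    centroid <- c(mean(rc[, 1]) + offset[1] - 2, mean(rc[, 2]) + offset[2] - 2)
  }
  structure(list(id = as.integer(id), mask = mask,
                 offset = as.integer(offset), area = as.integer(area),
                 perimeter = as.numeric(perimeter),
                 sphericity = compute_sphericity(area, perimeter),
                 centroid = as.numeric(centroid),
                 phase_origin = phase_origin, object_class = object_class),
            class = "segmented_object")
}

#' Isoperimetric sphericity (compactness) of a 2D object
#'
#' Computes the isoperimetric quotient `4 * pi * area / perimeter^2`, the
#' shape statistic used to gate bright objects: fiber-like neuropil scores
#' below 0.1 while round nuclei score above 0.5. Values are clipped to
#' (0, 1.2] to tolerate discretization overshoot of the perimeter
#' estimator; the value is decreasing in elongation at fixed area.
#'
#' @param area object area in pixels (or a `segmented_object`).
#' @param perimeter object perimeter in pixels (boundary-chain length).
#' @return Sphericity in (0, 1.2].
#' @examples
#' compute_sphericity(pi * 30^2, 2 * pi * 30)  # continuous disc -> 1
#' compute_sphericity(100, 40)                 # 10x10 square -> pi/4
#' @export
compute_sphericity <- function(area, perimeter = NULL) {
  if (inherits(area, "segmented_object")) {
    perimeter <- area$perimeter
    area <- area$area
  }
  if (any(area <= 0) || any(perimeter <= 0))
    stop_thgq("area and perimeter must be positive")
  pmin(4 * pi * area / perimeter^2, 1.2)
}

#' Tabulate a set of segmented objects
#'
#' @param objects list of `segmented_object`s.
#' @return A data.frame with one row per object: id, class, area_px,
#'   perimeter_px, sphericity, centroid_row, centroid_col (0-based),
#'   phase_origin.
#' @export
objects_table <- function(objects) {
  data.frame(
    id = vapply(objects, `[[`, integer(1), "id"),
    object_class = vapply(objects, `[[`, character(1), "object_class"),
    area_px = vapply(objects, `[[`, integer(1), "area"),
    perimeter_px = vapply(objects, `[[`, numeric(1), "perimeter"),
    sphericity = vapply(objects, `[[`, numeric(1), "sphericity"),
    centroid_row = vapply(objects, function(o) o$centroid[1], numeric(1)),
    centroid_col = vapply(objects, function(o) o$centroid[2], numeric(1)),
    phase_origin = vapply(objects, `[[`, character(1), "phase_origin"))
}

# Split touching objects: distance-transform watershed with h-maxima style
# seed suppression (EBImage::watershed `tolerance`); guaranteed to neither
# create nor destroy foreground pixels.
split_objects <- function(mask, h = 2) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(mask * 1)
  w <- EBImage::watershed(d, tolerance = h, ext = 1)
  matrix(as.integer(w), nrow(mask), ncol(mask))
}

#' Extract brain-cell bodies from the dark-hole phase
#'
#' Takes the dark-hole phase of a segmentation, fills interior holes (a
#' bright nucleus inside a dark cytoplasm leaves a hole in the dark phase),
#' splits slightly touching cells by a distance-transform watershed, and
#' discards components smaller than `min_area` pixels (small dark specks
#' are not cells; at ~0.3 um/px, 1000 px is roughly a 6 um x 6 um cell
#' footprint). Survivors are tagged `CELL_BODY`.
#'
#' @param phases phase label map from [segment_three_phase()].
#' @param min_area retention threshold in px; components with
#'   `area < min_area` are ignored (default 1000).
#' @param split_h watershed seed-suppression depth in px (default 2).
#' @return List of `segmented_object`s of class `CELL_BODY`.
#' @export
extract_dark_objects <- function(phases, min_area = 1000, split_h = 2) {
  mask <- unclass(phases) == PHASE_DARK
  if (!any(mask)) return(list())
  filled <- as.matrix(EBImage::fillHull(mask * 1)) > 0
  lab8 <- label_components(filled, 8L)
  lab <- split_labelwise(lab8, split_h)
  objs <- objects_from_labels(lab, "DARK_HOLE", "CELL_BODY")
  Filter(function(o) o$area >= min_area, objs)
}

# Apply watershed splitting within each 8-connected parent component so
# diagonal-only neighbors never merge and children keep parent pixels.
split_labelwise <- function(lab8, split_h) {
  mask <- lab8 > 0L
  w <- split_objects(mask, h = split_h)
  # watershed children may straddle 4-/8-connectivity; intersect children
  # with parents so splitting never merges distinct parents
  key <- (as.numeric(w) * (max(lab8) + 1) + as.numeric(lab8)) * mask
  uk <- sort(unique(key[key > 0]))
  out <- matrix(match(key, uk, nomatch = 0L), nrow(lab8), ncol(lab8))
  out
}

#' Classify bright objects into neuropil, nuclei and rejects
#'
#' Implements the bright-object decision cascade: connected components of
#' the bright phase smaller than `min_area` px (lipofuscin granules, specks)
#' are rejected; of the remainder, components with sphericity below
#' `neuropil_sphericity_max` are fiber-like neuropil; the rest are split
#' (slightly touching nuclei) and children with sphericity above
#' `nucleus_sphericity_min` and area below `max_nucleus_area` become nuclei.
#' Hough rescue detections are appended to the nucleus pool subject to the
#' same area ceiling (they bypass the bright-object size floor by default:
#' they are, by construction, faint nuclei the bright phase missed).
#'
#' @param phases phase label map from [segment_three_phase()].
#' @param hough list of Hough detections from [rescue_nuclei_hough()]
#'   (may be empty).
#' @param min_area bright-object size floor in px (default 500).
#' @param max_nucleus_area nucleus size ceiling in px (default 10000).
#' @param neuropil_sphericity_max sphericity below which an object is
#'   neuropil (default 0.1, strict).
#' @param nucleus_sphericity_min sphericity above which a split object is a
#'   nucleus (default 0.5, strict).
#' @param split_h watershed seed suppression depth in px (default 2).
#' @param hough_bypass_size_floor if `FALSE`, Hough detections must also
#'   clear `min_area` (default `TRUE`).
#' @return List of `segmented_object`s tagged `NEUROPIL`, `NUCLEUS` or
#'   `GRANULE_OR_REJECTED`.
#' @export
classify_bright_objects <- function(phases, hough = list(),
                                    min_area = 500, max_nucleus_area = 10000,
                                    neuropil_sphericity_max = 0.1,
                                    nucleus_sphericity_min = 0.5,
                                    split_h = 2,
                                    hough_bypass_size_floor = TRUE) {
  mask <- unclass(phases) == PHASE_BRIGHT
  out <- list()
  if (any(mask)) {
    lab <- label_components(mask, 8L)
    comps <- objects_from_labels(lab, "BRIGHT")
    keep_for_split <- list()
    for (o in comps) {
      if (o$area < min_area) {
        o$object_class <- "GRANULE_OR_REJECTED"; out <- c(out, list(o))
      } else if (o$sphericity < neuropil_sphericity_max) {
        o$object_class <- "NEUROPIL"; out <- c(out, list(o))
      } else keep_for_split <- c(keep_for_split, list(o))
    }
    if (length(keep_for_split)) {
      remaining <- union_mask(keep_for_split, dim(phases))
      lab <- split_labelwise(label_components(remaining, 8L), split_h)
      for (o in objects_from_labels(lab, "BRIGHT")) {
        o$object_class <-
          if (o$sphericity > nucleus_sphericity_min && o$area < max_nucleus_area)
            "NUCLEUS" else "GRANULE_OR_REJECTED"
        out <- c(out, list(o))
      }
    }
  }
  for (o in hough) {
    ok <- o$area < max_nucleus_area &&
      (hough_bypass_size_floor || o$area >= min_area)
    o$object_class <- if (ok) "NUCLEUS" else "GRANULE_OR_REJECTED"
    out <- c(out, list(o))
  }
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' Combine cell bodies and nuclei into whole-cell detections
#'
#' A dark hole is either a whole cell or the cytoplasm around a bright
#' nucleus, so each nucleus whose centroid lies inside a cell-body mask (or
#' within `max_gap_px` of it) is merged with that body; a nucleus merges
#' with at most one body (nearest wins, ties to the lower body id), and
#' nuclei with no body nearby stand alone as nucleus-only cells - they
#' still occupy cell space. The combined mask is the union of the members.
#'
#' @param cell_bodies list of `CELL_BODY` objects.
#' @param nuclei list of `NUCLEUS` objects.
#' @param max_gap_px merge tolerance in px between a nucleus centroid and
#'   the body mask (default 2).
#' @return List of cell assemblies: each has `cell_id`,
#'   `cytoplasm_object_id` (or `NA`), `nucleus_object_ids`, `mask`,
#'   `offset`, `combined_area` and `centroid`.
#' @export
assemble_cells <- function(cell_bodies, nuclei, max_gap_px = 2) {
  nb <- length(cell_bodies)
  assign_to <- integer(length(nuclei))
  for (j in seq_along(nuclei)) {
    cen <- nuclei[[j]]$centroid
    best <- 0L; bestd <- Inf
    for (i in seq_len(nb)) {
      d <- dist_to_mask(cen, cell_bodies[[i]])
      if (d <= max_gap_px && (d < bestd - 1e-9)) { bestd <- d; best <- i }
      # ties (equal distance) resolve to the lower body id: strict < above
    }
    assign_to[j] <- best
  }
  out <- list()
  for (i in seq_len(nb)) {
    members <- c(list(cell_bodies[[i]]), nuclei[assign_to == i])
    out[[length(out) + 1L]] <- make_assembly(
      length(out) + 1L, cell_bodies[[i]]$id,
      vapply(nuclei[assign_to == i], `[[`, integer(1), "id"), members)
  }
  for (j in which(assign_to == 0L)) {
    out[[length(out) + 1L]] <- make_assembly(
      length(out) + 1L, NA_integer_, nuclei[[j]]$id, list(nuclei[[j]]))
  }
  out
}

# Euclidean distance from a 0-based point to the nearest pixel of an
# object's mask (0 when inside).
dist_to_mask <- function(point, obj) {
  rc <- which(obj$mask, arr.ind = TRUE)
  rr <- rc[, 1] + obj$offset[1] - 2  # 0-based
  cc <- rc[, 2] + obj$offset[2] - 2
  sqrt(min((rr - point[1])^2 + (cc - point[2])^2))
}

make_assembly <- function(cell_id, cyto_id, nuc_ids, members) {
  r0 <- min(vapply(members, function(o) o$offset[1], integer(1)))
  c0 <- min(vapply(members, function(o) o$offset[2], integer(1)))
  r1 <- max(vapply(members, function(o) o$offset[1] + nrow(o$mask) - 1L, integer(1)))
  c1 <- max(vapply(members, function(o) o$offset[2] + ncol(o$mask) - 1L, integer(1)))
  m <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  for (o in members) {
    rr <- (o$offset[1] - r0 + 1L):(o$offset[1] - r0 + nrow(o$mask))
    cc <- (o$offset[2] - c0 + 1L):(o$offset[2] - c0 + ncol(o$mask))
    m[rr, cc] <- m[rr, cc] | o$mask
  }
  rc <- which(m, arr.ind = TRUE)
  structure(list(cell_id = cell_id, cytoplasm_object_id = cyto_id,
                 nucleus_object_ids = as.integer(nuc_ids),
                 mask = m, offset = c(r0, c0), combined_area = sum(m),
                 centroid = c(mean(rc[, 1]) + r0 - 2, mean(rc[, 2]) + c0 - 2)),
            class = "cell_assembly")
}
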