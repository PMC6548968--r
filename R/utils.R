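# Internal helpers shared across modules. All raster data are plain R
# matrices indexed [row, col]; coordinates are 0-based (row, col) with the
# origin at the top-left pixel in exported tables, 1-based inside R code.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_thgq <- function(...) stop(sprintf(...), call. = FALSE)

assert_image <- function(img, min_side = 2L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop_thgq("image must be a numeric matrix")
  if (any(!is.finite(img)))
    stop_thgq("image contains non-finite values")
  if (any(dim(img) < min_side))
    stop_thgq("image sides must be >= %d px", min_side)
  invisible(img)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# untouched, and `seed` fully determines the draws (determinism contract).
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Shift a matrix by (dr, dc) with replicated (Neumann) borders.
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- clamp(seq_len(h) + dr, 1L, h)
  ci <- clamp(seq_len(w) + dc, 1L, w)
  m[ri, ci, drop = FALSE]
}

# Minimal union-find used to merge diagonally touching 4-conn labels.
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# Connected-component labeling. EBImage::bwlabel is 4-connectivity; for the
# 8-connectivity required for objects we merge labels that touch diagonally.
label_components <- function(mask, connectivity = 8L) {
  storage.mode(mask) <- "double"
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (connectivity == 4L || n < 2L) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nrow(lab), -ncol(lab)]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -ncol(lab)]), as.vector(lab[-nrow(lab), -1])))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n)
  for (k in seq_len(nrow(pairs))) {
    a <- uf_find(parent, pairs[k, 1]); b <- uf_find(parent, pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  remap <- match(root, sort(unique(root)))
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

# Rasterize a filled ellipse; returns 1-based pixel indices (row, col).
ellipse_pixels <- function(center, a, b, theta, h, w) {
  r0 <- max(1L, floor(center[1] - max(a, b) - 1))
  r1 <- min(h, ceiling(center[1] + max(a, b) + 1))
  c0 <- max(1L, floor(center[2] - max(a, b) - 1))
  c1 <- min(w, ceiling(center[2] + max(a, b) + 1))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(0), col = integer(0)))
  rr <- r0:r1; cc <- c0:c1
  dr <- rep(rr - center[1], times = length(cc))
  dc <- rep(cc - center[2], each = length(rr))
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = rep(rr, times = length(cc))[keep],
        col = rep(cc, each = length(rr))[keep])
}

disc_pixels <- function(center, r, h, w) {
  ellipse_pixels(center, r, r, 0, h, w)
}

# Length of the 8-connected outer boundary chain of each labeled object:
# unit steps count 1, diagonal steps sqrt(2); floor of 4 for degenerate
# (single-pixel / tiny) objects so sphericity never divides by zero.
perimeter_from_labels <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(numeric(0))
  oc <- EBImage::ocontour(lab)
  per <- numeric(n)
  for (nm in names(oc)) {
    pts <- oc[[nm]]
    k <- as.integer(nm)
    if (nrow(pts) < 2L) { per[k] <- 4; next }
    d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
    steps <- sqrt(rowSums(d^2))
    per[k] <- max(sum(steps), 4)
  }
  per
}

# Per-label geometry of a label image: area, centroid (0-based), bounding
# box (1-based inclusive), perimeter.
features_from_labels <- function(lab) {
  n <- max(lab)
  if (n == 0L) {
    return(data.frame(id = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      r0 = integer(0), r1 = integer(0), c0 = integer(0),
                      c1 = integer(0), perimeter = numeric(0)))
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  rc <- arrayInd(idx, dim(lab))
  area <- tabulate(l, nbins = n)
  crow <- rowsum(rc[, 1], l)[, 1] / area
  ccol <- rowsum(rc[, 2], l)[, 1] / area
  r0 <- tapply(rc[, 1], l, min); r1 <- tapply(rc[, 1], l, max)
  c0 <- tapply(rc[, 2], l, min); c1 <- tapply(rc[, 2], l, max)
  data.frame(id = seq_len(n), area = area,
             centroid_row = crow - 1, centroid_col = ccol - 1,
             r0 = as.integer(r0), r1 = as.integer(r1),
             c0 = as.integer(c0), c1 = as.integer(c1),
             perimeter = perimeter_from_labels(lab))
}

# Build the list-of-objects representation from a label image.
objects_from_labels <- function(lab, phase_origin, object_class = NA_character_) {
  feats <- features_from_labels(lab)
  objs <- vector("list", nrow(feats))
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    sub <- lab[f$r0:f$r1, f$c0:f$c1, drop = FALSE] == f$id
    objs[[i]] <- new_segmented_object(
      id = f$id, mask = sub, offset = c(f$r0, f$c0), area = f$area,
      perimeter = f$perimeter, centroid = c(f$centroid_row, f$centroid_col),
      phase_origin = phase_origin, object_class = object_class)
  }
  objs
}

# Paint the union of object masks onto a logical canvas of dims `shape`.
union_mask <- function(objects, shape) {
  out <- matrix(FALSE, shape[1], shape[2])
  for (o in objects) {
    r <- o$offset[1]:(o$offset[1] + nrow(o$mask) - 1L)
    c <- o$offset[2]:(o$offset[2] + ncol(o$mask) - 1L)
    out[r, c] <- out[r, c] | o$mask
  }
  out
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma, boundary = "replicate"))
}
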