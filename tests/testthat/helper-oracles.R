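# Independent brute-force oracles used to cross-check the package's
# vectorized implementations. These are deliberately slow and simple.

# Moore-neighbor boundary tracing (Jacob's stopping criterion); returns the
# closed 8-connected outer boundary chain length: straight steps 1,
# diagonal steps sqrt(2). Degenerate objects floor at 4.
oracle_perimeter <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask != 0
  if (sum(mask) == 0) return(numeric(0))
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  # Moore neighborhood in clockwise order starting from W
  moore <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                  ncol = 2, byrow = TRUE)
  # start: first object pixel in column-major scan (its W neighbor is bg)
  idx <- which(pad, arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  start <- idx[1, ]
  boundary <- list(start)
  prev_dir <- 1  # came from W
  cur <- start
  # walk until the start pixel is re-entered from the same direction
  repeat {
    found <- FALSE
    for (step in 0:7) {
      dir <- ((prev_dir - 1 + step) %% 8) + 1
      cand <- cur + moore[dir, ]
      if (pad[cand[1], cand[2]]) {
        boundary[[length(boundary) + 1]] <- cand
        # backtrack: restart scan from the neighbor before the one found
        prev_dir <- ((dir - 1 + 5) %% 8) + 1
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (length(boundary) > 2 &&
        all(boundary[[length(boundary)]] == boundary[[2]]) &&
        all(boundary[[length(boundary) - 1]] == boundary[[1]])) {
      boundary <- boundary[seq_len(length(boundary) - 2)]
      break
    }
    if (length(boundary) > 8 * sum(mask) + 8) break  # safety
  }
  pts <- do.call(rbind, boundary)
  if (nrow(pts) < 2) return(4)
  d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  max(sum(sqrt(rowSums(d^2))), 4)
}

# Pixel-union percentage of space by direct painting.
oracle_pos <- function(masks_full, image_shape) {
  canvas <- matrix(FALSE, image_shape[1], image_shape[2])
  for (m in masks_full) canvas <- canvas | m
  sum(canvas) / prod(image_shape)
}

# Textbook Pearson correlation and two-sided t-test p-value.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

# Hand confusion-matrix counts.
oracle_confusion <- function(pred, truth) {
  tp <- sum(pred == "TUMOR" & truth == "TUMOR")
  fn <- sum(pred == "NORMAL" & truth == "TUMOR")
  tn <- sum(pred == "NORMAL" & truth == "NORMAL")
  fp <- sum(pred == "TUMOR" & truth == "NORMAL")
  list(sens = tp / (tp + fn), spec = tn / (tn + fp),
       agree = (tp + tn) / length(pred))
}

# Random connected blob mask (union of a few random discs), full-image.
random_blob_mask <- function(h, w, n_discs = 3, rmax = 12) {
  m <- matrix(FALSE, h, w)
  ctr0 <- c(sample(seq(rmax + 2, h - rmax - 2), 1),
            sample(seq(rmax + 2, w - rmax - 2), 1))
  for (i in seq_len(n_discs)) {
    r <- sample(3:rmax, 1)
    ctr <- ctr0 + round(runif(2, -rmax / 2, rmax / 2))
    rr <- pmax(1, ctr[1] - r):pmin(h, ctr[1] + r)
    cc <- pmax(1, ctr[2] - r):pmin(w, ctr[2] + r)
    for (a in rr) for (b in cc)
      if ((a - ctr[1])^2 + (b - ctr[2])^2 <= r^2) m[a, b] <- TRUE
  }
  m
}

# Filled disc / ellipse / bar masks for constructed geometry tests.
disc_mask <- function(h, w, ctr, r) {
  outer(seq_len(h), seq_len(w),
        function(a, b) (a - ctr[1])^2 + (b - ctr[2])^2 <= r^2)
}

bar_mask <- function(h, w, r0, c0, height, width) {
  m <- matrix(FALSE, h, w)
  m[r0:(r0 + height - 1), c0:(c0 + width - 1)] <- TRUE
  m
}

# Wrap a full-image mask as a segmented_object.
as_object <- function(mask, id = 1L, class = NA_character_,
                      origin = "BRIGHT") {
  rc <- which(mask, arr.ind = TRUE)
  r0 <- min(rc[, 1]); r1 <- max(rc[, 1])
  c0 <- min(rc[, 2]); c1 <- max(rc[, 2])
  new_segmented_object(id, mask[r0:r1, c0:c1, drop = FALSE], c(r0, c0),
                       phase_origin = origin, object_class = class)
}

# Greedy one-to-one centroid matching; returns c(tp, n_pred, n_true).
match_centroids <- function(pred_rc, true_rc, tol) {
  used <- rep(FALSE, nrow(true_rc)); tp <- 0
  for (i in seq_len(nrow(pred_rc))) {
    if (!nrow(true_rc)) break
    d <- sqrt((true_rc[, 1] - pred_rc[i, 1])^2 +
              (true_rc[, 2] - pred_rc[i, 2])^2)
    j <- which.min(ifelse(used, Inf, d))
    if (!used[j] && d[j] <= tol) { tp <- tp + 1; used[j] <- TRUE }
  }
  c(tp = tp, n_pred = nrow(pred_rc), n_true = nrow(true_rc))
}
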