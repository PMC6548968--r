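#' Three-phase segmentation into dark holes, bright objects and background
#'
#' Partitions a preprocessed THG image into three intensity phases: dark
#' holes (cell bodies/cytoplasm), bright objects (nuclei, neuropil fibers,
#' granules) and the remaining background. The segmentation minimizes a
#' three-phase piecewise-constant energy - squared deviation from the phase
#' mean plus a Potts boundary penalty `smoothness_mu` - by deterministic
#' iterated conditional modes, with the dark and bright phase means softly
#' anchored ("weighted") to the image's prior intensity extremes (the
#' `prior_extreme_percentiles` quantiles). The anchoring stabilizes the two
#' extreme phases against the dominant mid-intensity background. Phase
#' identity is fixed by intensity ordering of the converged means
#' (dark < background < bright), so the labeling is invariant to any
#' internal relabeling.
#'
#' Images with fewer than three distinct intensity levels have no
#' three-phase structure: an all-background map is returned with a warning.
#'
#' @param img preprocessed image in \[0, 1\].
#' @param max_iterations iteration cap (default 500).
#' @param convergence_tol stop when the fraction of pixels changing label
#'   falls below this (default 1e-4).
#' @param smoothness_mu Potts boundary penalty per disagreeing 4-neighbor,
#'   in squared-intensity units (default 0.15).
#' @param prior_extreme_percentiles percentiles `(low, high)` anchoring the
#'   dark and bright means (default `c(2, 98)`).
#' @param anchor_weight convex weight of the prior extreme in the mean
#'   update, in \[0, 1\] (default 0.5).
#' @param reinit_interval re-estimate phase means every this many label
#'   sweeps (default 1, i.e. every sweep).
#' @return An integer matrix of class `phase_label_map` with values
#'   [PHASE_BACKGROUND] (0), [PHASE_DARK] (1), [PHASE_BRIGHT] (2) and
#'   attributes `means` (named phase means), `iterations`, `converged`.
#' @export
segment_three_phase <- function(img, max_iterations = 500,
                                convergence_tol = 1e-4,
                                smoothness_mu = 0.15,
                                prior_extreme_percentiles = c(2, 98),
                                anchor_weight = 0.5,
                                reinit_interval = 1) {
  assert_image(img)
  p <- prior_extreme_percentiles
  if (!(p[1] > 0 && p[1] < p[2] && p[2] < 100))
    stop_thgq("need 0 < low_pct < high_pct < 100")
  if (!(convergence_tol > 0 && convergence_tol < 1))
    stop_thgq("convergence_tol must lie in (0,1)")
  h <- nrow(img); w <- ncol(img); n <- length(img)
  if (length(unique(as.vector(img))) < 3L) {
    warning("fewer than 3 distinct intensity levels; returning all-background")
    return(new_phase_map(matrix(PHASE_BACKGROUND, h, w),
                         means = c(dark = NA, background = NA, bright = NA),
                         iterations = 0L, converged = TRUE))
  }
  q_lo <- quantile(img, p[1] / 100, names = FALSE)
  q_hi <- quantile(img, p[2] / 100, names = FALSE)
  q_mid <- median(img)
  cm <- c(q_lo, q_mid, q_hi)  # phase means: 1=dark, 2=background, 3=bright
  # deterministic init: nearest anchor
  lab <- nearest_of_three(img, cm, cm)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  parity <- (outer(seq_len(h), seq_len(w), `+`) %% 2L) == 0L
  iterations <- 0L; converged <- FALSE
  for (it in seq_len(max_iterations)) {
    iterations <- it
    if ((it - 1L) %% max(1L, as.integer(reinit_interval)) == 0L) {
      for (k in 1:3) {
        px <- img[lab == k]
        if (length(px)) cm[k] <- mean(px)
      }
      cm[1] <- (1 - anchor_weight) * cm[1] + anchor_weight * q_lo
      cm[3] <- (1 - anchor_weight) * cm[3] + anchor_weight * q_hi
    }
    # red-black half-sweeps: each half updates against the other's current
    # labels, so the Potts energy is non-increasing and cannot oscillate
    changed <- 0
    for (color in c(TRUE, FALSE)) {
      cost <- vector("list", 3)
      for (k in 1:3) {
        ind <- (lab == k) * 1
        nk <- 0
        for (o in offs) nk <- nk + shift_mat(ind, o[1], o[2])
        cost[[k]] <- (img - cm[k])^2 + smoothness_mu * (4 - nk) / 4
      }
      newlab <- argmin_three(cost, img, cm)
      upd <- parity == color & newlab != lab
      changed <- changed + sum(upd)
      lab[upd] <- newlab[upd]
    }
    if (changed / n < convergence_tol) { converged <- TRUE; break }
  }
  # fix phase identity by intensity ordering of converged means
  ord <- order(cm)  # ascending: dark, background, bright
  out <- matrix(PHASE_BACKGROUND, h, w)
  out[lab == ord[1]] <- PHASE_DARK
  out[lab == ord[3]] <- PHASE_BRIGHT
  new_phase_map(out,
                means = c(dark = cm[ord[1]], background = cm[ord[2]],
                          bright = cm[ord[3]]),
                iterations = iterations, converged = converged)
}

new_phase_map <- function(m, means, iterations, converged) {
  storage.mode(m) <- "integer"
  structure(m, means = means, iterations = iterations, converged = converged,
            class = c("phase_label_map", class(m)))
}

# Elementwise argmin over three cost matrices with the deterministic
# tie-break: smaller |I - c_k|, then lowest phase index.
argmin_three <- function(cost, img, cm) {
  dev <- lapply(1:3, function(k) abs(img - cm[k]))
  best <- matrix(1L, nrow(img), ncol(img))
  bc <- cost[[1]]; bd <- dev[[1]]
  for (k in 2:3) {
    take <- cost[[k]] < bc | (cost[[k]] == bc & dev[[k]] < bd)
    best[take] <- k
    bc[take] <- cost[[k]][take]
    bd[take] <- dev[[k]][take]
  }
  best
}

nearest_of_three <- function(img, centers, cm) {
  cost <- lapply(1:3, function(k) (img - centers[k])^2)
  argmin_three(cost, img, cm)
}

#' Rescue faint round nuclei from the background by a circular Hough
#' transform with gradient-directed voting
#'
#' Some nuclei are too faint for the bright phase of
#' [segment_three_phase()]; they remain in the background as weak, round
#' intensity rims. This detector runs only on background-phase pixels: edge
#' pixels (gradient magnitude above `edge_threshold`) cast votes into an
#' accumulator along their gradient direction only (both orientations), at
#' distances `radius_range[1]` to `radius_range[2]`; directional voting
#' concentrates the votes of a circular rim onto its center. Accumulator
#' peaks above `accumulator_peak_threshold` (votes normalized by the
#' circumference `2*pi*r`, after light smoothing) become detections, with
#' greedy non-maximum suppression at `min_center_distance`. Detections
#' whose disc overlaps already-segmented bright objects by more than half
#' are discarded; masks are clipped to the image bounds. With
#' `allow_elliptical`, moderately elliptical rims are accepted by fitting
#' minor/major radii from the supporting edge pixels within +/-20% of the
#' peak radius.
#'
#' @param img preprocessed image in \[0, 1\].
#' @param phases phase label map from [segment_three_phase()].
#' @param radius_range integer `(r_min, r_max)` in px (default `c(4, 25)`).
#' @param edge_threshold gradient magnitude (intensity units per px) above
#'   which a background pixel votes (default 0.03).
#' @param accumulator_peak_threshold minimum pooled votes, normalized by the
#'   circumference `2*pi*r`, for an accumulator peak (default 1; a full
#'   2 px thick rim pooled over adjacent radii scores about 5).
#' @param min_center_distance non-maximum suppression radius in px
#'   (default 10).
#' @param allow_elliptical accept moderately elliptical rims (default TRUE).
#' @param min_angular_coverage fraction of 12 angular sectors around the
#'   center that must contain a radially aligned supporting edge pixel
#'   (default 0.67); a genuine circular rim is supported from all
#'   directions, stray fiber or cell-boundary edges from only a few.
#' @param min_interior_contrast minimum excess of the mean intensity inside
#'   the fitted circle over the surrounding annulus (default 0.05): a
#'   faint nucleus is a bright blob, while rims of dark inter-fiber gaps
#'   and noise blobs fail this polarity check.
#' @param max_bright_interior maximum fraction of the detection disc that
#'   may already carry the bright phase (default 0.3); rescued nuclei are
#'   by definition background structures, while partial rims around
#'   bright fiber segments carry large bright fractions. Detections
#'   overlapping bright objects by more than half are always discarded.
#' @return List of `segmented_object`s with `phase_origin = "HOUGH"`,
#'   `object_class = "NUCLEUS_CANDIDATE"`; each additionally carries
#'   `r_major`, `r_minor` and `votes`.
#' @export
rescue_nuclei_hough <- function(img, phases, radius_range = c(4, 25),
                                edge_threshold = 0.03,
                                accumulator_peak_threshold = 1,
                                min_center_distance = 10,
                                allow_elliptical = TRUE,
                                min_angular_coverage = 0.67,
                                min_interior_contrast = 0.05,
                                max_bright_interior = 0.3) {
  assert_image(img)
  stopifnot(all(dim(img) == dim(phases)))
  if (!(radius_range[1] > 0 && radius_range[1] < radius_range[2]))
    stop_thgq("need 0 < r_min < r_max")
  if (edge_threshold <= 0 || accumulator_peak_threshold <= 0)
    stop_thgq("thresholds must be > 0")
  h <- nrow(img); w <- ncol(img)
  bg <- unclass(phases) == PHASE_BACKGROUND
  if (!any(bg)) return(list())
  gx <- (shift_mat(img, 0, 1) - shift_mat(img, 0, -1)) / 2  # d/dcol
  gy <- (shift_mat(img, 1, 0) - shift_mat(img, -1, 0)) / 2  # d/drow
  gm <- sqrt(gx^2 + gy^2)
  edge <- which(bg & gm > edge_threshold)
  if (!length(edge)) return(list())
  rc <- arrayInd(edge, dim(img))
  ur <- gy[edge] / gm[edge]
  uc <- gx[edge] / gm[edge]
  radii <- seq(as.integer(radius_range[1]), as.integer(radius_range[2]))
  best_val <- matrix(0, h, w)
  best_r <- matrix(0L, h, w)
  raw_acc <- function(r) {
    acc <- matrix(0, h, w)
    for (sgn in c(1, -1)) {
      cr <- as.integer(round(rc[, 1] + sgn * r * ur))
      cc <- as.integer(round(rc[, 2] + sgn * r * uc))
      ok <- cr >= 1L & cr <= h & cc >= 1L & cc <= w
      if (any(ok))
        acc <- acc + tabulate((cc[ok] - 1L) * h + cr[ok], nbins = h * w)
    }
    acc
  }
  # pool votes over a 3x3 spatial window and adjacent radii (rim pixels
  # scatter over ~1 px / 1 radius after blur and rounding), then normalize
  # by the circumference so the score reads as rim coverage
  box3 <- function(m) {
    out <- 0
    for (dr in -1:1) for (dc in -1:1) out <- out + shift_mat(m, dr, dc)
    out
  }
  prev <- raw_acc(radii[1] - 1L)
  cur <- raw_acc(radii[1])
  for (i in seq_along(radii)) {
    nxt <- if (i < length(radii)) raw_acc(radii[i + 1L]) else matrix(0, h, w)
    pooled <- box3(prev + cur + nxt) / (2 * pi * radii[i])
    take <- pooled > best_val
    best_val[take] <- pooled[take]
    best_r[take] <- radii[i]
    prev <- cur; cur <- nxt
  }
  # candidate peaks: strictly-in-background local maxima above threshold
  local_max <- best_val >= max_filter3(best_val)
  cand <- which(local_max & bg & best_val > accumulator_peak_threshold)
  if (!length(cand)) return(list())
  cand <- cand[order(best_val[cand], decreasing = TRUE)]
  crc <- arrayInd(cand, dim(img))
  kept <- integer(0)
  for (i in seq_along(cand)) {
    if (!length(kept)) { kept <- i; next }
    d2 <- (crc[kept, 1] - crc[i, 1])^2 + (crc[kept, 2] - crc[i, 2])^2
    if (all(d2 >= min_center_distance^2)) kept <- c(kept, i)
  }
  bright <- unclass(phases) == PHASE_BRIGHT
  out <- list()
  for (i in kept) {
    ctr <- crc[i, ]; r <- best_r[cand[i]]
    # verification: supporting edge pixels lie on the rim (r +/- 2 px) and
    # their gradients point radially; require them to cover enough sectors
    # sub-pixel refinement: least-squares (Kasa) circle fit on the
    # supporting rim pixels, iterated once with the refined center
    ctr0 <- ctr
    for (tol in c(5, 3, 2)) {
      dr <- rc[, 1] - ctr[1]; dc <- rc[, 2] - ctr[2]
      d <- sqrt(dr^2 + dc^2)
      align <- abs(dr * ur + dc * uc) / pmax(d, 1e-9)
      supp <- d >= r - tol & d <= r + tol & align > 0.8
      if (sum(supp) >= 6) {
        k <- kasa_fit(rc[supp, 1], rc[supp, 2])
        if (!is.null(k) && sqrt(sum((k$center - ctr0)^2)) <= 8 &&
            k$r >= 0.8 * radius_range[1] && k$r <= 1.2 * radius_range[2]) {
          ctr <- k$center; r <- k$r
        }
      }
    }
    dr <- rc[, 1] - ctr[1]; dc <- rc[, 2] - ctr[2]
    d <- sqrt(dr^2 + dc^2)
    align <- abs(dr * ur + dc * uc) / pmax(d, 1e-9)
    supp <- d >= r - 2 & d <= r + 2 & align > 0.8
    if (sum(supp) >= 4) {
      sect <- unique(floor((atan2(dc[supp], dr[supp]) + pi) / (2 * pi) * 12))
      coverage <- length(sect) / 12
    } else coverage <- 0
    if (coverage < min_angular_coverage) next
    if (interior_contrast(img, ctr, r) < min_interior_contrast) next
    if (length(out)) {  # refined centers may collide: keep the first
      prev <- vapply(out, `[[`, numeric(2), "refined_center")
      if (min((prev[1, ] - ctr[1])^2 + (prev[2, ] - ctr[2])^2) <
          min_center_distance^2) next
    }
    fit <- c(r, r)
    if (allow_elliptical) {
      supp2 <- d >= 0.7 * r & d <= 1.3 * r & align > 0.8
      if (sum(supp2) >= 8) {
        qs <- quantile(d[supp2], c(0.1, 0.5, 0.9), names = FALSE)
        fit <- clamp(c(qs[1], qs[3]), 0.8 * r, 1.2 * r)
        r <- clamp(qs[2], 0.8 * r, 1.2 * r)
      }
    }
    px <- disc_pixels(ctr, r, h, w)  # clipped to bounds
    if (nrow(px) == 0L) next
    dm <- matrix(FALSE, h, w); dm[px] <- TRUE
    if (sum(dm & bright) / sum(dm) > min(0.5, max_bright_interior)) next
    r0 <- min(px[, 1]); c0 <- min(px[, 2])
    obj <- new_segmented_object(
      id = length(out) + 1L,
      mask = dm[r0:max(px[, 1]), c0:max(px[, 2]), drop = FALSE],
      offset = c(r0, c0), phase_origin = "HOUGH",
      object_class = "NUCLEUS_CANDIDATE")
    obj$r_major <- fit[2]; obj$r_minor <- fit[1]
    obj$votes <- best_val[cand[i]]
    obj$refined_center <- ctr
    obj$centroid <- ctr - 1  # sub-pixel center, 0-based
    out[[length(out) + 1L]] <- obj
  }
  out
}

# Mean intensity inside 0.7 r minus mean intensity in the 1.2-1.6 r
# annulus around a candidate center (both clipped to the image).
interior_contrast <- function(img, ctr, r) {
  h <- nrow(img); w <- ncol(img)
  inn <- disc_pixels(ctr, 0.7 * r, h, w)
  mid <- disc_pixels(ctr, 1.2 * r, h, w)
  out <- disc_pixels(ctr, 1.6 * r, h, w)
  if (!nrow(inn) || !nrow(out)) return(-Inf)
  lin_i <- (inn[, 2] - 1L) * h + inn[, 1]
  lin_a <- setdiff((out[, 2] - 1L) * h + out[, 1],
                   (mid[, 2] - 1L) * h + mid[, 1])
  if (!length(lin_a)) return(-Inf)
  mean(img[lin_i]) - mean(img[lin_a])
}

# Algebraic least-squares circle fit (Kasa): minimizes the algebraic
# distance; linear solve, robust enough for near-complete rims.
kasa_fit <- function(y, x) {
  A <- cbind(2 * y, 2 * x, 1)
  b <- y^2 + x^2
  sol <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                  error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (r2 <= 0) return(NULL)
  list(center = c(sol[1], sol[2]), r = sqrt(r2))
}

# 3x3 neighborhood maximum (excluding nothing; used for local-max test).
max_filter3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- pmax(out, shift_mat(m, dr, dc))
  }
  out
}
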