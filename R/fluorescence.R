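#' Quantify nuclei in a Hoechst (HOE) fluorescence image
#'
#' Fluorescence nucleus images are quantified like the bright objects of
#' THG images: enhance, denoise, three-phase segmentation, then the
#' bright-object cascade (size floor, sphericity sorting, splitting,
#' nucleus gates). In an HOE image the stained nuclei form the bright
#' phase and the unstained tissue the dark/background phases, so the
#' nucleus pool is exactly what the bright-object path returns.
#'
#' @param img raw HOE fluorescence image (numeric matrix).
#' @param config configuration list from [default_config()].
#' @return List: `nuclei` (list of `NUCLEUS` objects), `nucleus_pos`
#'   (their PoS), `phases`, `objects` (all bright objects).
#' @export
quantify_hoe <- function(img, config = default_config()) {
  pre <- preprocess_image(img, config)
  s <- config$segmentation
  phases <- withCallingHandlers(
    segment_three_phase(pre, s$max_iterations, s$convergence_tol,
                        s$smoothness_mu, unlist(s$prior_extreme_percentiles),
                        s$anchor_weight, s$reinit_interval),
    warning = function(w) invokeRestart("muffleWarning"))
  ob <- config$objects
  bright <- classify_bright_objects(phases, list(), ob$min_bright_area,
                                    ob$max_nucleus_area,
                                    ob$neuropil_sphericity_max,
                                    ob$nucleus_sphericity_min, ob$split_h)
  nuclei <- Filter(function(o) o$object_class == "NUCLEUS", bright)
  list(nuclei = nuclei, nucleus_pos = compute_pos(nuclei, dim(img)),
       phases = phases, objects = bright)
}

#' Correlate THG cell density with fluorescence nucleus density
#'
#' Pearson correlation (with the standard two-sided t-test p-value)
#' between the THG-derived cell PoS and the HOE-derived nucleus PoS across
#' spatially co-registered regions, plus a leave-one-out table for the
#' exclusion analysis: regions with uneven dye uptake depress the
#' correlation, and excluding such a region should restore it.
#'
#' @param pairs data.frame with columns `thg_cell_pos` and
#'   `hoe_nucleus_pos` (one row per region; `region_id` optional).
#' @return List: `r`, `p_value`, `n`, and `leave_one_out` - a data.frame
#'   with the excluded region index and the r/p recomputed on the
#'   remaining n - 1 pairs.
#' @export
correlate_densities <- function(pairs) {
  x <- pairs$thg_cell_pos; y <- pairs$hoe_nucleus_pos
  if (length(x) < 3) stop_thgq("need at least 3 paired regions")
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop_thgq("correlation undefined for a constant density vector")
  ct <- cor.test(x, y, method = "pearson")
  loo <- do.call(rbind, lapply(seq_along(x), function(i) {
    xi <- x[-i]; yi <- y[-i]
    if (length(xi) < 3 || diff(range(xi)) == 0 || diff(range(yi)) == 0)
      return(data.frame(excluded = i, r = NA_real_, p_value = NA_real_,
                        n = length(xi)))
    cti <- cor.test(xi, yi, method = "pearson")
    data.frame(excluded = i, r = unname(cti$estimate),
               p_value = cti$p.value, n = length(xi))
  }))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       leave_one_out = loo)
}
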