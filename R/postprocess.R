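# Convert the W-Net class map into the final plaque mask.
#
# The class map is unsupervised, so nothing says which class is plaque. The
# assignment is made in color space: each class's mean RGB is classified
# plaque / non-plaque by a k-nearest-neighbour vote against a small labelled
# palette of reference tones (Oil-Red-O reds as plaque seeds; wall and
# background tones as non-plaque seeds). The candidate mask is then
# intersected with the artery, cleaned morphologically (opening then
# closing with disk kernels), stripped of sub-threshold 8-connected
# clusters, and finally subjected to the empty-slide rule: below a small
# fraction of the artery area the slide is declared plaque-free.

#' Post-processing configuration
#'
#' @param knn_k neighbours in the palette vote (odd; default 3).
#' @param reference_palette data frame with columns `r`, `g`, `b` (8-bit)
#'   and `is_plaque` (logical); the default holds ORO red shades and
#'   wall/lumen/background tones from the generator's color model.
#' @param open_kernel_px,close_kernel_px disk radii (px) of the
#'   morphological opening and closing.
#' @param min_cluster_px 8-connected components smaller than this are
#'   removed (components exactly at the threshold are kept).
#' @param empty_fraction_threshold plaque fraction of the artery area below
#'   which a slide is declared plaque-free (default 0.005).
#' @param relative_cluster_threshold interpret `min_cluster_px` as a
#'   fraction of the artery area instead of absolute pixels.
#' @param adaptive_cluster_threshold halve the cluster threshold when total
#'   candidate plaque is below 5% of the artery (off by default).
#' @return an object of class `postprocess_config`.
#' @export
postprocess_config <- function(knn_k = 3L,
                               reference_palette = default_palette(),
                               open_kernel_px = 2L, close_kernel_px = 1L,
                               min_cluster_px = 10L,
                               empty_fraction_threshold = 0.005,
                               relative_cluster_threshold = FALSE,
                               adaptive_cluster_threshold = FALSE) {
  if (knn_k %% 2L == 0L) stop("knn_k must be odd")
  if (open_kernel_px < 1L || close_kernel_px < 1L) {
    stop("kernel radii must be at least 1 px")
  }
  if (min_cluster_px < 0) stop("min_cluster_px must be nonnegative")
  structure(list(knn_k = as.integer(knn_k),
                 reference_palette = reference_palette,
                 open_kernel_px = as.integer(open_kernel_px),
                 close_kernel_px = as.integer(close_kernel_px),
                 min_cluster_px = min_cluster_px,
                 empty_fraction_threshold = empty_fraction_threshold,
                 relative_cluster_threshold = relative_cluster_threshold,
                 adaptive_cluster_threshold = adaptive_cluster_threshold),
            class = "postprocess_config")
}

#' Default reference palette for plaque / non-plaque color voting
#' @return data frame with `r`, `g`, `b`, `is_plaque`.
#' @export
default_palette <- function() {
  # Plaque seeds span saturated ORO red through progressively diluted reds:
  # an unsupervised class that carries plaque is a partial-volume mixture of
  # red and wall tones and must still vote plaque at the class level (the
  # per-pixel refinement pass then removes the wall pixels it drags along).
  # The strongest dilutions sit close to wall tone, so they participate in
  # the class vote only (`pixel_vote = FALSE`): at pixel scale, dilution
  # means boundary mixing, and only confident tones may keep a pixel.
  # Non-plaque seeds cover wall, lumen, background and a neutral gray.
  data.frame(r = c(190, 170, 210, 215, 212, 218, 222,
                   225, 243, 236, 200),
             g = c(60, 50, 80, 130, 140, 162, 175,
                   185, 238, 228, 200),
             b = c(70, 60, 90, 140, 148, 170, 182,
                   195, 240, 232, 205),
             is_plaque = c(rep(TRUE, 7), rep(FALSE, 4)),
             pixel_vote = c(rep(TRUE, 5), FALSE, FALSE, rep(TRUE, 4)))
}

#' Select plaque-voted classes from a class map
#'
#' For each class present in the map, the mean RGB over its pixels is
#' classified plaque / non-plaque by a k-nn vote among the palette seeds
#' (Euclidean RGB distance; ties broken towards the nearer seed set by
#' summed distance). The union of plaque-voted classes is the candidate
#' mask; all classes voting non-plaque yields a valid empty candidate.
#'
#' With `pixel_refine` (the default) the same k-nn vote is then applied to
#' each candidate pixel's own color, and pixels voting non-plaque are
#' dropped. An unsupervised class is rarely pure; the class-level vote
#' decides *which* classes carry plaque, the pixel-level pass removes the
#' wall pixels such a class drags along.
#'
#' @param class_map a `class_map` from [infer_class_map].
#' @param slide the [slide_image] the map was computed on (colors are read
#'   from it, after any transfer already applied upstream).
#' @param cfg a [postprocess_config].
#' @param pixel_refine apply the per-pixel k-nn cleanup (default TRUE).
#' @return a [binary_mask] candidate (role `"plaque"`).
#' @export
select_plaque_classes <- function(class_map, slide,
                                  cfg = postprocess_config(),
                                  pixel_refine = TRUE) {
  pal <- cfg$reference_palette
  if (nrow(pal) == 0L || !any(pal$is_plaque) || all(pal$is_plaque)) {
    stop("palette needs both plaque and non-plaque seeds")
  }
  labels <- class_map$labels
  out <- matrix(FALSE, nrow(labels), ncol(labels))
  for (k in seq_len(class_map$k_classes)) {
    sel <- labels == k
    if (!any(sel)) next  # class with zero pixels: skipped
    mu <- vapply(1:3, function(c) mean(slide$pixels[, , c][sel]), numeric(1))
    if (knn_vote_plaque(mu, pal, cfg$knn_k)) out <- out | sel
  }
  if (pixel_refine && any(out)) {
    ppal <- if ("pixel_vote" %in% names(pal)) pal[pal$pixel_vote, ] else pal
    idx <- which(out)
    px <- cbind(slide$pixels[, , 1L][idx], slide$pixels[, , 2L][idx],
                slide$pixels[, , 3L][idx])
    d2 <- vapply(seq_len(nrow(ppal)), function(j) {
      (px[, 1L] - ppal$r[j])^2 + (px[, 2L] - ppal$g[j])^2 +
        (px[, 3L] - ppal$b[j])^2
    }, numeric(length(idx)))
    d2 <- matrix(d2, nrow = length(idx))
    kk <- min(cfg$knn_k, nrow(ppal))
    keep <- vapply(seq_len(length(idx)), function(i) {
      nn <- order(d2[i, ])[seq_len(kk)]
      sum(ppal$is_plaque[nn]) * 2L > kk
    }, logical(1))
    out[idx[!keep]] <- FALSE
  }
  binary_mask(out, role = "plaque", slide_id = slide$slide_id)
}

# k-nn vote of one RGB point against the labelled palette.
knn_vote_plaque <- function(rgb, palette, k) {
  d2 <- (palette$r - rgb[1L])^2 + (palette$g - rgb[2L])^2 +
    (palette$b - rgb[3L])^2
  k <- min(k, nrow(palette))
  nn <- order(d2)[seq_len(k)]
  votes <- sum(palette$is_plaque[nn])
  if (votes * 2L == k) {
    # even split cannot happen with odd k and full votes, but guard anyway
    sum(d2[nn][palette$is_plaque[nn]]) < sum(d2[nn][!palette$is_plaque[nn]])
  } else {
    votes * 2L > k
  }
}

#' Morphological cleaning: opening then closing with disk kernels
#'
#' @param mask a [binary_mask].
#' @param cfg a [postprocess_config] (radii `open_kernel_px`,
#'   `close_kernel_px`).
#' @return the cleaned [binary_mask].
#' @export
morph_clean <- function(mask, cfg = postprocess_config()) {
  # pad with background by the kernel radius so the image border is treated
  # as background, not replicated foreground
  r <- max(cfg$open_kernel_px, cfg$close_kernel_px) + 1L
  h <- nrow(mask$values); w <- ncol(mask$values)
  v <- matrix(0, h + 2L * r, w + 2L * r)
  v[(r + 1L):(r + h), (r + 1L):(r + w)] <- mask$values * 1
  open_brush <- EBImage::makeBrush(2L * cfg$open_kernel_px + 1L, "disc")
  close_brush <- EBImage::makeBrush(2L * cfg$close_kernel_px + 1L, "disc")
  v <- EBImage::opening(v, open_brush)
  v <- EBImage::closing(v, close_brush)
  out <- as.matrix(v)[(r + 1L):(r + h), (r + 1L):(r + w)] > 0.5
  binary_mask(out, role = mask$role, slide_id = mask$slide_id)
}

#' Remove small 8-connected clusters
#'
#' Components with area strictly below `min_cluster_px` are removed;
#' components exactly at the threshold are kept.
#'
#' @param mask a [binary_mask].
#' @param min_cluster_px area threshold in pixels.
#' @return list with the filtered [binary_mask] and `n_clusters`, the
#'   surviving component count.
#' @export
remove_small_clusters <- function(mask, min_cluster_px) {
  if (min_cluster_px < 0) stop("min_cluster_px must be nonnegative")
  lab <- cpp_label8(mask$values)
  if (max(lab) == 0L) {
    return(list(mask = mask, n_clusters = 0L))
  }
  sizes <- tabulate(lab[lab > 0L])
  keep_ids <- which(sizes >= min_cluster_px)
  keep <- matrix(lab %in% keep_ids & lab > 0L, nrow(lab))
  list(mask = binary_mask(keep, role = mask$role, slide_id = mask$slide_id),
       n_clusters = length(keep_ids))
}

#' Finalise the plaque mask and quantify it
#'
#' Fixed order: intersect the candidate with the artery, morphological
#' cleaning, small-cluster removal, then the empty-slide rule (a fraction
#' below `empty_fraction_threshold` forces an empty mask). Areas are
#' converted to mm^2 with `area = plaque_px * (pixel_spacing_um / 1000)^2`.
#'
#' @param candidate plaque candidate [binary_mask].
#' @param artery artery [binary_mask] (must be nonempty).
#' @param slide the [slide_image] (for `pixel_spacing_um` and ids).
#' @param cfg a [postprocess_config].
#' @return an object of class `plaque_result`: `plaque_mask`, `plaque_px`,
#'   `artery_px`, `plaque_fraction`, `plaque_area_mm2`, `is_empty`,
#'   `n_clusters`.
#' @export
finalize_plaque <- function(candidate, artery, slide,
                            cfg = postprocess_config()) {
  if (!any(artery$values)) {
    stop("artery mask is empty; skip this slide")
  }
  artery_px <- sum(artery$values)
  v <- binary_mask(candidate$values & artery$values, "plaque",
                   slide_id = slide$slide_id)
  v <- morph_clean(v, cfg)
  v <- binary_mask(v$values & artery$values, "plaque",
                   slide_id = slide$slide_id)
  thr <- cfg$min_cluster_px
  if (cfg$relative_cluster_threshold) thr <- thr * artery_px
  if (cfg$adaptive_cluster_threshold &&
      sum(v$values) < 0.05 * artery_px) {
    thr <- thr / 2
  }
  rc <- remove_small_clusters(v, thr)
  v <- rc$mask
  plaque_px <- sum(v$values)
  fraction <- plaque_px / artery_px
  is_empty <- fraction < cfg$empty_fraction_threshold
  if (is_empty && plaque_px > 0L) {
    v <- binary_mask(matrix(FALSE, nrow(v$values), ncol(v$values)),
                     "plaque", slide_id = slide$slide_id)
    plaque_px <- 0L
    fraction <- 0
  }
  area_mm2 <- plaque_px * (slide$pixel_spacing_um / 1000)^2
  structure(list(plaque_mask = v, plaque_px = plaque_px,
                 artery_px = artery_px, plaque_fraction = fraction,
                 plaque_area_mm2 = area_mm2, is_empty = is_empty,
                 n_clusters = if (is_empty) 0L else rc$n_clusters,
                 slide_id = slide$slide_id, mouse_id = slide$mouse_id),
            class = "plaque_result")
}

#' @export
print.plaque_result <- function(x, ...) {
  cat(sprintf(
    "<plaque_result %s: %.1f%% of artery (%.4f mm^2, %d clusters)%s>\n",
    x$slide_id, 100 * x$plaque_fraction, x$plaque_area_mm2, x$n_clusters,
    if (x$is_empty) ", empty" else ""))
  invisible(x)
}
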