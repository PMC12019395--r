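# Stage 1: propose an arterial bounding box, crop the slide to it, and paste
# crop-level predictions back to the full frame.
#
# The detector is a pluggable contract: any function `slide -> list of
# list(box = bbox, confidence)` can serve. The built-in desk-scale detector
# is a color-saliency proposer; an external one-class object detector (e.g.
# a YOLO-family model producing the same box format) can be plugged in for
# full-scale use.

#' Built-in color-saliency artery detector
#'
#' Marks pixels whose color is far from the background color (the
#' per-channel median, dominated by surrounding tissue), keeps the largest
#' 8-connected component, and returns its tight box. Confidence is the
#' saliency fraction of the component.
#'
#' @param threshold Euclidean RGB distance (8-bit units) above which a pixel
#'   counts as salient.
#' @return a detector function `slide -> list(list(box, confidence))`.
#' @export
saliency_detector <- function(threshold = 40) {
  function(slide) {
    px <- slide$pixels
    bg <- apply(px, 3L, stats::median)
    d2 <- (px[, , 1L] - bg[1L])^2 + (px[, , 2L] - bg[2L])^2 +
      (px[, , 3L] - bg[3L])^2
    sal <- d2 > threshold^2
    if (!any(sal)) return(list())
    lab <- cpp_label8(sal)
    sizes <- tabulate(lab[lab > 0L])
    keep <- lab == which.max(sizes)
    rows <- which(rowSums(keep) > 0)
    cols <- which(colSums(keep) > 0)
    list(list(box = bbox(min(cols) - 1L, min(rows) - 1L, max(cols),
                         max(rows)),
              confidence = max(sizes) / sum(sal)))
  }
}

roi_fallback_full <- function(shape_hw) {
  structure(list(box = bbox(0L, 0L, shape_hw[2L], shape_hw[1L]),
                 source = "fallback_full", confidence = 0),
            class = "roi_proposal")
}

pad_clip_box <- function(box, shape_hw, padding_frac) {
  pw <- padding_frac * bbox_width(box)
  ph <- padding_frac * bbox_height(box)
  bbox(max(0L, floor(box$x0 - pw)), max(0L, floor(box$y0 - ph)),
       min(shape_hw[2L], ceiling(box$x1 + pw)),
       min(shape_hw[1L], ceiling(box$y1 + ph)),
       confidence = box$confidence)
}

#' Propose a region of interest for a slide
#'
#' Selects the detector's highest-confidence box, pads it by `padding_frac`
#' per side and clips to the image. The function is total: if the detector
#' returns nothing, or the padded crop would be smaller than the
#' segmentation input size in either dimension (cropping below the network
#' input would discard rather than preserve detail), the whole frame is
#' returned as the fallback.
#'
#' @param slide a [slide_image].
#' @param detector detector function (default [saliency_detector()]).
#' @param padding_frac per-side padding fraction (default 0.05).
#' @param min_crop_size `(h, w)` minimum acceptable crop, normally the
#'   segmentation input size (default `c(480, 640)`).
#' @return an object of class `roi_proposal` with fields `box`, `source`
#'   (`"detector"`, `"gt_mask"` or `"fallback_full"`) and `confidence`.
#' @export
propose_roi <- function(slide, detector = saliency_detector(),
                        padding_frac = 0.05, min_crop_size = c(480L, 640L)) {
  shape <- dim(slide$pixels)[1:2]
  dets <- detector(slide)
  if (length(dets) == 0L) return(roi_fallback_full(shape))
  conf <- vapply(dets, function(d) d$confidence %||% 0, numeric(1))
  best <- dets[[which.max(conf)]]
  box <- pad_clip_box(best$box, shape, padding_frac)
  if (bbox_height(box) < min_crop_size[1L] ||
      bbox_width(box) < min_crop_size[2L]) {
    return(roi_fallback_full(shape))
  }
  structure(list(box = box, source = "detector",
                 confidence = best$confidence %||% NA_real_),
            class = "roi_proposal")
}

#' @export
print.roi_proposal <- function(x, ...) {
  cat(sprintf("<roi_proposal %s [%d,%d)x[%d,%d)>\n", x$source, x$box$x0,
              x$box$x1, x$box$y0, x$box$y1))
  invisible(x)
}

#' ROI from a ground-truth artery mask
#'
#' The tight box of the mask's foreground, padded and clipped; used to
#' evaluate the ROI pipeline with oracle boxes. An empty mask falls back to
#' the full frame.
#'
#' @param mask a [binary_mask].
#' @param padding_frac per-side padding fraction.
#' @param min_crop_size `(h, w)` below which the full frame is used;
#'   `c(1, 1)` disables the rule.
#' @return an `roi_proposal` with source `"gt_mask"` (or `"fallback_full"`).
#' @export
bbox_from_mask <- function(mask, padding_frac = 0.05,
                           min_crop_size = c(1L, 1L)) {
  shape <- dim(mask$values)
  if (!any(mask$values)) return(roi_fallback_full(shape))
  rows <- which(rowSums(mask$values) > 0)
  cols <- which(colSums(mask$values) > 0)
  box <- pad_clip_box(bbox(min(cols) - 1L, min(rows) - 1L, max(cols),
                           max(rows)),
                      shape, padding_frac)
  if (bbox_height(box) < min_crop_size[1L] ||
      bbox_width(box) < min_crop_size[2L]) {
    return(roi_fallback_full(shape))
  }
  structure(list(box = box, source = "gt_mask", confidence = 1),
            class = "roi_proposal")
}

#' Crop a slide to an ROI proposal
#'
#' @param slide a [slide_image].
#' @param proposal an `roi_proposal` (or bare [bbox]).
#' @return list with the cropped [slide_image] and the [crop_transform]
#'   needed to paste predictions back.
#' @export
crop_to_roi <- function(slide, proposal) {
  box <- if (inherits(proposal, "bbox")) proposal else proposal$box
  shape <- dim(slide$pixels)[1:2]
  validate_bbox_in(box, shape)
  crop <- slide$pixels[(box$y0 + 1L):box$y1, (box$x0 + 1L):box$x1, ,
                       drop = FALSE]
  list(slide = slide_image(crop, slide_id = slide$slide_id,
                           mouse_id = slide$mouse_id,
                           subdataset_id = slide$subdataset_id,
                           pixel_spacing_um = slide$pixel_spacing_um,
                           group_labels = slide$group_labels),
       transform = crop_transform(shape, box))
}

#' Paste a crop-level mask or map back to the full frame
#'
#' Values are placed at the box location; everything outside the box is
#' background (FALSE / 0). If the transform records a resize, the crop is
#' first resized back to the box size (bilinear; masks are interpolated as
#' 0/1 and re-thresholded at 0.5).
#'
#' @param x a [binary_mask], [prob_map], or bare matrix at crop resolution.
#' @param transform the [crop_transform] returned by [crop_to_roi].
#' @return the same kind of object at full-frame resolution.
#' @export
paste_back <- function(x, transform) {
  box <- transform$box
  bh <- bbox_height(box); bw <- bbox_width(box)
  vals <- if (is.matrix(x)) x else x$values
  is_mask <- inherits(x, "binary_mask") || is.logical(vals)
  expected <- transform$resize_to %||% c(bh, bw)
  if (!all(dim(vals) == expected)) {
    stop("crop shape ", paste(dim(vals), collapse = "x"),
         " inconsistent with transform (expected ",
         paste(expected, collapse = "x"), ")")
  }
  if (!is.null(transform$resize_to) && !all(transform$resize_to == c(bh, bw))) {
    vals <- resize_bilinear(vals * 1, bh, bw)
    if (is_mask) vals <- vals >= 0.5
  }
  full <- matrix(if (is_mask) FALSE else 0, transform$source_shape[1L],
                 transform$source_shape[2L])
  full[(box$y0 + 1L):box$y1, (box$x0 + 1L):box$x1] <- vals
  if (inherits(x, "binary_mask")) {
    binary_mask(full, role = x$role, slide_id = x$slide_id)
  } else if (inherits(x, "prob_map")) {
    prob_map(full, activation_state = x$activation_state)
  } else {
    full
  }
}
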