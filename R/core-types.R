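# Domain types shared by all pipeline stages.
#
# Coordinate convention, used everywhere without exception: pixel grids are
# row-major (H, W[, C]) arrays, rows run top to bottom; coordinates are
# 0-based; bounding boxes are half-open [x0, x1) x [y0, y1) so that
# width = x1 - x0 and crop indexing needs no +/-1 bookkeeping.

#' Construct a whole-slide image object
#'
#' @param pixels integer array `(H, W, 3)`, 8-bit RGB in `[0, 255]`.
#' @param slide_id,mouse_id,subdataset_id identifier strings.
#' @param pixel_spacing_um physical pixel spacing in micrometres per pixel.
#' @param group_labels optional named list carrying study metadata
#'   (`sex`, `genotype`, `diet`).
#' @return an object of class `slide_image`.
#' @export
slide_image <- function(pixels, slide_id = "slide", mouse_id = "mouse",
                        subdataset_id = "sub1", pixel_spacing_um = 10,
                        group_labels = NULL) {
  d <- dim(pixels)
  stopifnot(length(d) == 3L, d[3L] == 3L, d[1L] >= 1L, d[2L] >= 1L)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("slide_image: channel values must lie in [0, 255]")
  }
  if (pixel_spacing_um <= 0) stop("pixel_spacing_um must be positive")
  structure(list(pixels = pixels, slide_id = slide_id, mouse_id = mouse_id,
                 subdataset_id = subdataset_id,
                 pixel_spacing_um = pixel_spacing_um,
                 group_labels = group_labels,
                 aspect_ratio = d[2L] / d[1L]),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image %s: %dx%d px, mouse %s, %.3g um/px>\n",
              x$slide_id, d[2L], d[1L], x$mouse_id, x$pixel_spacing_um))
  invisible(x)
}

#' Construct a binary mask tied to a slide
#'
#' @param values logical `(H, W)` matrix.
#' @param role `"artery"` or `"plaque"`.
#' @param slide_id identifier of the slide the mask belongs to.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(values, role = c("artery", "plaque"),
                        slide_id = "slide") {
  role <- match.arg(role)
  stopifnot(is.matrix(values))
  storage.mode(values) <- "logical"
  structure(list(values = values, role = role, slide_id = slide_id),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %s/%s: %dx%d, %d foreground px>\n", x$slide_id,
              x$role, ncol(x$values), nrow(x$values), sum(x$values)))
  invisible(x)
}

#' Construct a probability/logit map
#'
#' Segmentation networks emit pre-activation logit maps so that ensemble
#' averaging can happen before the output non-linearity; `activation_state`
#' records which side of the sigmoid the values are on.
#'
#' @param values numeric `(H, W)` matrix.
#' @param activation_state `"logit"` or `"probability"`.
#' @return an object of class `prob_map`.
#' @export
prob_map <- function(values, activation_state = c("logit", "probability")) {
  activation_state <- match.arg(activation_state)
  stopifnot(is.matrix(values))
  if (activation_state == "probability" &&
      (min(values) < 0 || max(values) > 1)) {
    stop("probability map values must lie in [0, 1]")
  }
  structure(list(values = values, activation_state = activation_state),
            class = "prob_map")
}

#' Construct an axis-aligned bounding box
#'
#' Boxes are 0-based and half-open: `[x0, x1) x [y0, y1)`.
#'
#' @param x0,y0,x1,y1 integer corners.
#' @param confidence optional detector confidence in `[0, 1]`.
#' @return an object of class `bbox`.
#' @export
bbox <- function(x0, y0, x1, y1, confidence = NA_real_) {
  x0 <- as.integer(x0); y0 <- as.integer(y0)
  x1 <- as.integer(x1); y1 <- as.integer(y1)
  if (x0 < 0L || y0 < 0L || x1 <= x0 || y1 <= y0) {
    stop("invalid bbox: need 0 <= x0 < x1 and 0 <= y0 < y1")
  }
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                 confidence = confidence), class = "bbox")
}

bbox_width <- function(b) b$x1 - b$x0
bbox_height <- function(b) b$y1 - b$y0

validate_bbox_in <- function(b, shape_hw) {
  if (b$x1 > shape_hw[2L] || b$y1 > shape_hw[1L]) {
    stop("bbox exceeds image bounds")
  }
  invisible(b)
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox [%d,%d)x[%d,%d)%s>\n", x$x0, x$x1, x$y0, x$y1,
              if (is.na(x$confidence)) "" else
                sprintf(" conf %.2f", x$confidence)))
  invisible(x)
}

#' Record of a crop (and optional resize) so predictions can be pasted back
#'
#' @param source_shape `(H, W)` of the full frame.
#' @param box the `bbox` that was cropped.
#' @param resize_to optional `(h, w)` the crop was resized to.
#' @return an object of class `crop_transform`.
#' @export
crop_transform <- function(source_shape, box, resize_to = NULL) {
  structure(list(source_shape = as.integer(source_shape), box = box,
                 resize_to = if (!is.null(resize_to)) as.integer(resize_to)),
            class = "crop_transform")
}

#' Construct an aligned stack of masks or maps from ensemble members
#'
#' @param members list of `binary_mask` or `prob_map`, all one shape.
#' @param source_tags character vector naming each member (snapshot index,
#'   `"roi"`/`"full"` origin, ...).
#' @return an object of class `mask_stack`.
#' @export
mask_stack <- function(members, source_tags = NULL) {
  stopifnot(length(members) >= 1L)
  shapes <- vapply(members, function(m) paste(dim(m$values), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L) {
    stop("mask_stack members must share one shape")
  }
  if (is.null(source_tags)) {
    source_tags <- paste0("member", seq_along(members))
  }
  stopifnot(length(source_tags) == length(members))
  structure(list(members = members, source_tags = source_tags),
            class = "mask_stack")
}

#' @export
length.mask_stack <- function(x) length(x$members)

stack_is_binary <- function(stack) {
  all(vapply(stack$members, inherits, logical(1), "binary_mask"))
}

stack_array <- function(stack) {
  d <- dim(stack$members[[1L]]$values)
  vals <- lapply(stack$members, function(m) m$values * 1)
  array(unlist(vals, use.names = FALSE), dim = c(d, length(vals)))
}
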