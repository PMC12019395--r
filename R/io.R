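# Image, mask, bounding-box and manifest codecs.
#
# Slides: PNG or TIFF, 3-channel RGB, read losslessly; 16-bit inputs are
# rescaled to 8-bit by v8 = floor(v16 / 257 + 0.5) (rounding half up).
# Lossy JPEG input is rejected by default because recompression artifacts
# corrupt stain colors; `allow_lossy = TRUE` accepts it with a warning.
# Masks: single-channel PNG, 0 = background, 255 = foreground; on read any
# nonzero value maps to foreground (annotation tools disagree on the
# foreground value). Boxes: one-object YOLO-style text, "0 cx cy w h"
# normalised to [0, 1], class fixed to 0.

#' Read a whole-slide image from PNG or TIFF
#'
#' @param path file path (`.png`, `.tif`/`.tiff`; `.jpg` only with
#'   `allow_lossy`).
#' @param manifest_row optional one-row data frame carrying slide metadata
#'   (columns `slide_id`, `mouse_id`, `subdataset_id`, `pixel_spacing_um`,
#'   `sex`, `genotype`, `diet`).
#' @param allow_lossy accept lossy JPEG input (discouraged; default FALSE).
#' @return a [slide_image].
#' @export
read_slide <- function(path, manifest_row = NULL, allow_lossy = FALSE) {
  if (!file.exists(path)) stop("slide file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg")) {
    if (!allow_lossy) {
      stop("refusing lossy JPEG input (", path,
           "); pass allow_lossy = TRUE to accept it anyway")
    }
    warning("reading lossy JPEG slide: ", path)
    img <- EBImage::readImage(path)
    px <- aperm(as.array(img), c(2L, 1L, 3L))
  } else if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path)
  } else {
    stop("unsupported slide format: .", ext)
  }
  if (length(dim(px)) == 2L) stop("non-RGB slide (single channel): ", path)
  if (dim(px)[3L] == 4L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(px)[3L] != 3L) stop("non-RGB slide: ", path)
  # readers return [0, 1]; quantise to 8-bit with rounding half up
  pixels <- array(as.integer(floor(px * 255 + 0.5)), dim = dim(px))
  meta <- list(slide_id = tools::file_path_sans_ext(basename(path)),
               mouse_id = "unknown", subdataset_id = "unknown",
               pixel_spacing_um = 10, group_labels = NULL)
  if (!is.null(manifest_row)) {
    r <- as.list(manifest_row)
    meta$slide_id <- as.character(r$slide_id %||% meta$slide_id)
    meta$mouse_id <- as.character(r$mouse_id %||% meta$mouse_id)
    meta$subdataset_id <- as.character(r$subdataset_id %||%
                                         meta$subdataset_id)
    meta$pixel_spacing_um <- as.numeric(r$pixel_spacing_um %||%
                                          meta$pixel_spacing_um)
    if (!is.null(r$sex) || !is.null(r$genotype) || !is.null(r$diet)) {
      meta$group_labels <- list(sex = as.character(r$sex %||% NA),
                                genotype = as.character(r$genotype %||% NA),
                                diet = as.character(r$diet %||% NA))
    }
  }
  slide_image(pixels, slide_id = meta$slide_id, mouse_id = meta$mouse_id,
              subdataset_id = meta$subdataset_id,
              pixel_spacing_um = meta$pixel_spacing_um,
              group_labels = meta$group_labels)
}

#' Write a slide as 8-bit PNG
#' @param slide a [slide_image].
#' @param path output path.
#' @export
write_slide <- function(slide, path) {
  png::writePNG(slide$pixels / 255, path)
  invisible(path)
}

#' Write a binary mask as single-channel PNG (0 background / 255 foreground)
#' @param mask a [binary_mask].
#' @param path output path.
#' @param slide_shape optional `(H, W)` to validate the mask against.
#' @export
write_mask <- function(mask, path, slide_shape = NULL) {
  if (!is.null(slide_shape) && !all(dim(mask$values) == slide_shape)) {
    stop("mask shape does not match its slide")
  }
  png::writePNG(mask$values * 1, path)
  invisible(path)
}

#' Read a binary mask from PNG; any nonzero pixel is foreground
#' @param path PNG path.
#' @param role mask role (`"artery"` or `"plaque"`).
#' @param slide_id slide the mask belongs to.
#' @return a [binary_mask].
#' @export
read_mask <- function(path, role = "artery", slide_id = "slide") {
  if (!file.exists(path)) stop("mask file not found: ", path)
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  binary_mask(v > 0, role = role, slide_id = slide_id)
}

#' Write a bounding box as one-line YOLO-style text
#'
#' Format: `"0 cx cy w h"`, centre and size normalised by image width/height.
#'
#' @param box a [bbox].
#' @param image_shape `(H, W)` of the image the box lives on.
#' @param path output path.
#' @export
write_bbox <- function(box, image_shape, path) {
  validate_bbox_in(box, image_shape)
  H <- image_shape[1L]; W <- image_shape[2L]
  cx <- (box$x0 + box$x1) / 2 / W
  cy <- (box$y0 + box$y1) / 2 / H
  bw <- bbox_width(box) / W
  bh <- bbox_height(box) / H
  writeLines(sprintf("0 %.10g %.10g %.10g %.10g", cx, cy, bw, bh), path)
  invisible(path)
}

#' Read a bounding box from YOLO-style text
#'
#' Inverts the normalised encoding, rounding to the nearest integer pixel and
#' clipping to image bounds. An empty file yields `NULL` (no detection; the
#' caller decides the fallback).
#'
#' @param path text file path.
#' @param image_shape `(H, W)`.
#' @return a [bbox] or `NULL`.
#' @export
read_bbox <- function(path, image_shape) {
  if (!file.exists(path)) stop("bbox file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) == 0L) return(NULL)
  f <- as.numeric(strsplit(trimws(ln[1L]), "\\s+")[[1L]])
  vals <- f[2:5]
  if (any(vals < 0 | vals > 1)) {
    stop("normalised bbox values outside [0, 1]")
  }
  H <- image_shape[1L]; W <- image_shape[2L]
  x0 <- max(0L, as.integer(round(vals[1L] * W - vals[3L] * W / 2)))
  y0 <- max(0L, as.integer(round(vals[2L] * H - vals[4L] * H / 2)))
  x1 <- min(W, as.integer(round(vals[1L] * W + vals[3L] * W / 2)))
  y1 <- min(H, as.integer(round(vals[2L] * H + vals[4L] * H / 2)))
  bbox(x0, y0, x1, y1)
}

# ---- manifest -------------------------------------------------------------

manifest_columns <- c("slide_id", "path", "mask_artery", "mask_plaque",
                      "bbox", "mouse_id", "subdataset_id", "sex", "genotype",
                      "diet", "pixel_spacing_um", "split")

#' Read a dataset manifest CSV
#' @param path CSV path with the columns documented in [write_manifest].
#' @return a data frame of class `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_columns, names(m))
  if (length(missing)) stop("manifest missing columns: ",
                            paste(missing, collapse = ", "))
  class(m) <- c("dataset_manifest", "data.frame")
  m
}

#' Write a dataset manifest CSV
#'
#' Columns: `slide_id, path, mask_artery, mask_plaque, bbox, mouse_id,
#' subdataset_id, sex, genotype, diet, pixel_spacing_um, split`.
#'
#' @param manifest manifest data frame.
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest)[, manifest_columns],
                   path, row.names = FALSE)
  invisible(path)
}

#' Split a manifest into train/validation/test, grouped by mouse
#'
#' Whole mice are assigned to splits (a mouse never spans two splits, which
#' would leak near-identical serial sections across the split boundary).
#' Mice are shuffled with `seed` and assigned greedily to the split with the
#' largest remaining slide deficit, so achieved fractions are within one
#' mouse's worth of slides of the targets.
#'
#' @param manifest manifest data frame.
#' @param fractions train/val/test fractions summing to 1 (default 60/20/20).
#' @param seed integer; the split is deterministic given the seed.
#' @param stratify_by optional column name (e.g. `"subdataset_id"`); when
#'   set, the mouse-grouped split is performed within each stratum so every
#'   stratum contributes to every split.
#' @return the manifest with its `split` column filled.
#' @export
split_dataset <- function(manifest, fractions = c(0.6, 0.2, 0.2), seed = 1L,
                          stratify_by = NULL) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (!is.null(stratify_by)) {
    parts <- split(seq_len(nrow(manifest)), manifest[[stratify_by]])
    for (k in seq_along(parts)) {
      idx <- parts[[k]]
      manifest$split[idx] <- split_dataset(manifest[idx, ], fractions,
                                           derive_seed(seed, k))$split
    }
    return(manifest)
  }
  mice <- unique(manifest$mouse_id)
  n_splits <- sum(fractions > 0)
  if (length(mice) < n_splits) {
    stop("fewer mice (", length(mice), ") than nonempty splits (",
         n_splits, ")")
  }
  if (length(mice) < 3L) stop("need at least 3 mice to split")
  order_mice <- local_seed(seed, sample(mice))
  counts <- table(factor(manifest$mouse_id, levels = order_mice))
  total <- nrow(manifest)
  target <- fractions * total
  assigned <- stats::setNames(numeric(3L), c("train", "val", "test"))
  split_of <- character(length(order_mice))
  names(split_of) <- order_mice
  for (m in order_mice) {
    deficit <- target - assigned
    pick <- which.max(deficit)  # ties resolve to train, val, test in order
    split_of[m] <- names(assigned)[pick]
    assigned[pick] <- assigned[pick] + counts[[m]]
  }
  manifest$split <- unname(split_of[manifest$mouse_id])
  manifest
}
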