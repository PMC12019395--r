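test_that("ROI proposal is total: empty detection falls back to full frame", {
  g <- fixture_slide(0.3, 7)
  none <- function(slide) list()
  prop <- propose_roi(g$slide, none, min_crop_size = c(1, 1))
  expect_equal(prop$source, "fallback_full")
  expect_equal(c(prop$box$x0, prop$box$y0, prop$box$x1, prop$box$y1),
               c(0L, 0L, 160L, 120L))
})

test_that("detector boxes are padded per side and clipped", {
  g <- fixture_slide(0.3, 7)
  fixed <- function(slide) list(list(box = bbox(40, 30, 120, 90),
                                     confidence = 0.9))
  prop <- propose_roi(g$slide, fixed, padding_frac = 0.1,
                      min_crop_size = c(1, 1))
  expect_equal(prop$source, "detector")
  expect_equal(prop$box$x0, 32L)  # 40 - 0.1 * 80
  expect_equal(prop$box$x1, 128L)
  expect_equal(prop$box$y0, 24L)  # 30 - 0.1 * 60
  expect_equal(prop$box$y1, 96L)
})

test_that("crops smaller than the network input fall back to full frame", {
  g <- fixture_slide(0.3, 7)
  small <- function(slide) list(list(box = bbox(10, 10, 60, 50),
                                     confidence = 1))
  prop <- propose_roi(g$slide, small, padding_frac = 0,
                      min_crop_size = c(480, 640))
  expect_equal(prop$source, "fallback_full")
})

test_that("mask-derived boxes are tight, half-open, and handle empties", {
  m <- matrix(FALSE, 10, 12)
  m[4, 5] <- TRUE  # row 4 = y index 3, col 5 = x index 4
  prop <- bbox_from_mask(binary_mask(m, "artery"), padding_frac = 0)
  expect_equal(c(prop$box$x0, prop$box$y0, prop$box$x1, prop$box$y1),
               c(4L, 3L, 5L, 4L))
  empty <- bbox_from_mask(binary_mask(matrix(FALSE, 10, 12), "artery"))
  expect_equal(empty$source, "fallback_full")
})

test_that("mask boxes equal a brute-force min/max scan over random blobs", {
  for (seed in 1:50) {
    m <- random_blob_mask(24, 30, 2, seed)
    if (!any(m)) next
    prop <- bbox_from_mask(binary_mask(m, "artery"), padding_frac = 0)
    rows <- which(apply(m, 1, any))
    cols <- which(apply(m, 2, any))
    expect_equal(c(prop$box$x0, prop$box$y0, prop$box$x1, prop$box$y1),
                 c(min(cols) - 1L, min(rows) - 1L, max(cols), max(rows)))
  }
})

test_that("crop and paste-back are exact inverses without resize", {
  g <- fixture_slide(0.3, 7)
  cr <- crop_to_roi(g$slide, bbox(10, 10, 20, 20))
  expect_equal(dim(cr$slide$pixels), c(10L, 10L, 3L))
  expect_identical(cr$slide$pixels, g$slide$pixels[11:20, 11:20, ])
  # all-true crop mask pastes back true exactly on the box
  full <- paste_back(binary_mask(matrix(TRUE, 10, 10), "artery"),
                     cr$transform)
  expect_equal(sum(full$values), 100L)
  expect_true(all(full$values[11:20, 11:20]))
  expect_false(any(full$values[1:10, ]))
  # identity transform
  whole <- crop_to_roi(g$slide, bbox(0, 0, 160, 120))
  expect_identical(whole$slide$pixels, g$slide$pixels)
  back <- paste_back(binary_mask(matrix(TRUE, 120, 160), "artery"),
                     whole$transform)
  expect_true(all(back$values))
  # sum of true pixels preserved for sparse masks
  sp <- matrix(FALSE, 10, 10); sp[c(3, 17, 55)] <- TRUE
  expect_equal(sum(paste_back(binary_mask(sp, "artery"),
                              cr$transform)$values), 3L)
  expect_error(paste_back(binary_mask(matrix(TRUE, 5, 5), "artery"),
                          cr$transform), "inconsistent")
})

test_that("crop-resize-paste round trip keeps a rectangle above IoU 0.95", {
  # full-frame rectangle -> crop to box -> 2x downscale (as if for the
  # network) -> paste back with inverse resize -> compare to the original
  orig <- matrix(FALSE, 120, 160)
  orig[37:66, 41:100] <- TRUE
  box <- bbox(20, 20, 100, 80)
  tr <- crop_transform(c(120, 160), box, resize_to = c(30, 40))
  crop <- orig[21:80, 21:100]
  small <- plaqueseg:::resize_bilinear(crop * 1, 30, 40) >= 0.5
  pasted <- paste_back(binary_mask(small, "artery"), tr)
  iou <- sum(pasted$values & orig) / sum(pasted$values | orig)
  expect_gte(iou, 0.95)
})

test_that("saliency detector boxes contain the ground-truth artery box", {
  hits <- 0L
  for (seed in 1:20) {
    g <- generate_slide(synth_params(image_size = c(96, 128),
                                     target_plaque_fraction = 0.2,
                                     seed = seed))
    prop <- propose_roi(g$slide, saliency_detector(), padding_frac = 0.05,
                        min_crop_size = c(1, 1))
    gt <- bbox_from_mask(g$artery, padding_frac = 0)$box
    contained <- prop$box$x0 <= gt$x0 && prop$box$y0 <= gt$y0 &&
      prop$box$x1 >= gt$x1 && prop$box$y1 >= gt$y1
    hits <- hits + contained
  }
  expect_equal(hits, 20L)
})
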