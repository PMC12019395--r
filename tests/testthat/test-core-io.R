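test_that("slide images round-trip losslessly through PNG and TIFF", {
  px <- array(as.integer(floor(runif(32 * 24 * 3, 0, 256))),
              dim = c(24L, 32L, 3L))
  s <- slide_image(px, slide_id = "rt")
  for (ext in c("png", "tif")) {
    path <- tempfile(fileext = paste0(".", ext))
    if (ext == "png") {
      write_slide(s, path)
    } else {
      tiff::writeTIFF(px / 255, path, bits.per.sample = 8L)
    }
    back <- read_slide(path)
    expect_identical(back$pixels, px)
  }
  # all-white identity read
  wpath <- tempfile(fileext = ".png")
  png::writePNG(array(1, dim = c(4, 4, 3)), wpath)
  expect_true(all(read_slide(wpath)$pixels == 255L))
})

test_that("lossy JPEG input is refused unless explicitly allowed", {
  path <- tempfile(fileext = ".jpg")
  file.create(path)
  expect_error(read_slide(path), "lossy")
  expect_error(read_slide(tempfile(fileext = ".png")), "not found")
})

test_that("mask codec writes 0/255 and reads any nonzero as foreground", {
  m <- binary_mask(matrix(FALSE, 8, 8), "artery")
  p <- tempfile(fileext = ".png")
  write_mask(m, p)
  expect_false(any(read_mask(p)$values))
  # checkerboard round trip
  cb <- binary_mask(outer(1:8, 1:8, function(i, j) (i + j) %% 2 == 0),
                    "artery")
  write_mask(cb, p)
  expect_identical(read_mask(p)$values, cb$values)
  # grayscale 128 counts as foreground
  png::writePNG(matrix(128 / 255, 4, 4), p)
  expect_true(all(read_mask(p)$values))
  expect_error(write_mask(cb, p, slide_shape = c(9, 9)), "shape")
})

test_that("bbox codec matches the normalised one-line format", {
  p <- tempfile(fileext = ".txt")
  write_bbox(bbox(0, 0, 100, 100), c(100, 100), p)
  expect_equal(strsplit(readLines(p), " ")[[1]],
               c("0", "0.5", "0.5", "1", "1"))
  write_bbox(bbox(25, 25, 75, 75), c(100, 100), p)
  expect_equal(as.numeric(strsplit(readLines(p), " ")[[1]][-1]),
               c(0.5, 0.5, 0.5, 0.5))
  # empty file -> no box
  writeLines(character(0), p)
  expect_null(read_bbox(p, c(100, 100)))
  writeLines("0 2 0.5 0.5 0.5", p)
  expect_error(read_bbox(p, c(100, 100)), "outside")
})

test_that("bbox round trip is within one pixel on 640x480 frames", {
  p <- tempfile(fileext = ".txt")
  worst <- 0
  for (seed in 1:100) {
    set.seed(seed)
    x0 <- sample(0:600, 1); x1 <- x0 + sample(10:(640 - x0), 1)
    y0 <- sample(0:440, 1); y1 <- y0 + sample(10:(480 - y0), 1)
    b <- bbox(x0, y0, x1, y1)
    write_bbox(b, c(480, 640), p)
    b2 <- read_bbox(p, c(480, 640))
    worst <- max(worst, abs(c(b2$x0 - x0, b2$x1 - x1, b2$y0 - y0,
                              b2$y1 - y1)))
  }
  expect_lte(worst, 1)
})

test_that("mouse-grouped splitting hits 60/20/20 and never splits a mouse", {
  rows <- data.frame(slide_id = sprintf("s%02d", 1:10),
                     path = "x", mask_artery = "x", mask_plaque = "x",
                     bbox = "x", mouse_id = sprintf("m%02d", 1:10),
                     subdataset_id = "sub1", sex = "m", genotype = "wt",
                     diet = "chow", pixel_spacing_um = 10,
                     split = NA_character_)
  sp <- split_dataset(rows, c(0.6, 0.2, 0.2), seed = 0)
  expect_equal(unname(table(sp$split)[c("train", "val", "test")]),
               c(6L, 2L, 2L), ignore_attr = TRUE)
  # deterministic
  expect_identical(sp$split, split_dataset(rows, c(0.6, 0.2, 0.2), 0)$split)
  # one mouse with several slides lands in a single split
  rows5 <- rows[rep(1:4, c(5, 1, 1, 1)), ]
  rows5$slide_id <- sprintf("s%02d", 1:8)
  sp5 <- split_dataset(rows5, c(0.6, 0.2, 0.2), seed = 1)
  expect_length(unique(sp5$split[rows5$mouse_id == "m01"]), 1L)
  # partition: every record in exactly one split
  expect_false(any(is.na(sp$split)))
  expect_error(split_dataset(rows[1:2, ], c(0.6, 0.2, 0.2), 1), "mice")
  expect_error(split_dataset(rows, c(0.5, 0.2, 0.2), 1), "sum to 1")
})

test_that("manifest CSV round-trips", {
  m <- fixture_dataset()
  p <- tempfile(fileext = ".csv")
  write_manifest(m, p)
  back <- read_manifest(p)
  expect_equal(back$slide_id, m$slide_id)
  expect_equal(back$split, m$split)
})
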