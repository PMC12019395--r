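test_that("class color voting honours exact matches and majorities", {
  pal <- data.frame(r = c(190, 225, 225), g = c(60, 185, 185),
                    b = c(70, 195, 195),
                    is_plaque = c(TRUE, FALSE, FALSE))
  # zero distance to a plaque seed wins
  expect_true(plaqueseg:::knn_vote_plaque(c(190, 60, 70), pal, 1))
  # 1 plaque + 2 identical non-plaque seeds at equal distance, k = 3:
  # the non-plaque majority wins
  mid <- (c(190, 60, 70) + c(225, 185, 195)) / 2
  expect_false(plaqueseg:::knn_vote_plaque(mid, pal, 3))
})

test_that("class voting agrees with a brute-force nearest-neighbour loop", {
  pal <- default_palette()
  for (seed in 1:50) {
    set.seed(seed)
    rgb <- runif(3, 0, 255)
    k <- 3
    d2 <- (pal$r - rgb[1])^2 + (pal$g - rgb[2])^2 + (pal$b - rgb[3])^2
    nn <- order(d2)[1:k]
    expected <- sum(pal$is_plaque[nn]) > k / 2
    expect_identical(plaqueseg:::knn_vote_plaque(rgb, pal, k), expected)
  }
})

test_that("plaque classes are selected by their mean color", {
  g <- fixture_slide(0.3, 7)
  # build a synthetic class map: class 1 = plaque GT, class 2 = rest of wall
  labels <- matrix(0L, 120, 160)
  labels[g$artery$values] <- 2L
  labels[g$plaque$values] <- 1L
  cm <- structure(list(labels = labels, k_classes = 2L, soft = NULL),
                  class = "class_map")
  # class-level semantics without the pixel pass: the plaque-colored class
  # is selected wholesale, the wall class is not
  cand <- select_plaque_classes(cm, g$slide, pixel_refine = FALSE)
  expect_identical(cand$values, g$plaque$values)
  # with the pixel pass, the candidate stays inside the class selection and
  # keeps essentially all truly red pixels
  ref <- select_plaque_classes(cm, g$slide)
  expect_true(all(cand$values[ref$values]))
  expect_gte(sum(ref$values) / sum(cand$values), 0.98)
  expect_error(
    select_plaque_classes(cm, g$slide,
                          postprocess_config(reference_palette =
                            data.frame(r = 1, g = 1, b = 1,
                                       is_plaque = TRUE))),
    "palette")
})

test_that("morphological cleaning removes specks and keeps large disks", {
  cfg3 <- postprocess_config(open_kernel_px = 3, close_kernel_px = 1)
  empty <- binary_mask(matrix(FALSE, 20, 20), "plaque")
  expect_false(any(morph_clean(empty, cfg3)$values))
  speck <- binary_mask(diag(20) == 1 & row(diag(20)) == 10, "plaque")
  expect_false(any(morph_clean(speck, cfg3)$values))
  # a disk of radius 20 survives a radius-3 opening nearly intact
  yy <- matrix(1:50, 50, 50); xx <- t(yy)
  disk <- binary_mask((yy - 25)^2 + (xx - 25)^2 <= 20^2, "plaque")
  out <- morph_clean(disk, cfg3)
  iou <- sum(out$values & disk$values) / sum(out$values | disk$values)
  expect_gte(iou, 0.9)
})

test_that("small-cluster removal respects the area threshold boundary", {
  m <- matrix(FALSE, 20, 30)
  m[2:6, 2:11] <- TRUE        # 50 px
  m[15, 1:5] <- TRUE          # 5 px
  rc <- remove_small_clusters(binary_mask(m, "plaque"), 10)
  expect_equal(rc$n_clusters, 1L)
  expect_equal(sum(rc$mask$values), 50L)
  # component exactly at the threshold is kept
  exact <- matrix(FALSE, 10, 10); exact[1:2, 1:5] <- TRUE  # 10 px
  rc2 <- remove_small_clusters(binary_mask(exact, "plaque"), 10)
  expect_equal(rc2$n_clusters, 1L)
  expect_equal(sum(rc2$mask$values), 10L)
})

test_that("cluster filtering matches the flood-fill oracle", {
  for (seed in 1:20) {
    m <- random_blob_mask(24, 24, 4, seed)
    thr <- sample(c(5, 15, 40), 1)
    rc <- remove_small_clusters(binary_mask(m, "plaque"), thr)
    lab <- floodfill_oracle(m)
    sizes <- if (max(lab) > 0) tabulate(lab[lab > 0]) else integer(0)
    expect_equal(rc$n_clusters, sum(sizes >= thr))
    keep <- matrix(lab %in% which(sizes >= thr) & lab > 0, 24, 24)
    expect_identical(rc$mask$values, keep)
  }
})

test_that("finalisation computes fractions, areas and the empty rule", {
  artery <- binary_mask(matrix(c(rep(TRUE, 100), rep(FALSE, 100)), 10, 20),
                        "artery")
  slide <- slide_image(array(128L, dim = c(10, 20, 3)),
                       pixel_spacing_um = 10)
  cfg <- postprocess_config(open_kernel_px = 1, close_kernel_px = 1,
                            min_cluster_px = 0)
  # 25 plaque px in a solid block survive cleaning
  cand <- matrix(FALSE, 10, 20); cand[2:6, 2:6] <- TRUE
  res <- finalize_plaque(binary_mask(cand, "plaque"), artery, slide, cfg)
  expect_equal(res$plaque_px, 25L)
  expect_equal(res$plaque_fraction, 0.25)
  expect_equal(res$plaque_area_mm2, 25 * (10 / 1000)^2)
  expect_false(res$is_empty)
  # candidate equal to the artery: degenerate full fraction
  full <- finalize_plaque(artery, artery, slide, cfg)
  expect_equal(full$plaque_fraction, 1)
  # empty candidate: declared empty with zero area
  none <- finalize_plaque(binary_mask(matrix(FALSE, 10, 20), "plaque"),
                          artery, slide, cfg)
  expect_true(none$is_empty)
  expect_equal(none$plaque_area_mm2, 0)
  # plaque mask is always inside the artery
  spill <- matrix(TRUE, 10, 20)
  res2 <- finalize_plaque(binary_mask(spill, "plaque"), artery, slide, cfg)
  expect_true(all(artery$values[res2$plaque_mask$values]))
  expect_error(finalize_plaque(binary_mask(cand, "plaque"),
                               binary_mask(matrix(FALSE, 10, 20), "artery"),
                               slide, cfg), "skip")
})
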