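test_that("segmentation metrics reproduce hand-computed values", {
  gt <- matrix(FALSE, 4, 4)
  gt[1:2, 1:4] <- TRUE  # 8 positives
  perfect <- seg_metrics(gt, gt)
  expect_equal(perfect$miou, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  # tp = 6, fp = 2, fn = 2 construction
  pred <- matrix(FALSE, 4, 4)
  pred[1:2, 1:3] <- TRUE    # 6 tp over gt's first three columns
  pred[3:4, 1] <- TRUE      # 2 fp
  m <- seg_metrics(pred, gt)
  expect_equal(c(m$tp, m$fp, m$fn), c(6L, 2L, 2L))
  expect_equal(m$miou, 0.6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  # empty prediction with nonempty truth
  expect_warning(e <- seg_metrics(matrix(FALSE, 4, 4), gt), "precision")
  expect_equal(e$miou, 0)
  expect_equal(e$recall, 0)
  # both empty: a perfect prediction of a plaque-free slide
  b <- suppressWarnings(seg_metrics(matrix(FALSE, 2, 2),
                                    matrix(FALSE, 2, 2)))
  expect_equal(b$miou, 1)
  expect_error(seg_metrics(matrix(FALSE, 2, 2), gt), "shape")
  expect_equal(m$tp + m$fp + m$fn + m$tn, 16L)
})

test_that("quality bins use the exact boundary conventions", {
  expect_equal(quality_bin(0.5), "low")
  expect_equal(quality_bin(0.7), "medium")
  expect_equal(quality_bin(0.71), "high")
  expect_equal(quality_bin(0), "low")
  expect_equal(quality_bin(1), "high")
  expect_error(quality_bin(1.2), "0, 1")
})

test_that("method summaries aggregate means, sds and bin percentages", {
  mk <- function(miou) {
    structure(list(tp = 1, fp = 0, fn = 0, tn = 0, miou = miou,
                   precision = 0.9, recall = 0.8,
                   quality = quality_bin(miou)), class = "seg_metrics")
  }
  same <- summarize_method(list(mk(0.8), mk(0.8), mk(0.8)))
  expect_equal(same$miou_sd, 0)
  two <- summarize_method(list(mk(0.4), mk(0.8)))
  expect_equal(c(two$pct_low, two$pct_medium, two$pct_high), c(50, 0, 50))
  set.seed(2)
  vals <- runif(100)
  many <- summarize_method(lapply(vals, mk))
  expect_equal(many$miou_mean, mean(vals), tolerance = 1e-12)
  expect_equal(many$miou_sd, sd(vals), tolerance = 1e-12)
  expect_equal(many$pct_low + many$pct_medium + many$pct_high, 100)
  expect_error(summarize_method(list()), "empty")
})

test_that("per-mouse aggregation takes medians with the midpoint rule", {
  mk <- function(mouse, area) {
    structure(list(mouse_id = mouse, plaque_area_mm2 = area),
              class = "plaque_result")
  }
  meta <- data.frame(mouse_id = c("m1", "m2"), sex = c("m", "f"),
                     genotype = c("ko", "wt"), diet = c("wtd", "chow"))
  res <- list(mk("m1", 1), mk("m1", 2), mk("m1", 3),
              mk("m2", 1), mk("m2", 2), mk("m2", 3), mk("m2", 4))
  agg <- per_mouse_aggregate(res, meta)
  expect_equal(agg$median_area_mm2[agg$mouse_id == "m1"], 2)
  expect_equal(agg$median_area_mm2[agg$mouse_id == "m2"], 2.5)
  # permutation invariance
  agg2 <- per_mouse_aggregate(res[sample(7)], meta)
  expect_equal(agg, agg2)
  bad <- rbind(meta, data.frame(mouse_id = "m1", sex = "f", genotype = "ko",
                                diet = "wtd"))
  expect_error(per_mouse_aggregate(res, bad), "inconsistent")
})

test_that("correlation and regression match closed forms", {
  ref <- c(1, 2, 3, 4, 5)
  same <- compare_to_reference(ref, ref)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$slope, 1)
  expect_equal(same$intercept, 0)
  dbl <- compare_to_reference(2 * ref, ref)
  expect_equal(dbl$pearson_r, 1)
  expect_equal(dbl$slope, 2)
  for (seed in 1:20) {
    set.seed(seed)
    x <- rnorm(10); y <- 0.5 * x + rnorm(10)
    cc <- compare_to_reference(y, x)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    sxx <- sum((x - mean(x))^2)
    syy <- sum((y - mean(y))^2)
    expect_equal(cc$pearson_r, sxy / sqrt(sxx * syy), tolerance = 1e-10)
    expect_equal(cc$slope, sxy / sxx, tolerance = 1e-10)
    expect_equal(cc$intercept, mean(y) - cc$slope * mean(x),
                 tolerance = 1e-10)
  }
  expect_error(compare_to_reference(1:2, 1:2), "3")
  expect_error(compare_to_reference(c(1, 1, 1), 1:3), "variance")
})

test_that("group comparisons run pooled-variance t-tests per pair", {
  rec <- data.frame(mouse_id = sprintf("m%d", 1:8),
                    sex = rep(c("m", "f"), each = 4),
                    genotype = "ko", diet = "wtd",
                    median_area_mm2 = c(1, 2, 3, 4, 1, 2, 3, 4))
  tab <- group_compare(rec, grouping = "sex")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$t, 0)
  expect_equal(tab$p_value, 1)
  # fully separated constant groups
  rec2 <- rec
  rec2$median_area_mm2 <- rep(c(0, 1), each = 4)
  tab2 <- group_compare(rec2, grouping = "sex")
  expect_lt(tab2$p_value, 0.01)
  # closed-form pooled-variance oracle
  for (seed in 1:20) {
    set.seed(seed)
    a <- rnorm(5); b <- rnorm(6, mean = 0.5)
    rec3 <- data.frame(mouse_id = sprintf("m%d", 1:11),
                       sex = rep(c("m", "f"), c(5, 6)), genotype = "ko",
                       diet = "wtd", median_area_mm2 = c(a, b))
    tab3 <- group_compare(rec3, grouping = "sex")
    sp2 <- ((5 - 1) * var(a) + (6 - 1) * var(b)) / (5 + 6 - 2)
    tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 6))
    pval <- 2 * pt(-abs(tstat), df = 9)
    expect_equal(abs(tab3$t), abs(tstat), tolerance = 1e-10)
    expect_equal(tab3$p_value, pval, tolerance = 1e-10)
  }
  # undersized groups are skipped with a warning
  rec4 <- rec[c(1, 5:8), ]
  expect_warning(out <- group_compare(rec4, grouping = "sex"), "fewer")
  expect_equal(nrow(out), 0L)
})
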