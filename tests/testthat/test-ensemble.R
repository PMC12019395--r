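make_stack <- function(n, h = 16, w = 16, seed = 1, fp = 0.2, fn = 0.2) {
  gt <- binary_mask(random_blob_mask(h, w, 3, seed), "artery")
  generate_mask_stack(gt, n, flip_fp = fp, flip_fn = fn, seed = seed + 100)
}

test_that("alpha-overlap voting obeys the agreement boundary exactly", {
  # construct one pixel with 6 of 10 members true
  members <- lapply(1:10, function(i) {
    binary_mask(matrix(i <= 6, 1, 1), "artery")
  })
  st <- mask_stack(members)
  expect_true(combine_overlap(st, overlap_config(alpha = 6))$values[1, 1])
  expect_false(combine_overlap(st, overlap_config(alpha = 7))$values[1, 1])
})

test_that("alpha extremes give the union and the intersection", {
  st <- make_stack(10, seed = 3)
  uni <- Reduce(`|`, lapply(st$members, `[[`, "values"))
  int <- Reduce(`&`, lapply(st$members, `[[`, "values"))
  expect_identical(combine_overlap(st, overlap_config(1))$values, uni)
  expect_identical(combine_overlap(st, overlap_config(10))$values, int)
  expect_error(combine_overlap(st, overlap_config(11)), "exceeds")
})

test_that("overlap combination equals the per-pixel counting oracle", {
  for (seed in 1:20) {
    st <- make_stack(10, seed = seed)
    alpha <- sample(1:10, 1)
    expect_identical(combine_overlap(st, overlap_config(alpha))$values,
                     overlap_oracle(st, alpha))
  }
})

test_that("overlap is invariant to member order", {
  st <- make_stack(8, seed = 5)
  perm <- mask_stack(st$members[sample(8)])
  expect_identical(combine_overlap(st, overlap_config(4))$values,
                   combine_overlap(perm, overlap_config(4))$values)
})

test_that("logit averaging happens before the output function", {
  mk <- function(v) prob_map(matrix(v, 2, 2), "logit")
  st <- mask_stack(list(mk(3), mk(3), mk(3)))
  expect_true(all(combine_average(st)$values))
  # +2 and -2 average to logit 0 = probability 0.5: tie resolves foreground
  st2 <- mask_stack(list(mk(2), mk(-2)))
  expect_true(all(combine_average(st2)$values))
  # probability members are rejected unless explicitly allowed
  stp <- mask_stack(list(prob_map(matrix(0.9, 2, 2), "probability")))
  expect_error(combine_average(stp), "logit")
  expect_true(all(combine_average(stp, allow_probabilities = TRUE)$values))
})

test_that("averaging hard members equals majority voting with ties true", {
  # exhaustive over all per-pixel member patterns for n <= 4, using large
  # +/-L logits as hard surrogates
  L <- 50
  for (n in 1:4) {
    patterns <- expand.grid(rep(list(c(FALSE, TRUE)), n))
    maj <- ceiling(n / 2)
    for (r in seq_len(nrow(patterns))) {
      bits <- as.logical(patterns[r, ])
      st <- mask_stack(lapply(bits, function(b) {
        prob_map(matrix(if (b) L else -L, 1, 1), "logit")
      }))
      avg <- combine_average(st)$values[1, 1]
      vote <- sum(bits) >= maj  # ties (even n, half true) resolve true:
                                # mean logit 0 -> probability 0.5 -> true
      if (2 * sum(bits) == n) vote <- TRUE
      expect_identical(avg, vote)
    }
  }
})

test_that("predicted area, FP and FN are monotone in alpha", {
  gt <- binary_mask(random_blob_mask(24, 24, 3, seed = 11), "artery")
  st <- generate_mask_stack(gt, 10, flip_fp = 0.1, flip_fn = 0.1, seed = 4)
  area <- fp <- fn <- numeric(10)
  prev <- NULL
  for (a in 1:10) {
    out <- combine_overlap(st, overlap_config(a))
    area[a] <- sum(out$values)
    fp[a] <- sum(out$values & !gt$values)
    fn[a] <- sum(!out$values & gt$values)
    if (!is.null(prev)) {
      # nesting: higher alpha output is a subset of lower alpha output
      expect_true(all(prev$values[out$values]))
    }
    prev <- out
  }
  expect_true(all(diff(area) <= 0))
  expect_true(all(diff(fp) <= 0))
  expect_true(all(diff(fn) >= 0))
})

test_that("consensus map counts agreements and induces all thresholds", {
  st <- make_stack(6, seed = 9)
  cm <- consensus_map(st)
  expect_true(all(cm >= 0 & cm <= 6))
  for (a in 1:6) {
    expect_identical(combine_overlap(st, overlap_config(a))$values, cm >= a)
  }
  # unanimous and empty cases
  ones <- mask_stack(lapply(1:4, function(i)
    binary_mask(matrix(TRUE, 2, 2), "artery")))
  expect_true(all(consensus_map(ones) == 4L))
  zeros <- mask_stack(lapply(1:4, function(i)
    binary_mask(matrix(FALSE, 2, 2), "artery")))
  expect_true(all(consensus_map(zeros) == 0L))
})

test_that("the combined ROI ensemble mixes members and can overrule a
           faulty box", {
  gt <- random_blob_mask(16, 16, 2, seed = 21)
  full <- mask_stack(lapply(1:5, function(i)
    binary_mask(gt, "artery")))
  empty <- mask_stack(lapply(1:5, function(i)
    binary_mask(matrix(FALSE, 16, 16), "artery")))
  # identical stacks: combining is idempotent
  same <- combine_roi_ensemble(full, full, "overlap",
                               overlap_config(alpha = 6), k = 5,
                               selection = "last")
  expect_identical(same$values, gt)
  # a failed-box ROI stack (all empty) is outvoted at alpha = 4
  over <- combine_roi_ensemble(full, empty, "overlap",
                               overlap_config(alpha = 4), k = 5,
                               selection = "last")
  expect_identical(over$values, gt)
  # and wins at alpha = 6 (needs agreement beyond one source)
  lost <- combine_roi_ensemble(full, empty, "overlap",
                               overlap_config(alpha = 6), k = 5,
                               selection = "last")
  expect_false(any(lost$values))
  expect_error(combine_roi_ensemble(full, empty, "overlap",
                                    overlap_config(4), k = 9), "exceeds")
})

test_that("best-k member selection uses validation scores", {
  masks <- lapply(1:4, function(i)
    binary_mask(matrix(i >= 3, 1, 1), "artery"))
  st <- mask_stack(masks)
  # best two by score are members 3 and 4 (both true)
  out <- combine_roi_ensemble(st, st, "overlap", overlap_config(alpha = 4),
                              k = 2, selection = "best",
                              val_scores = list(full = c(0.1, 0.2, 0.9, 0.8),
                                                roi = c(0.1, 0.2, 0.9, 0.8)))
  expect_true(out$values[1, 1])
})
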