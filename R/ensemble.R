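# Mask-combination strategies for ensembles.
#
# Two strategies are provided. Averaging: the per-pixel arithmetic mean of
# the members' logit maps is passed through the sigmoid and thresholded.
# Alpha-overlap: an adaptation of majority voting in which a pixel is
# foreground iff at least alpha of the n member masks agree; alpha tunes the
# trade-off between false positives (shrinking with alpha) and false
# negatives (growing with alpha). Both are implemented by summing the
# stacked members and thresholding, so they run in one vectorised pass.

#' Overlap (alpha-of-n voting) configuration
#'
#' @param alpha required number of agreeing members (`1 <= alpha <= n`).
#' @param binarize_threshold probability threshold used when members need
#'   binarising first.
#' @return an object of class `overlap_config`.
#' @export
overlap_config <- function(alpha = 6L, binarize_threshold = 0.5) {
  if (alpha < 1L) stop("alpha must be at least 1")
  structure(list(alpha = as.integer(alpha),
                 binarize_threshold = binarize_threshold),
            class = "overlap_config")
}

#' Combine a stack of binary masks by alpha-overlap voting
#'
#' A pixel is foreground iff at least `alpha` of the `n` members mark it.
#' `alpha = 1` gives the union of the members, `alpha = n` their
#' intersection.
#'
#' @param stack a [mask_stack] of binary masks.
#' @param cfg an [overlap_config] (or a bare integer alpha).
#' @return a [binary_mask].
#' @export
combine_overlap <- function(stack, cfg) {
  if (!inherits(cfg, "overlap_config")) cfg <- overlap_config(cfg)
  if (!stack_is_binary(stack)) stop("combine_overlap needs binary members")
  n <- length(stack)
  if (cfg$alpha > n) stop("alpha (", cfg$alpha, ") exceeds stack size (", n,
                          ")")
  counts <- consensus_map(stack)
  m1 <- stack$members[[1L]]
  binary_mask(counts >= cfg$alpha, role = m1$role, slide_id = m1$slide_id)
}

#' Combine a stack of logit maps by averaging before the output function
#'
#' Per-pixel arithmetic mean of the members' logits, sigmoid, then threshold.
#' Pixels exactly at the threshold count as foreground (the tie must go
#' somewhere; foreground is the documented fixed choice).
#'
#' @param stack a [mask_stack] of [prob_map]s in logit state.
#' @param binarize_threshold probability threshold (default 0.5).
#' @param allow_probabilities accept probability-state members and average
#'   on the probability scale instead (off by default; averaging before the
#'   activation is the reference behaviour).
#' @return a [binary_mask].
#' @export
combine_average <- function(stack, binarize_threshold = 0.5,
                            allow_probabilities = FALSE) {
  states <- vapply(stack$members, function(m) {
    if (!inherits(m, "prob_map")) "other" else m$activation_state
  }, character(1))
  if (!allow_probabilities && any(states != "logit")) {
    stop("combine_average expects logit-state members; set ",
         "allow_probabilities = TRUE to average probabilities")
  }
  arr <- stack_array(stack)
  d <- dim(arr)
  avg <- matrix(apply(arr, c(1L, 2L), mean), d[1L], d[2L])
  prob <- if (all(states == "logit")) sigmoid(avg) else avg
  binary_mask(prob >= binarize_threshold, role = "artery",
              slide_id = "combined")
}

#' Combine full-frame and ROI ensembles into one mixed ensemble
#'
#' Takes `k` members from each source (default half of each), concatenates
#' them into one `2k`-member stack, and applies the chosen strategy (with
#' `alpha` counted against `n = 2k`). Because half the members never saw the
#' bounding box, they can overrule false positives or false negatives that a
#' faulty box induces in the ROI half, and vice versa.
#'
#' @param full_stack,roi_stack [mask_stack]s at full-frame resolution (ROI
#'   members already pasted back).
#' @param strategy `"overlap"` or `"average"`.
#' @param cfg an [overlap_config] (overlap) or threshold options (average).
#' @param k members taken from each stack (default half of each stack,
#'   i.e. 5 of 10 for the default ensembles).
#' @param selection `"best"` (highest validation score first, requires
#'   `val_scores`), `"last"`, or explicit member indices.
#' @param val_scores optional list with per-stack validation scores used by
#'   `selection = "best"`.
#' @return a [binary_mask].
#' @export
combine_roi_ensemble <- function(full_stack, roi_stack,
                                 strategy = c("overlap", "average"),
                                 cfg = overlap_config(), k = NULL,
                                 selection = "best", val_scores = NULL) {
  strategy <- match.arg(strategy)
  d1 <- dim(full_stack$members[[1L]]$values)
  d2 <- dim(roi_stack$members[[1L]]$values)
  if (!all(d1 == d2)) stop("stacks must be aligned at full-frame resolution")
  pick <- function(stack, scores, k) {
    n <- length(stack)
    if (k > n) stop("k (", k, ") exceeds stack size (", n, ")")
    idx <- if (is.numeric(selection)) {
      selection
    } else if (identical(selection, "best") && !is.null(scores)) {
      order(scores, decreasing = TRUE)[seq_len(k)]
    } else {
      seq.int(n - k + 1L, n)  # last-k
    }
    stack$members[idx]
  }
  k_full <- k %||% (length(full_stack) %/% 2L)
  k_roi <- k %||% (length(roi_stack) %/% 2L)
  members <- c(pick(full_stack, val_scores$full, k_full),
               pick(roi_stack, val_scores$roi, k_roi))
  mixed <- mask_stack(members,
                      source_tags = c(rep("full", k_full),
                                      rep("roi", k_roi)))
  if (strategy == "overlap") {
    combine_overlap(mixed, cfg)
  } else {
    combine_average(mixed)
  }
}

#' Per-pixel consensus count of a binary mask stack
#'
#' Counts, for each pixel, how many members mark it foreground; the map
#' doubles as an uncertainty visualisation (full agreement at `0` or `n`,
#' maximal disagreement in between). `combine_overlap(stack, alpha)` equals
#' `consensus_map(stack) >= alpha`.
#'
#' @param stack a [mask_stack] of binary masks.
#' @return an integer matrix with values in `[0, n]`.
#' @export
consensus_map <- function(stack) {
  if (length(stack) < 1L) stop("empty stack")
  if (!stack_is_binary(stack)) stop("consensus_map needs binary members")
  arr <- stack_array(stack)
  d <- dim(arr)
  counts <- matrix(0L, d[1L], d[2L])
  for (i in seq_len(d[3L])) {
    counts <- counts + matrix(as.integer(arr[, , i]), d[1L], d[2L])
  }
  counts
}

#' Write a consensus map as an 8-bit grayscale PNG scaled to [0, 255]
#'
#' @param counts integer consensus matrix.
#' @param n stack size the counts were computed from.
#' @param path output PNG path.
#' @export
write_consensus_png <- function(counts, n, path) {
  png::writePNG(counts / n, path)
  invisible(path)
}
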