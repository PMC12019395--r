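# Stage 2: supervised artery segmentation.
#
# Networks are trained under a combined region + distribution loss: soft
# Jaccard, soft Tversky (alpha = 0.3 penalising false positives, beta = 0.7
# penalising false negatives) and binary cross-entropy, summed with equal
# weights. Two training regimes are provided: a standard run (Adam, early
# stopping on validation mIoU) and a snapshot-ensemble run (SGD with
# momentum 0.9 under a triangular cyclic learning rate, one weight snapshot
# harvested at the end of each cycle where the rate returns to its minimum).

#' Segmentation model configuration
#'
#' @param architecture one of `"unetpp"`, `"unet"`, `"fpn"`, `"pan"`.
#' @param base_channels width of the first encoder level.
#' @param input_size `(h, w)` the network operates at (4:3, both divisible
#'   by 4); slides are resized to it and logits resized back.
#' @param learning_rate Adam learning rate for standard training.
#' @param loss_weights weights of the Jaccard, Tversky and BCE terms.
#' @param tversky_alpha,tversky_beta Tversky false-positive / false-negative
#'   penalties (defaults 0.3 / 0.7).
#' @param augmentation `"none"`, `"basic"` (horizontal & vertical flips,
#'   rotations) or `"advanced"` (adds color jittering and deformations).
#' @param epochs,batch_size,early_stop_patience training schedule.
#' @param seed integer seed for initialisation and batch order.
#' @return an object of class `seg_model_config`.
#' @export
seg_model_config <- function(architecture = "unetpp", base_channels = 8L,
                             input_size = c(480L, 640L),
                             learning_rate = 1e-4,
                             loss_weights = c(1, 1, 1),
                             tversky_alpha = 0.3, tversky_beta = 0.7,
                             augmentation = c("none", "basic", "advanced"),
                             epochs = 100L, batch_size = 16L,
                             early_stop_patience = 10L, seed = 1L) {
  augmentation <- match.arg(augmentation)
  input_size <- as.integer(input_size)
  if (any(input_size %% 4L != 0L)) {
    stop("input_size dimensions must be divisible by 4")
  }
  structure(list(architecture = architecture,
                 base_channels = as.integer(base_channels),
                 input_size = input_size, learning_rate = learning_rate,
                 loss_weights = loss_weights, tversky_alpha = tversky_alpha,
                 tversky_beta = tversky_beta, augmentation = augmentation,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "seg_model_config")
}

#' Cyclic learning-rate configuration for snapshot ensembles
#'
#' Triangular schedule: the rate rises linearly from `base_lr` to `max_lr`
#' over `step_size` optimiser steps and falls back over the next
#' `step_size`, so one cycle spans `2 * step_size` steps. With the default
#' step size of five epochs' worth of batches, a cycle is ten epochs and a
#' 100-epoch run yields ten snapshots.
#'
#' @param base_lr minimum learning rate (default `1e-4`).
#' @param max_lr maximum learning rate (default `1e-1`, a factor `1e3` up).
#' @param step_size steps per half-cycle; `NULL` means 5 x batches/epoch,
#'   resolved when training starts.
#' @param momentum SGD momentum (default 0.9).
#' @return an object of class `cyclic_lr_config`.
#' @export
cyclic_lr_config <- function(base_lr = 1e-4, max_lr = 1e-1,
                             step_size = NULL, momentum = 0.9) {
  if (!is.null(step_size) && step_size < 1) stop("step_size must be >= 1")
  structure(list(base_lr = base_lr, max_lr = max_lr, step_size = step_size,
                 momentum = momentum), class = "cyclic_lr_config")
}

#' Triangular cyclic learning-rate value at a given optimiser step
#'
#' @param step 0-based optimiser step.
#' @param cfg a [cyclic_lr_config] with a resolved `step_size`.
#' @return the learning rate; periodic with period `2 * step_size`, bounded
#'   in `[base_lr, max_lr]`, equal to `base_lr` at step 0 and to `max_lr` at
#'   `step_size`.
#' @export
cyclic_lr_value <- function(step, cfg) {
  if (is.null(cfg$step_size)) stop("step_size not resolved")
  s <- cfg$step_size
  phase <- step %% (2 * s)
  frac <- ifelse(phase <= s, phase / s, (2 * s - phase) / s)
  cfg$base_lr + (cfg$max_lr - cfg$base_lr) * frac
}

# ---- loss -----------------------------------------------------------------

# Value and gradient of the combined loss w.r.t. logits z; g is the 0/1
# target. Soft (real-valued) Jaccard and Tversky with eps-stabilised
# denominators; mean BCE with probability clipping.
.combined_loss_grad <- function(z, g, weights = c(1, 1, 1), alpha = 0.3,
                                beta = 0.7, eps = 1e-7) {
  p <- sigmoid(z)
  n <- length(p)
  spg <- sum(p * g)
  sp <- sum(p)
  sg <- sum(g)
  dj <- sp + sg - spg + eps
  lj <- 1 - (spg + eps) / dj
  a_fp <- sum(p * (1 - g))
  b_fn <- sum((1 - p) * g)
  dt <- spg + alpha * a_fp + beta * b_fn + eps
  lt <- 1 - (spg + eps) / dt
  pc <- pmin(pmax(p, eps), 1 - eps)
  lb <- -mean(g * log(pc) + (1 - g) * log(1 - pc))
  # gradients w.r.t. p
  gj <- -(g * dj - (spg + eps) * (1 - g)) / dj^2
  gt_ <- -(g * dt - (spg + eps) * (g + alpha * (1 - g) - beta * g)) / dt^2
  dLdp <- weights[1L] * gj + weights[2L] * gt_
  dz <- dLdp * p * (1 - p) + weights[3L] * (p - g) / n
  list(value = weights[1L] * lj + weights[2L] * lt + weights[3L] * lb,
       dx = array(dz, dim = dim(z)))
}

#' Combined Jaccard + Tversky + BCE segmentation loss
#'
#' `w_j * (1 - soft Jaccard) + w_t * (1 - soft Tversky(alpha, beta)) +
#' w_bce * BCE`, computed over all pixels. With `alpha = beta = 0.5` the
#' Tversky term reduces to Dice loss, with `alpha = beta = 1` to Jaccard
#' loss.
#'
#' @param pred predicted probabilities: a [prob_map] in probability state or
#'   a numeric array in `[0, 1]`.
#' @param target a [binary_mask] or logical array of the same shape.
#' @param weights length-3 weights `(w_jaccard, w_tversky, w_bce)`.
#' @param tversky_alpha,tversky_beta Tversky penalties.
#' @param eps stabiliser for denominators and BCE clipping.
#' @return a single nonnegative number; 0 (up to the BCE clipping floor) iff
#'   the prediction matches the target exactly.
#' @export
combined_loss <- function(pred, target, weights = c(1, 1, 1),
                          tversky_alpha = 0.3, tversky_beta = 0.7,
                          eps = 1e-7) {
  p <- if (inherits(pred, "prob_map")) {
    if (pred$activation_state != "probability") {
      stop("combined_loss expects probabilities; apply sigmoid first")
    }
    pred$values
  } else pred
  g <- if (inherits(target, "binary_mask")) target$values else target
  if (!all(dim(p) == dim(g))) stop("prediction/target shape mismatch")
  if (length(p) == 0L) stop("empty image")
  if (min(p) < 0 || max(p) > 1) stop("predictions must lie in [0, 1]")
  # evaluate via the gradient helper on the logit scale equivalent
  pc <- pmin(pmax(p, eps), 1 - eps)
  z <- log(pc / (1 - pc))
  .combined_loss_grad(z, g * 1, weights, tversky_alpha, tversky_beta,
                      eps)$value
}

# ---- data loading ---------------------------------------------------------

# Materialise manifest records as network-ready samples: x in [0,1] at
# input_size, y the 0/1 artery mask at the same size. With use_roi the slide
# is cropped first (bbox file when present, else the tight GT-mask box).
load_seg_samples <- function(manifest, cfg, use_roi = FALSE,
                             min_crop_size = c(1L, 1L)) {
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    slide <- read_slide(row$path, row)
    mask <- read_mask(row$mask_artery, "artery", row$slide_id)
    if (use_roi) {
      prop <- if (!is.na(row$bbox) && nzchar(row$bbox) &&
                  file.exists(row$bbox)) {
        b <- read_bbox(row$bbox, dim(slide$pixels)[1:2])
        if (is.null(b)) roi_fallback_full(dim(slide$pixels)[1:2]) else
          structure(list(box = pad_clip_box(b, dim(slide$pixels)[1:2], 0.05),
                         source = "detector", confidence = NA_real_),
                    class = "roi_proposal")
      } else {
        bbox_from_mask(mask, padding_frac = 0.05)
      }
      if (bbox_height(prop$box) < min_crop_size[1L] ||
          bbox_width(prop$box) < min_crop_size[2L]) {
        prop <- roi_fallback_full(dim(slide$pixels)[1:2])
      }
      cr <- crop_to_roi(slide, prop)
      slide <- cr$slide
      b <- prop$box
      mask <- binary_mask(mask$values[(b$y0 + 1L):b$y1, (b$x0 + 1L):b$x1,
                                      drop = FALSE],
                          role = mask$role, slide_id = mask$slide_id)
    }
    x <- resize_bilinear(slide$pixels / 255, cfg$input_size[1L],
                         cfg$input_size[2L])
    y <- resize_bilinear(mask$values * 1, cfg$input_size[1L],
                         cfg$input_size[2L]) >= 0.5
    list(x = x, y = y * 1, slide_id = row$slide_id)
  })
}

augment_sample <- function(s, level) {
  if (level == "none") return(s)
  x <- s$x; y <- s$y
  if (stats::runif(1) < 0.5) {  # horizontal flip
    x <- x[, rev(seq_len(ncol(y))), , drop = FALSE]
    y <- y[, rev(seq_len(ncol(y)))]
  }
  if (stats::runif(1) < 0.5) {  # vertical flip
    x <- x[rev(seq_len(nrow(y))), , , drop = FALSE]
    y <- y[rev(seq_len(nrow(y))), ]
  }
  if (stats::runif(1) < 0.5) {  # 180-degree rotation (preserves aspect)
    x <- x[rev(seq_len(nrow(y))), rev(seq_len(ncol(y))), , drop = FALSE]
    y <- y[rev(seq_len(nrow(y))), rev(seq_len(ncol(y)))]
  }
  if (level == "advanced") {
    if (stats::runif(1) < 0.5) {  # color jitter
      sc <- stats::runif(3, 0.9, 1.1)
      sh <- stats::runif(3, -0.05, 0.05)
      for (c in 1:3) x[, , c] <- pmin(pmax(x[, , c] * sc[c] + sh[c], 0), 1)
    }
    if (stats::runif(1) < 0.5) {  # small translation (deformation proxy)
      dh <- sample(-3:3, 1); dw <- sample(-3:3, 1)
      shift <- function(m, dh, dw) {
        H <- nrow(m); W <- ncol(m)
        ri <- pmin(pmax(seq_len(H) - dh, 1L), H)
        ci <- pmin(pmax(seq_len(W) - dw, 1L), W)
        m[ri, ci]
      }
      for (c in 1:3) x[, , c] <- shift(x[, , c], dh, dw)
      y <- shift(y, dh, dw)
    }
  }
  list(x = x, y = y, slide_id = s$slide_id)
}

miou_binary <- function(pred, gt) {
  tp <- sum(pred & gt)
  fp <- sum(pred & !gt)
  fn <- sum(!pred & gt)
  if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
}

val_miou <- function(net, params, samples) {
  if (length(samples) == 0L) return(NA_real_)
  mean(vapply(samples, function(s) {
    z <- nn_forward_value(net, params, s$x)
    miou_binary(sigmoid(z[, , 1L]) >= 0.5, s$y > 0.5)
  }, numeric(1)))
}

batch_grads <- function(net, params, samples, idx, cfg) {
  total <- NULL
  loss <- 0
  for (j in idx) {
    s <- augment_sample(samples[[j]], cfg$augmentation)
    lf <- function(z) .combined_loss_grad(z, array(s$y, dim = c(dim(s$y), 1L)),
                                          cfg$loss_weights, cfg$tversky_alpha,
                                          cfg$tversky_beta)
    r <- nn_loss_and_grads(net, params, s$x, lf)
    loss <- loss + r$loss
    if (is.null(total)) {
      total <- r$grads
    } else {
      for (nm in names(total)) total[[nm]] <- total[[nm]] + r$grads[[nm]]
    }
  }
  for (nm in names(total)) total[[nm]] <- total[[nm]] / length(idx)
  list(grads = total, loss = loss / length(idx))
}

# ---- training -------------------------------------------------------------

#' Train a single artery segmentation network
#'
#' Adam optimisation of the combined loss with early stopping on validation
#' mIoU: training halts when the validation score has not improved for
#' `early_stop_patience` epochs, and the best-validation weights are
#' returned.
#'
#' @param manifest dataset manifest with nonempty `train` and `val` splits.
#' @param cfg a [seg_model_config].
#' @param use_roi crop each slide to its arterial ROI before resizing
#'   (bounding-box file when present, else the tight ground-truth-mask box).
#' @param verbose print per-epoch progress.
#' @return an object of class `artery_model` with elements `net`, `params`,
#'   `cfg`, `history` (epoch, lr, train_loss, val_miou) and `best_val`.
#' @export
train_segmenter <- function(manifest, cfg = seg_model_config(),
                            use_roi = FALSE, verbose = FALSE) {
  train <- manifest[manifest$split == "train", ]
  val <- manifest[manifest$split == "val", ]
  if (nrow(train) == 0L) stop("empty train split")
  if (nrow(val) == 0L) stop("empty val split")
  tr_samples <- load_seg_samples(train, cfg, use_roi,
                                 min_crop_size = cfg$input_size)
  va_samples <- load_seg_samples(val, cfg, use_roi,
                                 min_crop_size = cfg$input_size)
  net <- build_segnet(cfg$architecture, 3L, 1L, cfg$base_channels,
                      seed = cfg$seed)
  params <- net$params
  opt <- optim_adam(params, lr = cfg$learning_rate)
  best <- list(params = params, val = -Inf, epoch = 0L)
  history <- NULL
  local_seed(derive_seed(cfg$seed, 1L), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(length(tr_samples))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      eloss <- 0
      for (b in batches) {
        r <- batch_grads(net, params, tr_samples, b, cfg)
        st <- optim_step(opt, params, r$grads)
        opt <- st$opt; params <- st$params
        eloss <- eloss + r$loss * length(b)
      }
      eloss <- eloss / length(tr_samples)
      vm <- val_miou(net, params, va_samples)
      history <- rbind(history,
                       data.frame(epoch = epoch, lr = cfg$learning_rate,
                                  train_loss = eloss, val_miou = vm))
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f, val mIoU %.4f", epoch, eloss,
                        vm))
      }
      if (vm > best$val) best <- list(params = params, val = vm,
                                      epoch = epoch)
      if (epoch - best$epoch >= cfg$early_stop_patience) break
    }
  })
  structure(list(net = net, params = best$params, cfg = cfg,
                 history = history, best_val = best$val, use_roi = use_roi),
            class = "artery_model")
}

#' @export
print.artery_model <- function(x, ...) {
  cat(sprintf(
    "<artery_model %s (%d base ch), %d epochs trained, best val mIoU %.3f>\n",
    x$cfg$architecture, x$cfg$base_channels, nrow(x$history), x$best_val))
  invisible(x)
}

#' Train a snapshot ensemble with a cyclic learning rate
#'
#' One SGD-with-momentum run under the triangular schedule of
#' [cyclic_lr_value]; the weight state is captured at the end of every
#' cycle, where the learning rate returns to its minimum and the network
#' sits in a converged local optimum. No early stopping is applied (cycles
#' must complete). `epochs` must be a multiple of the cycle length; the
#' default 100-epoch / 10-epoch-cycle schedule yields ten snapshots.
#'
#' @param manifest dataset manifest with `train` and `val` splits.
#' @param cfg a [seg_model_config].
#' @param lr_cfg a [cyclic_lr_config]; a `NULL` step size resolves to
#'   5 x batches-per-epoch.
#' @param use_roi crop slides to their arterial ROI (see [train_segmenter]).
#' @param clip_norm clip the global gradient norm to this value before each
#'   SGD step (default 1); the high-learning-rate phase of each cycle is
#'   meant to relocate the weights, not blow them up.
#' @param verbose print per-epoch progress.
#' @return an object of class `snapshot_set`: `snapshots` (list of weight
#'   states), `val_scores`, `net`, `cfg`, `history`.
#' @export
train_snapshot_ensemble <- function(manifest, cfg = seg_model_config(),
                                    lr_cfg = cyclic_lr_config(),
                                    use_roi = FALSE, clip_norm = 1,
                                    verbose = FALSE) {
  train <- manifest[manifest$split == "train", ]
  val <- manifest[manifest$split == "val", ]
  if (nrow(train) == 0L) stop("empty train split")
  tr_samples <- load_seg_samples(train, cfg, use_roi,
                                 min_crop_size = cfg$input_size)
  va_samples <- load_seg_samples(val, cfg, use_roi,
                                 min_crop_size = cfg$input_size)
  batches_per_epoch <- ceiling(length(tr_samples) / cfg$batch_size)
  if (is.null(lr_cfg$step_size)) {
    lr_cfg$step_size <- 5L * batches_per_epoch
  }
  cycle_epochs <- 2 * lr_cfg$step_size / batches_per_epoch
  if (cfg$epochs %% cycle_epochs != 0) {
    stop("epochs (", cfg$epochs, ") must be a multiple of the cycle length (",
         cycle_epochs, " epochs); nearest valid value: ",
         max(1, round(cfg$epochs / cycle_epochs)) * cycle_epochs)
  }
  net <- build_segnet(cfg$architecture, 3L, 1L, cfg$base_channels,
                      seed = cfg$seed)
  params <- net$params
  opt <- optim_sgd_momentum(params, momentum = lr_cfg$momentum)
  snapshots <- list()
  history <- NULL
  step <- 0L
  local_seed(derive_seed(cfg$seed, 2L), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(length(tr_samples))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      eloss <- 0
      lr_last <- NA_real_
      for (b in batches) {
        lr <- cyclic_lr_value(step, lr_cfg)
        r <- batch_grads(net, params, tr_samples, b, cfg)
        if (is.finite(clip_norm)) {
          gn <- sqrt(sum(vapply(r$grads, function(g) sum(g^2), numeric(1))))
          if (gn > clip_norm) {
            r$grads <- lapply(r$grads, function(g) g * (clip_norm / gn))
          }
        }
        st <- optim_step(opt, params, r$grads, lr = lr)
        opt <- st$opt; params <- st$params
        eloss <- eloss + r$loss * length(b)
        step <- step + 1L
        lr_last <- lr
        if (step %% (2L * lr_cfg$step_size) == 0L) {
          snapshots[[length(snapshots) + 1L]] <- params
        }
      }
      eloss <- eloss / length(tr_samples)
      history <- rbind(history, data.frame(epoch = epoch, lr = lr_last,
                                           train_loss = eloss,
                                           val_miou = NA_real_))
      if (verbose) message(sprintf("epoch %d: loss %.4f", epoch, eloss))
    }
  })
  val_scores <- vapply(snapshots, function(p) val_miou(net, p, va_samples),
                       numeric(1))
  structure(list(snapshots = snapshots, val_scores = val_scores, net = net,
                 cfg = cfg, lr_cfg = lr_cfg, history = history,
                 use_roi = use_roi, cycle_epochs = cycle_epochs),
            class = "snapshot_set")
}

#' @export
print.snapshot_set <- function(x, ...) {
  cat(sprintf("<snapshot_set: %d snapshots (%g-epoch cycles), val mIoU %s>\n",
              length(x$snapshots), x$cycle_epochs,
              paste(sprintf("%.3f", x$val_scores), collapse = ", ")))
  invisible(x)
}

#' Predict a full-resolution logit map for a slide
#'
#' The slide is resized to the network input size, passed forward, and the
#' logits are resized back to the source resolution (bilinear interpolation
#' on the pre-activation values, so ensemble averaging can happen before the
#' output function).
#'
#' @param model an `artery_model`, or a list with `net` and `params` (one
#'   snapshot of a `snapshot_set`).
#' @param slide a [slide_image] (full frame or ROI crop).
#' @param input_size optional `(h, w)` override.
#' @return a [prob_map] in logit state at the slide's resolution.
#' @export
predict_prob_map <- function(model, slide, input_size = NULL) {
  input_size <- as.integer(input_size %||% model$cfg$input_size)
  d <- dim(slide$pixels)
  if (d[1L] == 0L || d[2L] == 0L) stop("image with zero area")
  x <- if (all(d[1:2] == input_size)) {
    slide$pixels / 255
  } else {
    resize_bilinear(slide$pixels / 255, input_size[1L], input_size[2L])
  }
  z <- nn_forward_value(model$net, model$params, x)[, , 1L]
  if (!all(d[1:2] == input_size)) {
    z <- resize_bilinear(z, d[1L], d[2L])
  }
  prob_map(z, activation_state = "logit")
}

#' @export
predict.artery_model <- function(object, newdata, ...) {
  predict_prob_map(object, newdata)
}
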