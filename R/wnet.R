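# Stage 3: unsupervised plaque segmentation with a W-Net.
#
# Two stacked encoder-decoder networks form an autoencoder: the encoder maps
# the artery-region crop to a per-pixel soft assignment over K classes
# (softmax), the decoder reconstructs the image from that assignment.
# Training alternates two updates per batch: (1) an encoder-only step
# minimising the soft normalized-cut loss, which pushes the soft assignment
# towards spatially coherent, feature-homogeneous partitions, and (2) a
# joint encoder+decoder step minimising mean-squared reconstruction error,
# which stops the assignment from collapsing to a single class. No labels
# are used anywhere. After training only the encoder matters: the class map
# is the per-pixel argmax of its output.

#' W-Net configuration
#'
#' @param k_classes number of latent classes K (>= 2; default 4: plaque,
#'   wall, lumen-like and background-like tissue is the working resolution
#'   this task needs).
#' @param base_channels encoder/decoder width.
#' @param input_patch `(h, w)` patch size, both divisible by 4.
#' @param sigma_intensity affinity bandwidth on the brightness feature,
#'   8-bit intensity units (default 10).
#' @param sigma_spatial affinity bandwidth on pixel distance, px (default 4).
#' @param affinity_radius spatial cutoff of the affinity graph, px
#'   (default 5); pixels at or beyond this distance have weight 0.
#' @param loss_balance weight of the soft-n-cut step relative to the
#'   reconstruction step, applied as a factor on the encoder step's learning
#'   rate (the steps alternate under separate adaptive optimisers, so
#'   scaling the loss itself would have no effect). Default 1; the task
#'   weightings published for this stain are not recoverable, so the
#'   balance is exposed.
#' @param epochs,batch_size,lr,seed training schedule (Adam).
#' @param color_affinity use the 3-channel color distance instead of
#'   brightness as the affinity feature.
#' @return an object of class `wnet_config`.
#' @export
wnet_config <- function(k_classes = 4L, base_channels = 8L,
                        input_patch = c(64L, 64L), sigma_intensity = 10,
                        sigma_spatial = 4, affinity_radius = 5L,
                        loss_balance = 1, epochs = 10L, batch_size = 1L,
                        lr = 5e-3, seed = 1L, color_affinity = FALSE) {
  if (k_classes < 2L) stop("k_classes must be at least 2")
  if (affinity_radius < 1L) stop("affinity_radius must be at least 1")
  if (sigma_intensity <= 0 || sigma_spatial <= 0) {
    stop("sigmas must be positive")
  }
  input_patch <- as.integer(input_patch)
  if (any(input_patch %% 4L != 0L)) {
    stop("input_patch dimensions must be divisible by 4")
  }
  structure(list(k_classes = as.integer(k_classes),
                 base_channels = as.integer(base_channels),
                 input_patch = input_patch,
                 sigma_intensity = sigma_intensity,
                 sigma_spatial = sigma_spatial,
                 affinity_radius = as.integer(affinity_radius),
                 loss_balance = loss_balance, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed), color_affinity = color_affinity),
            class = "wnet_config")
}

# Affinity feature of an image: brightness (default) or color channels,
# always on the 8-bit scale so sigma_intensity keeps its units. image in
# [0, 1].
wnet_features <- function(image01, cfg) {
  if (cfg$color_affinity) {
    image01 * 255
  } else {
    f <- (image01[, , 1L, drop = FALSE] + image01[, , 2L, drop = FALSE] +
            image01[, , 3L, drop = FALSE]) / 3 * 255
    f  # (H, W, 1)
  }
}

# Loss value and gradient w.r.t. the assignment p given precomputed affinity
# sums. For each class k with assoc_k = sum_u p_k(u) (W p_k)(u) and
# deg_k = sum_u p_k(u) d(u), the loss is K - sum_k assoc_k / deg_k (a 0/0
# ratio counts as 0); d(assoc_k)/dp_k(u) = 2 (W p_k)(u) by symmetry of W.
.soft_ncut_grad <- function(p, feat, cfg) {
  d3 <- dim(p)
  K <- d3[3L]
  terms <- cpp_ncut_terms(feat, p, ag_dim3(feat), as.integer(d3),
                          cfg$affinity_radius, cfg$sigma_intensity,
                          cfg$sigma_spatial)
  Wp <- terms$Wp
  deg <- terms$d
  dx <- array(0, dim = d3)
  value <- K
  for (k in seq_len(K)) {
    assoc <- sum(p[, , k] * Wp[, , k])
    degk <- sum(p[, , k] * deg)
    if (degk > 0) {
      value <- value - assoc / degk
      dx[, , k] <- -(2 * Wp[, , k] * degk - assoc * deg) / degk^2
    }
  }
  list(value = value, dx = dx)
}

#' Soft normalized-cut loss of a per-pixel class assignment
#'
#' Affinities `w(u, v) = exp(-||F(u)-F(v)||^2 / sigma_I^2) *
#' exp(-||X(u)-X(v)||^2 / sigma_X^2)` for spatial distance below
#' `affinity_radius` (0 otherwise). The loss is
#' `K - sum_k [sum_u p_k(u) sum_v w(u,v) p_k(v)] / [sum_u p_k(u) sum_t
#' w(u,t)]`, with a 0/0 ratio defined as 0; it lies in `[0, K]`, equals
#' `K - 1` for the uniform assignment, and 0 for a hard partition into
#' mutually zero-affinity groups.
#'
#' @param assignments `(H, W, K)` array; each pixel's class distribution
#'   must sum to 1 (tolerance `1e-5`).
#' @param image `(H, W, 3)` array in `[0, 1]` (or a [slide_image]) from
#'   which the affinity feature is computed.
#' @param cfg a [wnet_config] carrying the affinity parameters.
#' @return the loss value.
#' @export
soft_ncut_loss <- function(assignments, image, cfg = wnet_config()) {
  sums <- apply(assignments, c(1L, 2L), sum)
  if (max(abs(sums - 1)) > 1e-5) {
    stop("per-pixel class distributions must sum to 1")
  }
  px <- if (inherits(image, "slide_image")) image$pixels / 255 else image
  feat <- wnet_features(px, cfg)
  .soft_ncut_grad(assignments, feat, cfg)$value
}

#' Train a W-Net on artery-region crops
#'
#' Unsupervised training is sensitive to initialisation: a run can collapse
#' most of the softmax mass onto a subset of classes and never recover.
#' Like other unsupervised partitioners (k-means restarts), the trainer
#' therefore runs `restarts` independent seeded attempts (the first with
#' the configured seed) and keeps the one with the lowest final
#' reconstruction loss — a label-free criterion, since a collapsed class
#' structure cannot reconstruct the stain contrasts.
#'
#' @param images list of `(H, W, 3)` arrays in `[0, 1]` (artery-masked
#'   crops; pixels outside the artery already set to the background
#'   constant), each at `cfg$input_patch` size.
#' @param cfg a [wnet_config].
#' @param restarts number of independent seeded training attempts
#'   (default 3); the attempt with the lowest final reconstruction loss is
#'   returned.
#' @param verbose print per-epoch losses.
#' @return an object of class `wnet_model`: `encoder`, `decoder` (segnet
#'   specs), `enc_params`, `dec_params`, `cfg`, `history` (per-epoch ncut
#'   and reconstruction losses of the selected attempt), `restart` (which
#'   attempt won).
#' @export
wnet_train <- function(images, cfg = wnet_config(), restarts = 3L,
                       verbose = FALSE) {
  if (restarts > 1L) {
    best <- NULL
    for (r in seq_len(restarts)) {
      cfg_r <- cfg
      if (r > 1L) cfg_r$seed <- derive_seed(cfg$seed, 1000L + r)
      m <- wnet_train(images, cfg_r, restarts = 1L, verbose = verbose)
      rec <- m$history$recon_loss[nrow(m$history)]
      if (verbose) message(sprintf("restart %d: final recon %.5f", r, rec))
      if (is.null(best) || rec < best$rec) {
        best <- list(model = m, rec = rec, restart = r)
      }
    }
    best$model$restart <- best$restart
    return(best$model)
  }
  if (length(images) == 0L) stop("empty training set")
  ok <- vapply(images, function(x) all(dim(x)[1:2] == cfg$input_patch),
               logical(1))
  if (!all(ok)) stop("all patches must match cfg$input_patch")
  K <- cfg$k_classes
  encoder <- build_segnet("unet", 3L, K, cfg$base_channels,
                          norm = "instance", seed = cfg$seed)
  decoder <- build_segnet("unet", K, 3L, cfg$base_channels,
                          norm = "instance",
                          seed = derive_seed(cfg$seed, 11L))
  enc_params <- encoder$params
  dec_params <- decoder$params
  opt_enc <- optim_adam(enc_params, lr = cfg$lr * cfg$loss_balance)
  opt_all <- optim_adam(c(stats::setNames(enc_params,
                                          paste0("enc.", names(enc_params))),
                          stats::setNames(dec_params,
                                          paste0("dec.", names(dec_params)))),
                        lr = cfg$lr)
  history <- NULL
  softmax_post <- function(tape, out) ag_softmax_c(tape, out)
  local_seed(derive_seed(cfg$seed, 3L), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(length(images))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      e_ncut <- 0; e_rec <- 0
      for (b in batches) {
        # step 1: encoder update on the soft-n-cut objective
        gsum <- NULL; lsum <- 0
        for (j in b) {
          x <- images[[j]]
          feat <- wnet_features(x, cfg)
          lf <- function(pv) {
            r <- .soft_ncut_grad(pv, feat, cfg)
            list(value = cfg$loss_balance * r$value,
                 dx = cfg$loss_balance * r$dx)
          }
          r <- nn_loss_and_grads(encoder, enc_params, x, lf,
                                 post = softmax_post)
          lsum <- lsum + r$loss
          if (is.null(gsum)) gsum <- r$grads else
            for (nm in names(gsum)) gsum[[nm]] <- gsum[[nm]] + r$grads[[nm]]
        }
        for (nm in names(gsum)) gsum[[nm]] <- gsum[[nm]] / length(b)
        st <- optim_step(opt_enc, enc_params, gsum)
        opt_enc <- st$opt; enc_params <- st$params
        e_ncut <- e_ncut + lsum

        # step 2: joint encoder+decoder update on reconstruction MSE
        gsum <- NULL; lsum <- 0
        for (j in b) {
          x <- images[[j]]
          tape <- ag_tape()
          en <- lapply(enc_params, function(v) ag_var(tape, v))
          dn <- lapply(dec_params, function(v) ag_var(tape, v))
          xin <- ag_var(tape, x)
          pmap <- ag_softmax_c(tape, encoder$forward(en, tape, xin))
          recon <- decoder$forward(dn, tape, pmap)
          lnode <- ag_loss(tape, recon, function(v) {
            list(value = mean((v - x)^2), dx = 2 * (v - x) / length(x))
          })
          ag_backward(tape, lnode)
          lsum <- lsum + lnode$value
          g <- c(stats::setNames(lapply(en, function(nd) nd$grad %||%
                                          (nd$value * 0)),
                                 paste0("enc.", names(en))),
                 stats::setNames(lapply(dn, function(nd) nd$grad %||%
                                          (nd$value * 0)),
                                 paste0("dec.", names(dn))))
          if (is.null(gsum)) gsum <- g else
            for (nm in names(gsum)) gsum[[nm]] <- gsum[[nm]] + g[[nm]]
        }
        for (nm in names(gsum)) gsum[[nm]] <- gsum[[nm]] / length(b)
        joint <- c(stats::setNames(enc_params,
                                   paste0("enc.", names(enc_params))),
                   stats::setNames(dec_params,
                                   paste0("dec.", names(dec_params))))
        st <- optim_step(opt_all, joint, gsum)
        opt_all <- st$opt
        enc_params <- stats::setNames(
          st$params[paste0("enc.", names(enc_params))], names(enc_params))
        dec_params <- stats::setNames(
          st$params[paste0("dec.", names(dec_params))], names(dec_params))
        e_rec <- e_rec + lsum
      }
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  ncut_loss = e_ncut / length(images),
                                  recon_loss = e_rec / length(images)))
      if (verbose) {
        message(sprintf("epoch %d: ncut %.4f, recon %.5f", epoch,
                        e_ncut / length(images), e_rec / length(images)))
      }
    }
  })
  structure(list(encoder = encoder, decoder = decoder,
                 enc_params = enc_params, dec_params = dec_params,
                 cfg = cfg, history = history, restart = 1L),
            class = "wnet_model")
}

#' @export
print.wnet_model <- function(x, ...) {
  cat(sprintf("<wnet_model: K = %d, %d epochs, final recon MSE %.5f>\n",
              x$cfg$k_classes, nrow(x$history),
              x$history$recon_loss[nrow(x$history)]))
  invisible(x)
}

#' Infer the W-Net class map inside the arterial region
#'
#' Optionally color-transfers the slide to the dataset statistics, crops to
#' the artery box, sets non-artery pixels to the background constant so the
#' encoder only sees arterial tissue, runs the encoder and takes the
#' per-pixel argmax. Pixels outside the artery receive the reserved
#' background label 0; classes are labelled 1..K.
#'
#' @param model a `wnet_model`.
#' @param slide a [slide_image].
#' @param artery_mask a [binary_mask] for the slide.
#' @param stats optional `color_stats` for dataset-level transfer.
#' @return an object of class `class_map`: integer `(H, W)` label matrix
#'   (`labels`), `k_classes`, and the per-class `soft` assignment array at
#'   full resolution.
#' @export
infer_class_map <- function(model, slide, artery_mask, stats = NULL) {
  if (!all(dim(slide$pixels)[1:2] == dim(artery_mask$values))) {
    stop("slide/mask shape mismatch")
  }
  d <- dim(artery_mask$values)
  K <- model$cfg$k_classes
  if (!any(artery_mask$values)) {
    return(structure(list(labels = matrix(0L, d[1L], d[2L]), k_classes = K,
                          soft = NULL), class = "class_map"))
  }
  if (!is.null(stats)) slide <- color_transfer_apply(slide, stats)
  prop <- bbox_from_mask(artery_mask, padding_frac = 0.02)
  cr <- crop_to_roi(slide, prop)
  b <- prop$box
  sub_mask <- artery_mask$values[(b$y0 + 1L):b$y1, (b$x0 + 1L):b$x1,
                                 drop = FALSE]
  x <- cr$slide$pixels / 255
  bg <- vapply(1:3, function(c) mean(x[, , c][!sub_mask]), numeric(1))
  if (any(is.nan(bg))) bg <- c(0.5, 0.5, 0.5)
  for (c in 1:3) {
    layer <- x[, , c]
    layer[!sub_mask] <- bg[c]
    x[, , c] <- layer
  }
  # the encoder is fully convolutional and instance-normalised, so inference
  # runs at the crop's native resolution (padded to a multiple of 4); this
  # avoids the boundary blur a resize through the training patch size causes
  pad <- nn_pad_to_multiple(x, 4L)
  soft_pad <- nn_forward_value(model$encoder, model$enc_params, pad$x,
                               post = function(tape, out)
                                 ag_softmax_c(tape, out))
  soft <- nn_unpad(soft_pad, dim(x)[1:2])
  lab_crop <- apply(soft, c(1L, 2L), which.max)
  lab_crop[!sub_mask] <- 0L
  labels <- matrix(0L, d[1L], d[2L])
  labels[(b$y0 + 1L):b$y1, (b$x0 + 1L):b$x1] <- lab_crop
  soft_full <- array(0, dim = c(d, K))
  for (k in seq_len(K)) {
    layer <- matrix(0, d[1L], d[2L])
    layer[(b$y0 + 1L):b$y1, (b$x0 + 1L):b$x1] <- soft[, , k]
    soft_full[, , k] <- layer
  }
  structure(list(labels = labels, k_classes = K, soft = soft_full),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:x$k_classes))
  cat(sprintf("<class_map: K = %d; label counts %s>\n", x$k_classes,
              paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                    collapse = " ")))
  invisible(x)
}
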