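# The reduced encoder-decoder family used for artery segmentation and as the
# two halves of the W-Net. Four shapes are provided (unet, unetpp, fpn, pan)
# at depth 2 with a configurable channel width; all share single-conv blocks
# (3x3 + ReLU) so the desk-scale networks stay small enough to train on CPU.
# Larger external backbones can replace them through the detector/segmenter
# plug-in contracts; the shapes here define the topology, not the capacity,
# of their full-scale counterparts.

nn_init_conv <- function(kh, kw, cin, cout) {
  # He initialisation for ReLU blocks
  sd <- sqrt(2 / (kh * kw * cin))
  array(stats::rnorm(kh * kw * cin * cout, sd = sd), dim = c(kh, kw, cin, cout))
}

nn_conv_param <- function(params, name, kh, kw, cin, cout) {
  params[[paste0(name, ".w")]] <- nn_init_conv(kh, kw, cin, cout)
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

nn_dense_param <- function(params, name, cin, cout) {
  params[[paste0(name, ".w")]] <- matrix(stats::rnorm(cout * cin,
                                                      sd = sqrt(2 / cin)),
                                         cout, cin)
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

#' Build a small encoder-decoder segmentation network
#'
#' Constructs the parameter set and forward pass of one member of the reduced
#' architecture family. All four shapes take an `(H, W, in_channels)` array
#' with `H` and `W` divisible by 4 and return an `(H, W, out_channels)` map of
#' logits (no output activation).
#'
#' @param architecture one of `"unet"`, `"unetpp"`, `"fpn"`, `"pan"`.
#' @param in_channels,out_channels input and output channel counts.
#' @param base_channels width of the first encoder level; deeper levels double.
#' @param norm `"none"` or `"instance"`: instance-normalise every conv
#'   block's output before its ReLU (used by the unsupervised W-Net halves,
#'   where unnormalised activations let the class softmax saturate).
#' @param seed integer seed for weight initialisation.
#' @return an object of class `segnet` with elements `params` (named list of
#'   arrays) and `forward(params, tape, x_node)`.
#' @export
build_segnet <- function(architecture = c("unetpp", "unet", "fpn", "pan"),
                         in_channels = 3L, out_channels = 1L,
                         base_channels = 8L, norm = c("none", "instance"),
                         seed = 1L) {
  architecture <- match.arg(architecture)
  norm <- match.arg(norm)
  c1 <- as.integer(base_channels)
  c2 <- 2L * c1
  c4 <- 4L * c1
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  p <- list()
  cb <- function(tape, pr, name, x) {
    h <- ag_conv(tape, x, pr[[paste0(name, ".w")]], pr[[paste0(name, ".b")]])
    if (norm == "instance") h <- ag_instnorm(tape, h)
    ag_relu(tape, h)
  }
  if (architecture == "unet") {
    p <- nn_conv_param(p, "e1", 3, 3, in_channels, c1)
    p <- nn_conv_param(p, "e2", 3, 3, c1, c2)
    p <- nn_conv_param(p, "mid", 3, 3, c2, c4)
    p <- nn_conv_param(p, "d2", 3, 3, c4 + c2, c2)
    p <- nn_conv_param(p, "d1", 3, 3, c2 + c1, c1)
    p <- nn_conv_param(p, "head", 1, 1, c1, out_channels)
    forward <- function(pr, tape, x) {
      e1 <- cb(tape, pr, "e1", x)
      e2 <- cb(tape, pr, "e2", ag_pool2(tape, e1))
      mid <- cb(tape, pr, "mid", ag_pool2(tape, e2))
      d2 <- cb(tape, pr, "d2", ag_cat(tape, list(ag_up2(tape, mid), e2)))
      d1 <- cb(tape, pr, "d1", ag_cat(tape, list(ag_up2(tape, d2), e1)))
      ag_conv(tape, d1, pr[["head.w"]], pr[["head.b"]])
    }
  } else if (architecture == "unetpp") {
    # nested dense skip pathway X01, X11, X02
    p <- nn_conv_param(p, "x00", 3, 3, in_channels, c1)
    p <- nn_conv_param(p, "x10", 3, 3, c1, c2)
    p <- nn_conv_param(p, "x20", 3, 3, c2, c4)
    p <- nn_conv_param(p, "x01", 3, 3, c1 + c2, c1)
    p <- nn_conv_param(p, "x11", 3, 3, c2 + c4, c2)
    p <- nn_conv_param(p, "x02", 3, 3, c1 + c1 + c2, c1)
    p <- nn_conv_param(p, "head", 1, 1, c1, out_channels)
    forward <- function(pr, tape, x) {
      x00 <- cb(tape, pr, "x00", x)
      x10 <- cb(tape, pr, "x10", ag_pool2(tape, x00))
      x20 <- cb(tape, pr, "x20", ag_pool2(tape, x10))
      x01 <- cb(tape, pr, "x01", ag_cat(tape, list(x00, ag_up2(tape, x10))))
      x11 <- cb(tape, pr, "x11", ag_cat(tape, list(x10, ag_up2(tape, x20))))
      x02 <- cb(tape, pr, "x02",
                ag_cat(tape, list(x00, x01, ag_up2(tape, x11))))
      ag_conv(tape, x02, pr[["head.w"]], pr[["head.b"]])
    }
  } else {
    # fpn / pan: lateral 1x1 projections + top-down additive pathway;
    # pan adds channel attention on the top feature.
    p <- nn_conv_param(p, "e1", 3, 3, in_channels, c1)
    p <- nn_conv_param(p, "e2", 3, 3, c1, c2)
    p <- nn_conv_param(p, "mid", 3, 3, c2, c4)
    p <- nn_conv_param(p, "l1", 1, 1, c1, c1)
    p <- nn_conv_param(p, "l2", 1, 1, c2, c1)
    p <- nn_conv_param(p, "ltop", 1, 1, c4, c1)
    p <- nn_conv_param(p, "smooth", 3, 3, c1, c1)
    p <- nn_conv_param(p, "head", 1, 1, c1, out_channels)
    attn <- architecture == "pan"
    if (attn) {
      p <- nn_dense_param(p, "att1", c4, c1)
      p <- nn_dense_param(p, "att2", c1, c1)
    }
    forward <- function(pr, tape, x) {
      e1 <- cb(tape, pr, "e1", x)
      e2 <- cb(tape, pr, "e2", ag_pool2(tape, e1))
      mid <- cb(tape, pr, "mid", ag_pool2(tape, e2))
      top <- ag_conv(tape, mid, pr[["ltop.w"]], pr[["ltop.b"]])
      if (attn) {
        s <- ag_gap(tape, mid)
        s <- ag_relu(tape, ag_dense(tape, s, pr[["att1.w"]], pr[["att1.b"]]))
        s <- ag_sigmoid_vec(tape, ag_dense(tape, s, pr[["att2.w"]],
                                           pr[["att2.b"]]))
        top <- ag_scale_channels(tape, top, s)
      }
      p2 <- ag_add(tape, ag_conv(tape, e2, pr[["l2.w"]], pr[["l2.b"]]),
                   ag_up2(tape, top))
      p1 <- ag_add(tape, ag_conv(tape, e1, pr[["l1.w"]], pr[["l1.b"]]),
                   ag_up2(tape, p2))
      sm <- cb(tape, pr, "smooth", p1)
      ag_conv(tape, sm, pr[["head.w"]], pr[["head.b"]])
    }
  }
  structure(list(params = p, forward = forward,
                 architecture = architecture, in_channels = in_channels,
                 out_channels = out_channels, base_channels = c1,
                 norm = norm),
            class = "segnet")
}

# Run forward + a loss, return list(loss, grads). `loss_fn(logits_value)` must
# return list(value, dx). `x` is an (H, W, C) array.
nn_loss_and_grads <- function(net, params, x, loss_fn, post = NULL) {
  tape <- ag_tape()
  pn <- lapply(params, function(v) ag_var(tape, v))
  xin <- ag_var(tape, x)
  out <- net$forward(pn, tape, xin)
  if (!is.null(post)) out <- post(tape, out)
  lnode <- ag_loss(tape, out, loss_fn)
  ag_backward(tape, lnode)
  grads <- lapply(pn, function(nd) {
    if (is.null(nd$grad)) nd$value * 0 else nd$grad
  })
  list(loss = lnode$value, grads = grads, output = out$value)
}

nn_forward_value <- function(net, params, x, post = NULL) {
  tape <- ag_tape()
  pn <- lapply(params, function(v) ag_var(tape, v))
  out <- net$forward(pn, tape, ag_var(tape, x))
  if (!is.null(post)) out <- post(tape, out)
  out$value
}

# ---- optimizers -----------------------------------------------------------

optim_adam <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st <- list(m = lapply(params, function(v) v * 0),
             v = lapply(params, function(v) v * 0), t = 0L,
             lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
  structure(st, class = "optim_adam")
}

optim_step <- function(opt, params, grads, lr = NULL) UseMethod("optim_step")

#' @export
optim_step.optim_adam <- function(opt, params, grads, lr = NULL) {
  if (is.null(lr)) lr <- opt$lr
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * grads[[nm]]
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * grads[[nm]]^2
    mh <- opt$m[[nm]] / (1 - opt$beta1^opt$t)
    vh <- opt$v[[nm]] / (1 - opt$beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + opt$eps)
  }
  list(opt = opt, params = params)
}

optim_sgd_momentum <- function(params, lr = 1e-4, momentum = 0.9) {
  structure(list(v = lapply(params, function(v) v * 0), lr = lr,
                 momentum = momentum), class = "optim_sgd")
}

#' @export
optim_step.optim_sgd <- function(opt, params, grads, lr = NULL) {
  if (is.null(lr)) lr <- opt$lr
  for (nm in names(params)) {
    opt$v[[nm]] <- opt$momentum * opt$v[[nm]] - lr * grads[[nm]]
    params[[nm]] <- params[[nm]] + opt$v[[nm]]
  }
  list(opt = opt, params = params)
}

# ---- shape plumbing -------------------------------------------------------

# Pad an (H, W, C) array with edge replication so H and W are multiples of m.
nn_pad_to_multiple <- function(x, m = 4L) {
  d <- dim(x)
  ph <- (m - d[1L] %% m) %% m
  pw <- (m - d[2L] %% m) %% m
  if (ph == 0L && pw == 0L) return(list(x = x, pad = c(0L, 0L)))
  ri <- c(seq_len(d[1L]), rep(d[1L], ph))
  ci <- c(seq_len(d[2L]), rep(d[2L], pw))
  list(x = x[ri, ci, , drop = FALSE], pad = c(ph, pw))
}

nn_unpad <- function(y, orig_hw) {
  y[seq_len(orig_hw[1L]), seq_len(orig_hw[2L]), , drop = FALSE]
}
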