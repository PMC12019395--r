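# Minimal reverse-mode autograd over (H, W, C) arrays, backing the small
# encoder-decoder networks this package trains. Nodes live on a tape in
# creation order; backward walks the tape in reverse. Convolution, pooling
# and upsampling kernels are compiled (src/convops.cpp); everything else is
# vectorised R. Gradients are verified against finite differences in the
# test suite.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp
}

ag_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  tape$nodes[[length(tape$nodes) + 1L]] <- nd
  nd
}

ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# Leaf variable (input or parameter).
ag_var <- function(tape, value) ag_node(tape, value)

ag_dim3 <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) d <- c(d, 1L)
  as.integer(d)
}

ag_conv <- function(tape, x, w, b) {
  xd <- ag_dim3(x$value)
  wd <- as.integer(dim(w$value))
  y <- cpp_conv2d_fwd(x$value, w$value, b$value, xd, wd)
  ag_node(tape, y, list(x, w, b), function(nd) {
    gr <- cpp_conv2d_bwd(x$value, w$value, nd$grad, xd, wd)
    ag_accum(x, gr$dx)
    ag_accum(w, gr$dw)
    ag_accum(b, gr$db)
  })
}

ag_relu <- function(tape, x) {
  y <- pmax(x$value, 0)
  ag_node(tape, y, list(x), function(nd) {
    ag_accum(x, nd$grad * (x$value > 0))
  })
}

ag_pool2 <- function(tape, x) {
  xd <- ag_dim3(x$value)
  fw <- cpp_maxpool2_fwd(x$value, xd)
  ag_node(tape, fw$y, list(x), function(nd) {
    ag_accum(x, cpp_maxpool2_bwd(nd$grad, fw$argmax, xd))
  })
}

ag_up2 <- function(tape, x) {
  xd <- ag_dim3(x$value)
  y <- cpp_up2_fwd(x$value, xd)
  ag_node(tape, y, list(x), function(nd) {
    ag_accum(x, cpp_up2_bwd(nd$grad, xd))
  })
}

ag_cat <- function(tape, xs) {
  vals <- lapply(xs, function(n) n$value)
  dims <- lapply(vals, ag_dim3)
  ch <- vapply(dims, `[`, integer(1), 3L)
  y <- array(unlist(vals, use.names = FALSE),
             dim = c(dims[[1L]][1:2], sum(ch)))
  ag_node(tape, y, xs, function(nd) {
    off <- 0L
    for (i in seq_along(xs)) {
      ag_accum(xs[[i]], array(nd$grad[, , off + seq_len(ch[i]), drop = FALSE],
                              dim = dims[[i]]))
      off <- off + ch[i]
    }
  })
}

ag_add <- function(tape, x, y) {
  ag_node(tape, x$value + y$value, list(x, y), function(nd) {
    ag_accum(x, nd$grad)
    ag_accum(y, nd$grad)
  })
}

# Global average pool: (H, W, C) -> length-C vector.
ag_gap <- function(tape, x) {
  d <- ag_dim3(x$value)
  y <- apply(array(x$value, dim = d), 3L, mean)
  ag_node(tape, y, list(x), function(nd) {
    g <- array(rep(nd$grad / (d[1L] * d[2L]), each = d[1L] * d[2L]), dim = d)
    ag_accum(x, g)
  })
}

ag_dense <- function(tape, v, w, b) {
  y <- as.numeric(w$value %*% v$value + b$value)
  ag_node(tape, y, list(v, w, b), function(nd) {
    ag_accum(v, as.numeric(crossprod(w$value, nd$grad)))
    ag_accum(w, outer(nd$grad, v$value))
    ag_accum(b, nd$grad)
  })
}

ag_relu_vec <- ag_relu

ag_sigmoid_vec <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(tape, s, list(x), function(nd) {
    ag_accum(x, nd$grad * s * (1 - s))
  })
}

# Per-channel rescaling of a feature map by a length-C vector (attention).
ag_scale_channels <- function(tape, x, s) {
  d <- ag_dim3(x$value)
  sv <- rep(s$value, each = d[1L] * d[2L])
  y <- array(as.numeric(x$value) * sv, dim = d)
  ag_node(tape, y, list(x, s), function(nd) {
    ag_accum(x, array(as.numeric(nd$grad) * sv, dim = d))
    ag_accum(s, apply(array(as.numeric(nd$grad) * as.numeric(x$value),
                            dim = d), 3L, sum))
  })
}

# Instance normalisation: each channel standardised over its spatial extent
# (mean 0, variance 1). No learned affine; keeps activations in range so the
# class softmax cannot saturate early in unsupervised training.
ag_instnorm <- function(tape, x, eps = 1e-5) {
  d <- ag_dim3(x$value)
  n <- d[1L] * d[2L]
  xa <- array(x$value, dim = d)
  mu <- apply(xa, 3L, mean)
  v <- apply(xa, 3L, function(m) mean((m - mean(m))^2))
  sdv <- sqrt(v + eps)
  y <- sweep(sweep(xa, 3L, mu), 3L, sdv, `/`)
  ag_node(tape, y, list(x), function(nd) {
    dy <- array(nd$grad, dim = d)
    m1 <- apply(dy, 3L, mean)
    m2 <- apply(dy * y, 3L, mean)
    dx <- sweep(sweep(dy, 3L, m1) - sweep(y, 3L, m2, `*`), 3L, sdv, `/`)
    ag_accum(x, dx)
  })
}

# Channel-wise softmax: (H, W, K) -> per-pixel class distribution.
ag_softmax_c <- function(tape, x) {
  d <- ag_dim3(x$value)
  m <- array(x$value, dim = d)
  mx <- apply(m, c(1L, 2L), max)
  e <- exp(m - array(mx, dim = d))
  z <- apply(e, c(1L, 2L), sum)
  p <- e / array(z, dim = d)
  ag_node(tape, p, list(x), function(nd) {
    dot <- apply(nd$grad * p, c(1L, 2L), sum)
    ag_accum(x, p * (nd$grad - array(dot, dim = d)))
  })
}

# Scalar node from an externally differentiated loss: `fn(x_value)` must
# return list(value = scalar, dx = gradient array w.r.t. x_value).
ag_loss <- function(tape, x, fn) {
  res <- fn(x$value)
  ag_node(tape, res$value, list(x), function(nd) {
    ag_accum(x, nd$grad * res$dx)
  })
}

# Backpropagate from a scalar output node through the whole tape.
ag_backward <- function(tape, out) {
  out$grad <- 1
  for (i in rev(seq_along(tape$nodes))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}
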