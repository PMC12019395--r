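# Shared fixtures, all generated in code at test time.

# Small slide + ground truth, memoised per test run.
fixture_slide <- local({
  cache <- list()
  function(frac = 0.3, seed = 7, size = c(120L, 160L)) {
    key <- paste(frac, seed, paste(size, collapse = "x"))
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_slide(
        synth_params(image_size = size, target_plaque_fraction = frac,
                     seed = seed))
    }
    cache[[key]]
  }
})

# A random binary mask with a few blobs.
random_blob_mask <- function(h = 32, w = 32, n_blobs = 3, seed = 1) {
  local({
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    m <- matrix(FALSE, h, w)
    for (i in seq_len(n_blobs)) {
      cy <- runif(1, 1, h); cx <- runif(1, 1, w); r <- runif(1, 1, min(h, w) / 4)
      yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
      m <- m | ((yy - cy)^2 + (xx - cx)^2 <= r^2)
    }
    m
  })
}

# Independent per-pixel counting oracle for mask combination.
overlap_oracle <- function(stack, alpha) {
  d <- dim(stack$members[[1L]]$values)
  out <- matrix(FALSE, d[1L], d[2L])
  for (i in seq_len(d[1L])) {
    for (j in seq_len(d[2L])) {
      cnt <- 0L
      for (m in stack$members) if (m$values[i, j]) cnt <- cnt + 1L
      out[i, j] <- cnt >= alpha
    }
  }
  out
}

# Brute-force 8-connected flood-fill labelling oracle.
floodfill_oracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (!mask[i, j] || lab[i, j] != 0L) next
      nxt <- nxt + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(queue) > 0L) {
        cur <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ni <- cur[1L] + di; nj <- cur[2L] + dj
          if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
              mask[ni, nj] && lab[ni, nj] == 0L) {
            lab[ni, nj] <- nxt
            queue[[length(queue) + 1L]] <- c(ni, nj)
          }
        }
      }
    }
  }
  lab
}

# Brute-force soft-n-cut evaluation (double loop over all pixel pairs).
ncut_oracle <- function(p, feat, radius, sigmaI, sigmaX) {
  d <- dim(p); H <- d[1L]; W <- d[2L]; K <- d[3L]
  f <- array(feat, dim = c(H, W, length(feat) / (H * W)))
  wmat <- matrix(0, H * W, H * W)
  for (u in seq_len(H * W)) {
    uy <- (u - 1L) %% H + 1L; ux <- (u - 1L) %/% H + 1L
    for (v in seq_len(H * W)) {
      vy <- (v - 1L) %% H + 1L; vx <- (v - 1L) %/% H + 1L
      sp2 <- (uy - vy)^2 + (ux - vx)^2
      if (sp2 >= radius^2) next
      fd2 <- sum((f[uy, ux, ] - f[vy, vx, ])^2)
      wmat[u, v] <- exp(-fd2 / sigmaI^2) * exp(-sp2 / sigmaX^2)
    }
  }
  loss <- K
  for (k in seq_len(K)) {
    pk <- as.numeric(p[, , k])
    num <- as.numeric(t(pk) %*% wmat %*% pk)
    den <- sum(pk * rowSums(wmat))
    if (den > 0) loss <- loss - num / den
  }
  loss
}

# Tiny training dataset on disk, memoised; used by training-path tests.
fixture_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "plaqueseg-fixture-ds")
      cache <<- generate_dataset(
        dir, n_slides = 16, n_mice = 8, n_subdatasets = 2,
        params_template = synth_params(image_size = c(96L, 128L),
                                       target_plaque_fraction = 0.3),
        seed = 11)
    }
    cache
  }
})
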