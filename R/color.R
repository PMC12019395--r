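# Statistical color transfer in the decorrelated l-alpha-beta space.
#
# RGB is mapped to LMS cone space, log-compressed, and rotated into the
# classical l-alpha-beta basis whose channels are approximately
# decorrelated for natural images. Transfer then matches each channel's
# mean and standard deviation to target statistics; pooling those targets
# over a whole dataset homogenises staining appearance across slides, the
# step the unsupervised plaque network needs when subdatasets drift in
# color.

.rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
.lms2rgb <- solve(.rgb2lms)
.lms2lab <- matrix(c(1 / sqrt(3), 0, 0,
                     0, 1 / sqrt(6), 0,
                     0, 0, 1 / sqrt(2)), 3, 3) %*%
  matrix(c(1, 1, 1,
           1, 1, -2,
           1, -1, 0), 3, 3, byrow = TRUE)
.lab2lms <- solve(.lms2lab)
.log_eps <- 1e-6

# pixels: (H, W, 3) in [0, 255] -> N x 3 matrix in l-alpha-beta
rgb_to_lab_matrix <- function(pixels) {
  n <- prod(dim(pixels)[1:2])
  rgb <- matrix(as.numeric(pixels) / 255, n, 3L)
  lms <- rgb %*% t(.rgb2lms)
  loglms <- log10(pmax(lms, .log_eps))
  loglms %*% t(.lms2lab)
}

lab_matrix_to_rgb <- function(lab, dims_hw) {
  loglms <- lab %*% t(.lab2lms)
  lms <- 10^loglms
  rgb <- lms %*% t(.lms2rgb)
  rgb <- pmin(pmax(rgb, 0), 1)
  array(as.integer(floor(rgb * 255 + 0.5)), dim = c(dims_hw, 3L))
}

#' Pooled color statistics of an image set in transfer space
#'
#' Pools up to `sample_cap` pixels per image (seeded subsample) and returns
#' the per-channel mean and standard deviation of the pooled pixel set in
#' l-alpha-beta space. Pooling pixels (rather than averaging per-image
#' statistics) weights every sampled pixel equally, which is what "the color
#' space of the whole dataset" means here.
#'
#' @param images list of [slide_image]s (or bare `(H, W, 3)` arrays in
#'   `[0, 255]`).
#' @param sample_cap maximum pixels sampled per image (default 50000).
#' @param seed integer seed for the subsample.
#' @return an object of class `color_stats`: `mean`, `sd` (length 3),
#'   `n_pixels_sampled`, `space = "lab"`.
#' @export
dataset_color_stats <- function(images, sample_cap = 50000L, seed = 1L) {
  if (length(images) == 0L) stop("empty image list")
  pooled <- local_seed(seed, {
    do.call(rbind, lapply(images, function(im) {
      px <- if (inherits(im, "slide_image")) im$pixels else im
      lab <- rgb_to_lab_matrix(px)
      if (nrow(lab) > sample_cap) {
        lab[sample(nrow(lab), sample_cap), , drop = FALSE]
      } else lab
    }))
  })
  structure(list(mean = colMeans(pooled), sd = apply(pooled, 2L, stats::sd),
                 n_pixels_sampled = nrow(pooled), space = "lab"),
            class = "color_stats")
}

#' @export
print.color_stats <- function(x, ...) {
  cat(sprintf(
    "<color_stats (%s): mean %s, sd %s, %d px>\n", x$space,
    paste(sprintf("%.3f", x$mean), collapse = "/"),
    paste(sprintf("%.3f", x$sd), collapse = "/"), x$n_pixels_sampled))
  invisible(x)
}

#' Transfer an image's color statistics to a target
#'
#' Per channel in l-alpha-beta space: `x' = (x - mu_img) * (sd_target /
#' sd_img) + mu_target`. A channel with `sd_img < guard_eps` (constant-color
#' image) is shifted only, never rescaled. The result is converted back to
#' RGB with clipping to `[0, 255]`.
#'
#' @param image a [slide_image] (or `(H, W, 3)` array).
#' @param target a `color_stats` object.
#' @param guard_eps standard-deviation floor below which the scale factor is
#'   1 (default `1e-8`).
#' @param return_space return the raw transfer-space pixel matrix (before
#'   conversion back to RGB and clipping) instead of an image; used to
#'   verify the affine normalisation exactly.
#' @return the transferred image, same type as the input (or an `N x 3`
#'   l-alpha-beta matrix when `return_space = TRUE`).
#' @export
color_transfer_apply <- function(image, target, guard_eps = 1e-8,
                                 return_space = FALSE) {
  px <- if (inherits(image, "slide_image")) image$pixels else image
  lab <- rgb_to_lab_matrix(px)
  mu <- colMeans(lab)
  sd_img <- apply(lab, 2L, stats::sd)
  scale <- ifelse(sd_img < guard_eps, 1, target$sd / sd_img)
  out <- sweep(sweep(lab, 2L, mu), 2L, scale, `*`)
  out <- sweep(out, 2L, target$mean, `+`)
  if (return_space) return(out)
  res <- lab_matrix_to_rgb(out, dim(px)[1:2])
  if (inherits(image, "slide_image")) {
    image$pixels <- res
    image
  } else res
}

#' Serialise color statistics as a small JSON sidecar
#' @param stats a `color_stats` object.
#' @param path output JSON path.
#' @export
write_color_stats <- function(stats, path) {
  jsonlite::write_json(list(space = stats$space, mean = stats$mean,
                            sd = stats$sd,
                            n_pixels_sampled = stats$n_pixels_sampled),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read color statistics from a JSON sidecar
#' @param path JSON path written by [write_color_stats].
#' @return a `color_stats` object.
#' @export
read_color_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(x$mean), sd = as.numeric(x$sd),
                 n_pixels_sampled = as.integer(x$n_pixels_sampled),
                 space = x$space), class = "color_stats")
}

# Transfer-space moments of an image, used by tests and diagnostics.
color_moments <- function(image) {
  px <- if (inherits(image, "slide_image")) image$pixels else image
  lab <- rgb_to_lab_matrix(px)
  list(mean = colMeans(lab), sd = apply(lab, 2L, stats::sd))
}
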