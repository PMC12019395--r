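# Synthetic slide generator.
#
# Real aortic-root sections show a roughly annular vessel wall around a pale
# lumen, surrounded by background tissue, with Oil-Red-O-positive plaque as
# saturated red deposits confined to the wall. The generator emulates exactly
# that topology -- an annulus with smooth low-frequency radial perturbation,
# red blobs inside the wall, per-subdataset color drift and pixel noise --
# with exact ground truth, so every downstream stage is testable without the
# private datasets. It makes no claim to photorealism (no valve leaflets, no
# sectioning artifacts).

#' Parameters for the synthetic slide generator
#'
#' @param image_size `(H, W)` in pixels, width:height 4:3. The default
#'   matches the smallest slide resolution the pipeline targets; tests use
#'   smaller sizes.
#' @param center_jitter maximum displacement of the ring centre from the
#'   image centre, as a fraction of `min(H, W)`.
#' @param outer_radius_range,inner_radius_range sampling ranges for the wall
#'   radii, as fractions of `min(H, W)`.
#' @param target_plaque_fraction desired plaque area as a fraction of the
#'   wall area, in `[0, 0.8)` (observed plaque burdens top out near 0.77).
#' @param n_plaque_blobs number of candidate plaque blobs generated; the
#'   prefix needed to reach the target fraction is used.
#' @param background_texture_scale amplitude (8-bit units) of the smooth
#'   background texture.
#' @param color_profile named list with `offset` (length-3 additive RGB
#'   shift) emulating per-subdataset staining/scanner drift.
#' @param noise_sd pixel noise standard deviation, 8-bit units.
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @return an object of class `synth_params`.
#' @export
synth_params <- function(image_size = c(720L, 960L), center_jitter = 0.05,
                         outer_radius_range = c(0.30, 0.38),
                         inner_radius_range = c(0.14, 0.20),
                         target_plaque_fraction = 0.3, n_plaque_blobs = 400L,
                         background_texture_scale = 6,
                         color_profile = list(offset = c(0, 0, 0)),
                         noise_sd = 4, seed = 1L) {
  stopifnot(length(image_size) == 2L)
  if (target_plaque_fraction < 0 || target_plaque_fraction >= 0.8) {
    stop("target_plaque_fraction must lie in [0, 0.8)")
  }
  if (min(outer_radius_range) <= max(inner_radius_range)) {
    stop("outer radius range must lie strictly above the inner radius range")
  }
  structure(list(image_size = as.integer(image_size),
                 center_jitter = center_jitter,
                 outer_radius_range = outer_radius_range,
                 inner_radius_range = inner_radius_range,
                 target_plaque_fraction = target_plaque_fraction,
                 n_plaque_blobs = as.integer(n_plaque_blobs),
                 background_texture_scale = background_texture_scale,
                 color_profile = color_profile, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# Smooth 2-D noise: coarse white noise upsampled bilinearly.
smooth_noise <- function(H, W, cells = 8L) {
  coarse <- matrix(stats::rnorm(cells * cells), cells, cells)
  resize_bilinear(coarse, H, W)
}

# Generator palette (constants of the simulation, not claims about real
# staining): plaque is ORO-like saturated red, the wall pale pink, the lumen
# and surround near-white tissue tones.
.synth_colors <- list(plaque = c(190, 60, 70), wall = c(225, 185, 195),
                      lumen = c(243, 238, 240), background = c(236, 228, 232))

#' Generate one synthetic slide with ground truth
#'
#' @param params a [synth_params].
#' @param slide_id,mouse_id,subdataset_id identifiers attached to the slide.
#' @param pixel_spacing_um physical pixel spacing recorded in the metadata.
#' @return a list with elements `slide` ([slide_image]), `artery` and
#'   `plaque` ([binary_mask]s, plaque a subset of artery), and `box`
#'   ([bbox], the tight box of the artery mask).
#' @export
generate_slide <- function(params, slide_id = "synth", mouse_id = "mouse1",
                           subdataset_id = "sub1", pixel_spacing_um = 10) {
  local_seed(params$seed, {
    H <- params$image_size[1L]; W <- params$image_size[2L]
    m <- min(H, W)
    cy <- H / 2 + stats::runif(1, -1, 1) * params$center_jitter * m
    cx <- W / 2 + stats::runif(1, -1, 1) * params$center_jitter * m
    r_out <- stats::runif(1, params$outer_radius_range[1L],
                          params$outer_radius_range[2L]) * m
    r_in <- stats::runif(1, params$inner_radius_range[1L],
                         params$inner_radius_range[2L]) * m
    # low-frequency radial perturbation shared by both wall boundaries
    nharm <- 3L
    amp <- stats::runif(nharm, 0, 0.06)
    phase <- stats::runif(nharm, 0, 2 * pi)
    yy <- matrix(seq_len(H) - 0.5 - cy, H, W)
    xx <- matrix(seq_len(W) - 0.5 - cx, H, W, byrow = TRUE)
    rr <- sqrt(yy^2 + xx^2)
    th <- atan2(yy, xx)
    pert <- 1
    for (k in seq_len(nharm)) {
      pert <- pert + amp[k] * sin(k * th + phase[k])
    }
    artery <- rr >= r_in * pert & rr <= r_out * pert
    lumen <- rr < r_in * pert
    if (!any(artery)) stop("degenerate geometry: empty artery mask")

    # candidate plaque blobs inside the wall; the shortest prefix reaching
    # the target fraction is kept, so achieved fraction is monotone in the
    # target for a fixed seed
    wall_px <- sum(artery)
    plaque <- matrix(FALSE, H, W)
    if (params$target_plaque_fraction > 0) {
      target_px <- params$target_plaque_fraction * wall_px
      blob_r <- 0.45 * (r_out - r_in)
      for (i in seq_len(params$n_plaque_blobs)) {
        if (sum(plaque) >= target_px) break
        bth <- stats::runif(1, 0, 2 * pi)
        brad <- stats::runif(1, r_in, r_out)
        bcy <- cy + brad * sin(bth)
        bcx <- cx + brad * cos(bth)
        br <- stats::runif(1, 0.35, 0.9) * blob_r
        blob <- (yy + cy - bcy)^2 + (xx + cx - bcx)^2 <= br^2
        plaque <- plaque | (blob & artery)
      }
      achieved <- sum(plaque) / wall_px
      if (achieved < params$target_plaque_fraction - 0.05) {
        stop("target_plaque_fraction ", params$target_plaque_fraction,
             " not reachable with n_plaque_blobs = ", params$n_plaque_blobs,
             " and the chosen radii (achieved ", round(achieved, 3), ")")
      }
    }

    # paint regions, then texture, subdataset color drift and noise
    px <- array(0, dim = c(H, W, 3L))
    for (ch in 1:3) {
      layer <- matrix(.synth_colors$background[ch], H, W)
      layer[lumen] <- .synth_colors$lumen[ch]
      layer[artery] <- .synth_colors$wall[ch]
      layer[plaque] <- .synth_colors$plaque[ch]
      layer <- layer + params$background_texture_scale * smooth_noise(H, W)
      layer <- layer + params$color_profile$offset[ch]
      layer <- layer + stats::rnorm(H * W, sd = params$noise_sd)
      px[, , ch] <- pmin(pmax(layer, 0), 255)
    }
    px <- array(as.integer(floor(px + 0.5)), dim = dim(px))

    rows <- which(rowSums(artery) > 0)
    cols <- which(colSums(artery) > 0)
    box <- bbox(min(cols) - 1L, min(rows) - 1L, max(cols), max(rows))
    list(slide = slide_image(px, slide_id = slide_id, mouse_id = mouse_id,
                             subdataset_id = subdataset_id,
                             pixel_spacing_um = pixel_spacing_um),
         artery = binary_mask(artery, "artery", slide_id),
         plaque = binary_mask(plaque, "plaque", slide_id),
         box = box)
  })
}

#' Generate a synthetic dataset on disk with a manifest
#'
#' Slides are assigned round-robin to mice and subdatasets; each subdataset
#' receives its own color-profile offset so that dataset-level color transfer
#' has real drift to remove. Slides, masks and boxes are written under `dir`
#' and a split manifest is returned (and written as `manifest.csv`).
#'
#' @param dir output directory (created if needed).
#' @param n_slides,n_mice,n_subdatasets dataset sizes (`n_mice <= n_slides`).
#' @param params_template a [synth_params] used for every slide; per-slide
#'   seeds and per-subdataset color offsets are derived from it.
#' @param plaque_fractions optional vector of target fractions cycled over
#'   slides (default: the template's single target).
#' @param subdataset_offsets optional list of length-3 RGB offsets, one per
#'   subdataset (default: graded red-channel drift, 12 units apart).
#' @param seed integer master seed.
#' @param split_fractions train/val/test fractions for [split_dataset].
#' @return the manifest data frame (invisibly also on disk).
#' @export
generate_dataset <- function(dir, n_slides, n_mice, n_subdatasets = 1L,
                             params_template = synth_params(),
                             plaque_fractions = NULL,
                             subdataset_offsets = NULL, seed = 1L,
                             split_fractions = c(0.6, 0.2, 0.2)) {
  if (n_slides < 1L) stop("need at least one slide")
  if (n_mice > n_slides) stop("n_mice must not exceed n_slides")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(subdataset_offsets)) {
    subdataset_offsets <- lapply(seq_len(n_subdatasets) - 1L,
                                 function(i) c(12 * i, -4 * i, 2 * i))
  }
  if (is.null(plaque_fractions)) {
    plaque_fractions <- params_template$target_plaque_fraction
  }
  rows <- vector("list", n_slides)
  sexes <- c("m", "f")
  genotypes <- c("ko", "wt")
  diets <- c("wtd", "chow")
  for (i in seq_len(n_slides)) {
    mouse_i <- (i - 1L) %% n_mice + 1L
    sub_i <- (i - 1L) %% n_subdatasets + 1L
    p <- params_template
    p$seed <- derive_seed(seed, i)
    p$color_profile <- list(offset = subdataset_offsets[[sub_i]])
    p$target_plaque_fraction <-
      plaque_fractions[(i - 1L) %% length(plaque_fractions) + 1L]
    sid <- sprintf("slide%03d", i)
    g <- generate_slide(p, slide_id = sid,
                        mouse_id = sprintf("mouse%02d", mouse_i),
                        subdataset_id = sprintf("sub%02d", sub_i))
    paths <- list(slide = file.path(dir, paste0(sid, ".png")),
                  artery = file.path(dir, paste0(sid, "_artery.png")),
                  plaque = file.path(dir, paste0(sid, "_plaque.png")),
                  bbox = file.path(dir, paste0(sid, ".txt")))
    write_slide(g$slide, paths$slide)
    write_mask(g$artery, paths$artery)
    write_mask(g$plaque, paths$plaque)
    write_bbox(g$box, dim(g$artery$values), paths$bbox)
    rows[[i]] <- data.frame(slide_id = sid, path = paths$slide,
                            mask_artery = paths$artery,
                            mask_plaque = paths$plaque, bbox = paths$bbox,
                            mouse_id = sprintf("mouse%02d", mouse_i),
                            subdataset_id = sprintf("sub%02d", sub_i),
                            sex = sexes[(mouse_i - 1L) %% 2L + 1L],
                            genotype = genotypes[((mouse_i - 1L) %/% 2L) %% 2L + 1L],
                            diet = diets[((mouse_i - 1L) %/% 4L) %% 2L + 1L],
                            pixel_spacing_um = 10,
                            split = NA_character_,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (n_mice >= 3L) {
    manifest <- split_dataset(manifest, split_fractions,
                              seed = derive_seed(seed, 0L))
  } else {
    manifest$split <- "train"
  }
  class(manifest) <- c("dataset_manifest", "data.frame")
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Generate a corrupted mask stack around a known ground truth
#'
#' Each member is an independent pixel-flip corruption of `gt`: background
#' pixels turn foreground with probability `flip_fp`, foreground pixels turn
#' background with probability `flip_fn` (i.i.d. across pixels and members).
#' This is the fixture for exercising the mask-combination strategies.
#'
#' @param gt a [binary_mask] ground truth.
#' @param n number of members.
#' @param flip_fp,flip_fn flip probabilities in `[0, 1)`.
#' @param seed integer seed.
#' @return a [mask_stack] of `n` binary masks.
#' @export
generate_mask_stack <- function(gt, n, flip_fp = 0.1, flip_fn = 0.1,
                                seed = 1L) {
  if (n < 1L) stop("n must be at least 1")
  if (flip_fp < 0 || flip_fp >= 1 || flip_fn < 0 || flip_fn >= 1) {
    stop("flip rates must lie in [0, 1)")
  }
  local_seed(seed, {
    members <- lapply(seq_len(n), function(i) {
      u <- matrix(stats::runif(length(gt$values)), nrow(gt$values))
      v <- ifelse(gt$values, u >= flip_fn, u < flip_fp)
      binary_mask(v, role = gt$role, slide_id = gt$slide_id)
    })
    mask_stack(members, source_tags = paste0("corrupt", seq_len(n)))
  })
}
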