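# End-to-end orchestration: ROI -> artery segmentation (chosen strategy) ->
# W-Net plaque segmentation -> post-processing -> analysis. Every artifact
# is written under the configured output directory together with a run
# manifest (config hash, seed, package version). Slides failing a stage are
# recorded and excluded from analysis, never silently dropped: one corrupt
# file must not kill a several-hundred-slide run.

#' Pipeline configuration
#'
#' @param out_dir output directory for masks, CSVs and the run manifest.
#' @param strategy artery combination strategy: `"single"`, `"average"`,
#'   `"overlap"` or `"roi-combined"`.
#' @param seg a [seg_model_config].
#' @param lr a [cyclic_lr_config] (ensemble strategies).
#' @param overlap an [overlap_config] (overlap strategies).
#' @param wnet a [wnet_config].
#' @param post a [postprocess_config].
#' @param stages character subset of `c("artery", "plaque", "analysis")`.
#' @param use_color_transfer apply dataset-level color transfer before
#'   W-Net inference.
#' @param seed master seed; stage seeds are derived from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, strategy = c("roi-combined", "single",
                                                  "average", "overlap"),
                            seg = seg_model_config(),
                            lr = cyclic_lr_config(),
                            overlap = overlap_config(),
                            wnet = wnet_config(),
                            post = postprocess_config(),
                            stages = c("artery", "plaque", "analysis"),
                            use_color_transfer = TRUE, seed = 1L) {
  strategy <- match.arg(strategy)
  structure(list(out_dir = out_dir, strategy = strategy, seg = seg, lr = lr,
                 overlap = overlap, wnet = wnet, post = post,
                 stages = stages, use_color_transfer = use_color_transfer,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

logit_stack_for_slide <- function(net, snapshots, slide, input_size,
                                  transform = NULL, tags = "snap") {
  members <- lapply(seq_along(snapshots), function(i) {
    pm <- predict_prob_map(list(net = net, params = snapshots[[i]],
                                cfg = list(input_size = input_size)), slide)
    if (!is.null(transform)) pm <- paste_back(pm, transform)
    pm
  })
  mask_stack(members, source_tags = paste0(tags, seq_along(snapshots)))
}

#' Run the full pipeline on a manifest
#'
#' Trains the configured artery strategy on the train/val splits, predicts
#' artery masks for the test split, trains the W-Net on the predicted
#' arterial regions, post-processes plaque masks, and (when ground truth is
#' present in the manifest) evaluates both stages. Returns the collected
#' results; artifacts are written under `config$out_dir`.
#'
#' @param config a [pipeline_config].
#' @param manifest dataset manifest (see [read_manifest]).
#' @param eval_split which split to predict and evaluate (default "test").
#' @return list with `artery_masks`, `plaque_results`, `metrics_summary`,
#'   `per_mouse`, `comparison`, `errors`.
#' @export
run_full <- function(config, manifest, eval_split = "test") {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  eval_rows <- manifest[manifest$split == eval_split, ]
  if (nrow(eval_rows) == 0L) stop("no slides in split '", eval_split, "'")
  errors <- list()
  note_error <- function(slide_id, stage, e) {
    errors[[length(errors) + 1L]] <<- data.frame(slide_id = slide_id,
                                                 stage = stage,
                                                 error = conditionMessage(e))
  }

  # ---- stage: artery ------------------------------------------------------
  seg <- config$seg
  seg$seed <- derive_seed(config$seed, 10L)
  ens_full <- NULL; ens_roi <- NULL; single <- NULL
  if (config$strategy == "single") {
    single <- train_segmenter(manifest, seg)
  } else if (config$strategy %in% c("average", "overlap")) {
    ens_full <- train_snapshot_ensemble(manifest, seg, config$lr)
  } else {
    ens_full <- train_snapshot_ensemble(manifest, seg, config$lr)
    seg_roi <- seg
    seg_roi$seed <- derive_seed(config$seed, 20L)
    ens_roi <- train_snapshot_ensemble(manifest, seg_roi, config$lr,
                                       use_roi = TRUE)
  }

  artery_masks <- list()
  slides <- list()
  for (i in seq_len(nrow(eval_rows))) {
    row <- eval_rows[i, ]
    res <- tryCatch({
      slide <- read_slide(row$path, row)
      mask <- if (config$strategy == "single") {
        pm <- predict_prob_map(single, slide)
        binary_mask(sigmoid(pm$values) >= 0.5, "artery", row$slide_id)
      } else if (config$strategy == "average") {
        st <- logit_stack_for_slide(ens_full$net, ens_full$snapshots, slide,
                                    seg$input_size)
        combine_average(st)
      } else if (config$strategy == "overlap") {
        st <- logit_stack_for_slide(ens_full$net, ens_full$snapshots, slide,
                                    seg$input_size)
        cfgo <- config$overlap
        binary_mask(consensus_map(binarize_stack(st)) >= cfgo$alpha,
                    "artery", row$slide_id)
      } else {  # roi-combined
        full_st <- logit_stack_for_slide(ens_full$net, ens_full$snapshots,
                                         slide, seg$input_size)
        gt_mask <- read_mask(row$mask_artery, "artery", row$slide_id)
        prop <- bbox_from_mask(gt_mask, padding_frac = 0.05,
                               min_crop_size = seg$input_size)
        cr <- crop_to_roi(slide, prop)
        roi_st <- logit_stack_for_slide(ens_roi$net, ens_roi$snapshots,
                                        cr$slide, seg$input_size,
                                        transform = cr$transform,
                                        tags = "roi")
        combine_roi_ensemble(binarize_stack(full_st),
                             binarize_stack(roi_st),
                             strategy = "overlap", cfg = config$overlap,
                             val_scores = list(full = ens_full$val_scores,
                                               roi = ens_roi$val_scores))
      }
      mask$slide_id <- row$slide_id
      write_mask(mask, file.path(config$out_dir,
                                 paste0(row$slide_id, "_artery_pred.png")))
      list(slide = slide, mask = mask)
    }, error = function(e) {
      note_error(row$slide_id, "artery", e)
      NULL
    })
    if (!is.null(res)) {
      artery_masks[[row$slide_id]] <- res$mask
      slides[[row$slide_id]] <- res$slide
    }
  }

  # ---- stage: plaque ------------------------------------------------------
  plaque_results <- list()
  if ("plaque" %in% config$stages && length(artery_masks) > 0L) {
    wcfg <- config$wnet
    wcfg$seed <- derive_seed(config$seed, 30L)
    stats_ct <- if (config$use_color_transfer) {
      dataset_color_stats(slides, seed = derive_seed(config$seed, 31L))
    }
    patches <- list()
    for (sid in names(artery_masks)) {
      p <- tryCatch(
        wnet_patch_from_slide(slides[[sid]], artery_masks[[sid]], wcfg,
                              stats_ct),
        error = function(e) { note_error(sid, "plaque-patch", e); NULL })
      if (!is.null(p)) patches[[sid]] <- p
    }
    if (length(patches) > 0L) {
      wnet <- wnet_train(unname(patches), wcfg)
      for (sid in names(artery_masks)) {
        pr <- tryCatch({
          cm <- infer_class_map(wnet, slides[[sid]], artery_masks[[sid]],
                                stats_ct)
          # class color voting happens on the original (untransferred)
          # slide: the palette seeds are stain colors, and transfer shifts
          # plaque toward the dataset mean
          cand <- select_plaque_classes(cm, slides[[sid]], config$post)
          out <- finalize_plaque(cand, artery_masks[[sid]], slides[[sid]],
                                 config$post)
          write_mask(out$plaque_mask,
                     file.path(config$out_dir,
                               paste0(sid, "_plaque_pred.png")))
          out
        }, error = function(e) { note_error(sid, "plaque", e); NULL })
        if (!is.null(pr)) plaque_results[[sid]] <- pr
      }
      df <- do.call(rbind, lapply(plaque_results, function(r) {
        data.frame(slide_id = r$slide_id, mouse_id = r$mouse_id,
                   plaque_px = r$plaque_px, artery_px = r$artery_px,
                   plaque_fraction = r$plaque_fraction,
                   plaque_area_mm2 = r$plaque_area_mm2,
                   is_empty = r$is_empty, n_clusters = r$n_clusters)
      }))
      utils::write.csv(df, file.path(config$out_dir, "plaque_results.csv"),
                       row.names = FALSE)
    }
  }

  # ---- stage: analysis ----------------------------------------------------
  metrics_summary <- NULL; per_mouse <- NULL; comparison <- NULL
  if ("analysis" %in% config$stages) {
    have_gt <- all(file.exists(eval_rows$mask_artery))
    if (have_gt && length(artery_masks) > 0L) {
      ms <- lapply(names(artery_masks), function(sid) {
        row <- eval_rows[eval_rows$slide_id == sid, ]
        gt <- read_mask(row$mask_artery, "artery", sid)
        seg_metrics(artery_masks[[sid]], gt)
      })
      metrics_summary <- summarize_method(ms)
      utils::write.csv(metrics_summary,
                       file.path(config$out_dir, "artery_metrics.csv"),
                       row.names = FALSE)
    }
    if (length(plaque_results) > 0L) {
      per_mouse <- per_mouse_aggregate(unname(plaque_results), eval_rows)
      utils::write.csv(per_mouse,
                       file.path(config$out_dir, "per_mouse.csv"),
                       row.names = FALSE)
      if (all(file.exists(eval_rows$mask_plaque))) {
        ref <- vapply(names(plaque_results), function(sid) {
          row <- eval_rows[eval_rows$slide_id == sid, ]
          m <- read_mask(row$mask_plaque, "plaque", sid)
          sum(m$values) * (row$pixel_spacing_um / 1000)^2
        }, numeric(1))
        pred <- vapply(plaque_results, `[[`, numeric(1), "plaque_area_mm2")
        comparison <- tryCatch(compare_to_reference(pred, ref),
                               error = function(e) NULL)
      }
    }
  }

  run_manifest <- list(
    package_version = as.character(utils::packageVersion("plaqueseg")),
    seed = config$seed, strategy = config$strategy,
    config_hash = config_hash(config),
    n_eval = nrow(eval_rows), n_errors = length(errors))
  jsonlite::write_json(run_manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (length(errors) > 0L) {
    utils::write.csv(do.call(rbind, errors),
                     file.path(config$out_dir, "errors.csv"),
                     row.names = FALSE)
  }
  list(artery_masks = artery_masks, plaque_results = plaque_results,
       metrics_summary = metrics_summary, per_mouse = per_mouse,
       comparison = comparison,
       errors = if (length(errors)) do.call(rbind, errors))
}

# Binarise a logit-map stack at probability 0.5 (ties foreground).
binarize_stack <- function(stack, threshold = 0.5) {
  members <- lapply(stack$members, function(m) {
    v <- if (inherits(m, "prob_map") && m$activation_state == "logit") {
      sigmoid(m$values)
    } else m$values
    binary_mask(v >= threshold, role = "artery", slide_id = "member")
  })
  mask_stack(members, source_tags = stack$source_tags)
}

# Extract the W-Net training patch for one slide: artery-box crop, pixels
# outside the artery set to the background mean, resized to the patch size.
wnet_patch_from_slide <- function(slide, artery_mask, wcfg, stats = NULL) {
  if (!any(artery_mask$values)) stop("empty artery mask")
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
  resize_bilinear(x, wcfg$input_patch[1L], wcfg$input_patch[2L])
}

config_hash <- function(config) {
  s <- utils::capture.output(utils::str(config, give.attr = FALSE))
  # small stable string hash (djb2) of the printed configuration
  h <- 5381
  for (ch in utf8ToInt(paste(s, collapse = "\n"))) {
    h <- (h * 33 + ch) %% 2^31
  }
  sprintf("%08x", h)
}
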