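# End-to-end model interface in the classic fit/predict idiom: bdsk_fit()
# trains the segmentation network on a cohort manifest and calibrates the
# section-level operating point; the fitted object predicts section calls for
# new slides.

#' Fit the whole-slide BD/SK model on a cohort
#'
#' Builds the tile dataset (tissue detection, sectioning, overlapping tiles),
#' trains the reduced U-Net by focal-loss minimisation with a slide-level
#' 80/20 split, then calibrates the section-level operating point on the
#' combined training + validation sections: minimum-area line search by ROC
#' AUC and probability-threshold selection by F-beta (beta = 2 for the BD
#' call, beta = 1 for SK).
#'
#' @param manifest cohort manifest data frame (see [generate_cohort()] /
#'   [read_manifest()]).
#' @param input_side network/tile input side in px (divisible by 32).
#' @param preset encoder preset, `"small"` (CPU scale) or `"paper"`.
#' @param training a [training_config()].
#' @param min_overlap_um minimum tile overlap in microns.
#' @param min_section_area_mm2 section area filter.
#' @param mode decision mode, `"cascade"` or `"relative_area"`.
#' @param areas,thresholds calibration grids (see [area_grid()],
#'   [threshold_grid()]).
#' @param seed master seed (network init; training uses `training$seed`).
#' @param verbose print progress.
#' @return an object of class `bdsk_model` with components `network`,
#'   `history`, `calibration_bd`, `calibration_sk`, `params`
#'   (a [decision_params()]), `input_side`, `min_overlap_um`,
#'   `min_section_area_mm2`, `config_hash`.
#' @export
bdsk_fit <- function(manifest, input_side = 256L, preset = "small",
                     training = training_config(), min_overlap_um = 64,
                     min_section_area_mm2 = 0.01, mode = "cascade",
                     areas = area_grid(), thresholds = threshold_grid(),
                     seed = 1L, verbose = FALSE) {
  stopifnot(is.data.frame(manifest), nrow(manifest) > 0)
  dataset <- make_tile_dataset(manifest, input_side, min_overlap_um,
                               min_section_area_mm2)
  net <- build_network(network_config(input_side, preset), seed = seed)
  fit <- train(dataset, net, training, verbose = verbose)
  net <- fit$model

  # calibration sections: all slides, combined splits
  secs <- collect_section_maps(net, manifest, input_side, min_overlap_um,
                               min_section_area_mm2)
  truth <- vapply(secs, function(s) s$truth_class, "")
  is_bd <- truth == "BD"
  sk_subset <- truth != "BD"
  maps <- lapply(secs, function(s) s$map)
  cal_bd <- calibrate_call(maps, is_bd, "BD vs all", channel = 1L, beta = 2,
                           areas = areas, thresholds = thresholds)
  # SK calibrated against Normal when the cohort has Normal sections,
  # otherwise against the remaining (BD) sections
  sk_truth <- truth %in% c("SK", "SK_with_BD_focus")
  if (length(unique(sk_truth[sk_subset])) == 2) {
    cal_sk <- calibrate_call(maps[sk_subset], sk_truth[sk_subset],
                             "SK vs Normal", channel = 2L, beta = 1,
                             areas = areas, thresholds = thresholds)
  } else {
    cal_sk <- calibrate_call(maps, sk_truth, "SK vs rest", channel = 2L,
                             beta = 1, areas = areas, thresholds = thresholds)
  }
  params <- decision_params(threshold_bd = cal_bd$threshold,
                            threshold_sk = cal_sk$threshold,
                            min_area_bd = cal_bd$min_area_mm2,
                            min_area_sk = cal_sk$min_area_mm2,
                            mode = mode)
  obj <- structure(list(
    network = net, history = fit$history,
    calibration_bd = cal_bd, calibration_sk = cal_sk, params = params,
    input_side = as.integer(input_side), min_overlap_um = min_overlap_um,
    min_section_area_mm2 = min_section_area_mm2,
    n_slides = length(unique(manifest$slide_path)), seed = as.integer(seed)
  ), class = "bdsk_model")
  obj$config_hash <- config_hash(list(input_side, preset,
                                      unclass_deep(training), mode, seed))
  obj
}

#' Predict heat maps and calls for one slide
#'
#' @param model a `bdsk_model` (or a bare `bdsk_network`, with `params`
#'   supplied).
#' @param image H x W x 3 RGB array.
#' @param mpp microns per pixel of the image.
#' @param params [decision_params()] override (default: the model's).
#' @param min_section_area_mm2 section filter override.
#' @return list with `sections` (list of `bdsk_section`), `maps`
#'   (post-processed `bdsk_section_heatmap`s) and `calls`
#'   (list of `bdsk_section_call`).
#' @export
predict_slide <- function(model, image, mpp = 1, params = NULL,
                          min_section_area_mm2 = NULL) {
  net <- if (inherits(model, "bdsk_model")) model$network else model
  if (is.null(params)) {
    params <- if (inherits(model, "bdsk_model")) model$params else
      decision_params()
  }
  if (is.null(min_section_area_mm2)) {
    min_section_area_mm2 <- if (inherits(model, "bdsk_model"))
      model$min_section_area_mm2 else 0.01
  }
  overlap <- if (inherits(model, "bdsk_model")) model$min_overlap_um else 64
  input_side <- net$cfg$input_side
  tis <- detect_tissue(image, mpp)
  secs <- extract_sections(tis, min_section_area_mm2)
  maps <- list(); calls <- list()
  for (i in seq_along(secs)) {
    maps[[i]] <- section_heatmap(net, image, secs[[i]], input_side, overlap)
    calls[[i]] <- call_section(maps[[i]], params)
  }
  list(sections = secs, maps = maps, calls = calls)
}

# Predict + stitch + post-process one section.
section_heatmap <- function(net, image, section, input_side, min_overlap_um) {
  cfg <- tiling_config(tile_size_um = input_side * section$mpp,
                       min_overlap_um = min_overlap_um, mpp = section$mpp)
  plan <- plan_tiles(section, cfg)
  tms <- lapply(seq_len(nrow(plan)), function(i) {
    tile <- extract_tile(image, plan$x0[i], plan$y0[i], plan$side_px[i])
    predict_tile(net, tile, coord = c(plan$x0[i], plan$y0[i]))
  })
  postprocess(stitch_heatmaps(tms, section))
}

# Heat maps plus mask-derived truth for every section of a manifest.
collect_section_maps <- function(net, manifest, input_side, min_overlap_um,
                                 min_section_area_mm2) {
  out <- list()
  for (sp in unique(manifest$slide_path)) {
    rows <- manifest[manifest$slide_path == sp, ]
    mpp <- rows$mpp[1]
    img <- read_slide_image(sp)
    msk <- read_label_mask(rows$mask_path[1])
    tis <- detect_tissue(img, mpp)
    secs <- extract_sections(tis, min_section_area_mm2)
    for (sec in secs) {
      map <- section_heatmap(net, img, sec, input_side, min_overlap_um)
      tr <- section_truth_from_mask(msk, sec)
      out[[length(out) + 1L]] <- list(slide = sp, section_id = sec$id,
                                      map = map, truth_class = tr$class,
                                      truth_bd = tr$area_bd,
                                      truth_sk = tr$area_sk)
    }
  }
  out
}

# Ground-truth class and areas of a detected section, read off the label mask.
section_truth_from_mask <- function(mask, section) {
  bb <- section$bbox
  sub <- mask[(bb["y0"] + 1):bb["y1"], (bb["x0"] + 1):bb["x1"], drop = FALSE]
  sub <- sub * section$mask
  n_bd <- sum(sub == 1L); n_sk <- sum(sub == 2L)
  cls <- if (n_bd > 0 && n_sk > 0) "SK_with_BD_focus"
  else if (n_bd > 0) "BD" else if (n_sk > 0) "SK" else "Normal"
  list(class = cls,
       area_bd = pixels_to_mm2(n_bd, section$mpp),
       area_sk = pixels_to_mm2(n_sk, section$mpp))
}

#' @export
print.bdsk_model <- function(x, ...) {
  cat("Whole-slide BD/SK segmentation model\n")
  print(x$network)
  cat(sprintf("trained on %d slides; best validation IoU %.3f\n",
              x$n_slides, max(x$history$val_iou, na.rm = TRUE)))
  print(x$calibration_bd)
  print(x$calibration_sk)
  cat(sprintf("decision mode: %s (config %s)\n", x$params$mode, x$config_hash))
  invisible(x)
}

#' @export
summary.bdsk_model <- function(object, ...) {
  structure(list(model = object), class = "summary.bdsk_model")
}

#' @export
print.summary.bdsk_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(m$history, 5), row.names = FALSE)
  cat("\nOperating point:\n")
  print(coef(m))
  invisible(x)
}

#' Calibrated operating-point parameters of a fitted model
#' @param object a `bdsk_model`.
#' @param ... unused.
#' @return named numeric vector.
#' @export
coef.bdsk_model <- function(object, ...) {
  p <- object$params
  c(threshold_bd = p$threshold_bd, threshold_sk = p$threshold_sk,
    min_area_bd_mm2 = p$min_area_bd, min_area_sk_mm2 = p$min_area_sk,
    relative_area_cutoff = p$relative_area_cutoff)
}

#' Plot training history or calibration curves
#'
#' @param x a `bdsk_model`.
#' @param which `"history"` (per-epoch IoU and loss), `"area"` (AUC vs
#'   candidate minimum area) or `"threshold"` (F-beta vs threshold).
#' @param ... passed to the underlying plot.
#' @export
plot.bdsk_model <- function(x, which = c("history", "area", "threshold"),
                            ...) {
  which <- match.arg(which)
  if (which == "history") {
    h <- x$history
    plot(h$epoch, h$val_iou, type = "b", ylim = c(0, 1), xlab = "epoch",
         ylab = "IoU", pch = 19, ...)
    graphics::lines(h$epoch, h$train_iou, type = "b", lty = 2, pch = 1)
    graphics::legend("bottomright", c("validation", "training"),
                     lty = c(1, 2), pch = c(19, 1), bty = "n")
  } else if (which == "area") {
    g <- x$calibration_bd$area_grid
    plot(g$area_mm2, g$auc, log = "x", type = "b",
         xlab = "minimum area (mm^2)", ylab = "AUC", ...)
    graphics::points(x$calibration_bd$min_area_mm2, x$calibration_bd$auc,
                     pch = 19)
  } else {
    g <- x$calibration_bd$threshold_grid
    plot(g$threshold, g$fbeta, type = "b", xlab = "threshold",
         ylab = "F-beta", ...)
    graphics::points(x$calibration_bd$threshold, x$calibration_bd$fbeta,
                     pch = 19)
  }
  invisible(x)
}

#' Predict section calls for new slides
#'
#' @param object a fitted `bdsk_model`.
#' @param newdata a manifest data frame (columns `slide_path`, `mpp`; one row
#'   per section or per slide) or a character vector of image paths (mpp 1).
#' @param mode decision-mode override (`"cascade"` or `"relative_area"`).
#' @param ... unused.
#' @return data frame with one row per detected section: `slide_path`,
#'   `section_id`, `area_bd_mm2`, `area_sk_mm2`, `r_percent`, `label`,
#'   `score_bd`, `score_sk` (per-section ROC scores at the calibrated minimum
#'   areas), `mode`, `params_hash`.
#' @export
predict.bdsk_model <- function(object, newdata, mode = NULL, ...) {
  if (is.character(newdata)) {
    newdata <- data.frame(slide_path = newdata, mpp = 1,
                          stringsAsFactors = FALSE)
  }
  params <- object$params
  if (!is.null(mode)) {
    params$mode <- match.arg(mode, c("cascade", "relative_area"))
  }
  phash <- config_hash(unclass_deep(params))
  rows <- list()
  for (sp in unique(newdata$slide_path)) {
    mpp <- newdata$mpp[newdata$slide_path == sp][1]
    img <- read_slide_image(sp)
    pred <- predict_slide(object, img, mpp, params = params)
    for (i in seq_along(pred$calls)) {
      cl <- pred$calls[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        slide_path = sp, section_id = cl$section_id,
        area_bd_mm2 = cl$area_bd_mm2, area_sk_mm2 = cl$area_sk_mm2,
        r_percent = cl$r_percent, label = cl$label,
        score_bd = section_score(pred$maps[[i]], params$min_area_bd, 1L),
        score_sk = section_score(pred$maps[[i]], params$min_area_sk, 2L),
        mode = params$mode, params_hash = phash,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Evaluate a fitted model on a labelled cohort
#'
#' Predicts every slide of the manifest, derives per-section truth from the
#' label masks, and computes AUC / sensitivity / specificity for the requested
#' comparisons.
#'
#' @param model a `bdsk_model`.
#' @param manifest labelled manifest (with `mask_path`).
#' @param call_specs comparisons to evaluate (see [evaluate_calls()]).
#' @param mode decision-mode override.
#' @return list with `metrics` (one row per comparison) and `sections`
#'   (per-section calls, scores and truth).
#' @export
evaluate_model <- function(model, manifest,
                           call_specs = c("BD vs all", "BD vs SK",
                                          "SK vs Normal"),
                           mode = NULL) {
  params <- model$params
  if (!is.null(mode)) params$mode <- match.arg(mode,
                                               c("cascade", "relative_area"))
  secs <- collect_section_maps(model$network, manifest, model$input_side,
                               model$min_overlap_um,
                               model$min_section_area_mm2)
  calls <- vapply(secs, function(s) call_section(s$map, params)$label, "")
  truth <- vapply(secs, function(s) s$truth_class, "")
  score_bd <- vapply(secs, function(s)
    section_score(s$map, params$min_area_bd, 1L), 0)
  score_sk <- vapply(secs, function(s)
    section_score(s$map, params$min_area_sk, 2L), 0)
  metrics <- do.call(rbind, lapply(call_specs, function(cs) {
    sc <- if (cs == "SK vs Normal") score_sk else score_bd
    evaluate_calls(calls, truth, cs, scores = sc)
  }))
  sections <- data.frame(
    slide = vapply(secs, function(s) s$slide, ""),
    section_id = vapply(secs, function(s) s$section_id, 0L),
    truth = truth, call = calls, score_bd = score_bd, score_sk = score_sk,
    stringsAsFactors = FALSE)
  list(metrics = metrics, sections = sections)
}

#' Calibration summary of a fitted model
#'
#' One row per calibrated call with the selected minimum area and threshold
#' and their scores, in the layout of an operating-point report table.
#'
#' @param model a `bdsk_model`.
#' @param path optional CSV path; when given the table is also written there.
#' @return data frame with columns `call, auc, min_area_mm2, threshold,
#'   fbeta, beta`.
#' @export
calibration_table <- function(model, path = NULL) {
  stopifnot(inherits(model, "bdsk_model"))
  rows <- lapply(list(model$calibration_bd, model$calibration_sk), function(c0) {
    data.frame(call = c0$call, auc = c0$auc, min_area_mm2 = c0$min_area_mm2,
               threshold = c0$threshold, fbeta = c0$fbeta, beta = c0$beta,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' Render a probability-overlay image
#'
#' BD is rendered yellow and SK orange over the slide, with per-pixel alpha
#' equal to the predicted probability (zero probability is fully transparent).
#' Heat maps are up-sampled to slide resolution by nearest neighbour, keeping
#' the 8 px block structure of the output stride visible.
#'
#' @param image H x W x 3 slide RGB array.
#' @param maps list of `bdsk_section_heatmap`s for the slide.
#' @param palette list with `bd` and `sk` RGB triples in \[0,1\].
#' @return H x W x 4 RGBA array (the overlay alone, composited over
#'   transparency).
#' @export
render_overlay <- function(image, maps,
                           palette = list(bd = c(1, 1, 0),
                                          sk = c(1, 0.65, 0))) {
  stopifnot(is_rgb_array(image))
  H <- dim(image)[1]; W <- dim(image)[2]
  out <- array(0, c(H, W, 4))
  for (map in maps) {
    bb <- map$bbox
    for (ch in 1:2) {
      pm <- map$probs[, , ch]
      up <- pm[rep(seq_len(nrow(pm)), each = 8), rep(seq_len(ncol(pm)),
                                                     each = 8), drop = FALSE]
      ys <- (bb["y0"] + 1):min(bb["y0"] + nrow(up), H)
      xs <- (bb["x0"] + 1):min(bb["x0"] + ncol(up), W)
      up <- up[seq_along(ys), seq_along(xs), drop = FALSE]
      col <- if (ch == 1) palette$bd else palette$sk
      alpha <- out[ys, xs, 4]
      take <- up > alpha  # per pixel, keep the more probable class
      for (c3 in 1:3) {
        plane <- out[ys, xs, c3]
        plane[take] <- col[c3]
        out[ys, xs, c3] <- plane
      }
      alpha[take] <- up[take]
      out[ys, xs, 4] <- alpha
    }
  }
  out
}
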