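# Supervised training: focal loss, IoU monitoring, slide-level splitting,
# paired augmentation, Adam optimisation.

#' Training configuration
#'
#' @param gamma focal-loss focusing parameter (default 2).
#' @param lr initial Adam learning rate (default 1e-4); decays per epoch on a
#'   cosine schedule when `lr_decay` is `TRUE`.
#' @param lr_decay cosine-anneal the learning rate over the epochs.
#' @param batch_size tiles per optimisation step.
#' @param epochs number of epochs (default 40).
#' @param augment logical, or an [augment_config()] for fine control.
#' @param split_fraction slide-level training fraction (default 0.8).
#' @param seed seed controlling the split, shuffling and augmentation.
#' @return an object of class `bdsk_training_config`.
#' @export
training_config <- function(gamma = 2, lr = 1e-4, batch_size = 8L,
                            epochs = 40L, augment = TRUE,
                            split_fraction = 0.8, seed = 1L,
                            lr_decay = TRUE) {
  stopifnot(gamma >= 0, lr > 0, batch_size >= 1, epochs >= 1,
            split_fraction > 0, split_fraction < 1)
  if (isTRUE(augment)) augment <- augment_config()
  if (isFALSE(augment)) augment <- augment_config(rotate = FALSE, flip = FALSE,
                                                  elastic = FALSE, noise = FALSE,
                                                  blur = FALSE, photometric = FALSE)
  structure(list(gamma = gamma, lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), augment = augment,
                 split_fraction = split_fraction, seed = as.integer(seed),
                 lr_decay = isTRUE(lr_decay)),
            class = "bdsk_training_config")
}

#' Serialize / restore a training configuration (YAML)
#' @param cfg a [training_config()].
#' @param path file path.
#' @return `write_training_config` returns the path invisibly;
#'   `read_training_config` the restored object.
#' @export
write_training_config <- function(cfg, path) {
  yaml::write_yaml(unclass_deep(cfg), path)
  invisible(path)
}

#' @rdname write_training_config
#' @export
read_training_config <- function(path) {
  v <- yaml::read_yaml(path)
  training_config(gamma = v$gamma, lr = v$lr, batch_size = v$batch_size,
                  epochs = v$epochs,
                  augment = do.call(augment_config, v$augment),
                  split_fraction = v$split_fraction, seed = v$seed,
                  lr_decay = v$lr_decay)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Focal loss
#'
#' \eqn{FL(p_t) = -(1 - p_t)^\gamma \log(p_t)} averaged over all pixels and
#' channels, with \eqn{p_t} the predicted probability of the true class.
#' At \eqn{\gamma = 0} this is the mean binary cross-entropy.
#'
#' @param pred array of probabilities in \[0,1\].
#' @param target array of binary targets, same shape.
#' @param gamma focusing parameter, >= 0.
#' @param eps clamp applied to `pred` for numerical stability.
#' @return scalar loss >= 0.
#' @export
focal_loss <- function(pred, target, gamma = 2, eps = 1e-7) {
  if (!identical(dim(pred), dim(target)) &&
      length(pred) != length(target)) {
    stop("prediction and target shapes differ")
  }
  if (!is.null(dim(pred)) && !is.null(dim(target)) &&
      !identical(dim(pred), dim(target))) {
    stop("prediction and target shapes differ")
  }
  p <- pmin(pmax(pred, eps), 1 - eps)
  pt <- ifelse(target > 0.5, p, 1 - p)
  mean(-(1 - pt)^gamma * log(pt))
}

# d focal_loss / d pred (per element, including the 1/N of the mean).
focal_grad <- function(pred, target, gamma = 2, eps = 1e-7) {
  p <- pmin(pmax(pred, eps), 1 - eps)
  pos <- target > 0.5
  g <- array(0, dim(pred) %||% length(pred))
  # y = 1: L = -(1-p)^g log p
  gp <- gamma * (1 - p)^(pmax(gamma - 1, 0)) * log(p) - (1 - p)^gamma / p
  # y = 0: L = -p^g log(1-p)
  gn <- -gamma * p^(pmax(gamma - 1, 0)) * log(1 - p) + p^gamma / (1 - p)
  g[pos] <- gp[pos]
  g[!pos] <- gn[!pos]
  inside <- pred > eps & pred < 1 - eps  # clamp region has zero gradient
  g * inside / length(pred)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intersection over union
#'
#' @param pred,target binary (logical or 0/1) arrays of the same shape.
#' @return IoU in \[0,1\]; defined as 1 when both are empty.
#' @export
iou <- function(pred, target) {
  p <- as.logical(pred); t0 <- as.logical(target)
  u <- sum(p | t0)
  if (u == 0) return(1)
  sum(p & t0) / u
}

# Block-max downsample of an integer label mask into the two-channel target at
# the output stride: an output pixel is positive if any covered input pixel is.
downsample_labels <- function(mask, factor = 8L, classes = c(1L, 2L)) {
  H <- nrow(mask); W <- ncol(mask)
  stopifnot(H %% factor == 0, W %% factor == 0)
  A <- kronecker(diag(H / factor), matrix(1, 1, factor))   # (H/f) x H
  B <- kronecker(diag(W / factor), matrix(1, factor, 1))   # W x (W/f)
  out <- array(0, c(H / factor, W / factor, length(classes)))
  for (i in seq_along(classes)) {
    s <- A %*% (mask == classes[i]) %*% B
    out[, , i] <- (s > 0) * 1
  }
  out
}

# --- augmentation ------------------------------------------------------------

#' Augmentation configuration
#'
#' Geometric transforms (rotation, flips, elastic deformation) are applied
#' identically to tile and mask (mask by nearest neighbour); photometric
#' transforms (noise, blur, brightness/contrast/colour) touch the tile only.
#'
#' @param rotate random multiples of 90 degrees.
#' @param flip random horizontal/vertical flips.
#' @param elastic random elastic deformation.
#' @param elastic_amp displacement amplitude in px.
#' @param noise additive Gaussian noise on the tile.
#' @param noise_sd noise standard deviation.
#' @param blur random light Gaussian blur.
#' @param photometric random brightness/contrast/per-channel colour scaling.
#' @return an object of class `bdsk_augment_config`.
#' @export
augment_config <- function(rotate = TRUE, flip = TRUE, elastic = TRUE,
                           elastic_amp = 2, noise = TRUE, noise_sd = 0.02,
                           blur = TRUE, photometric = TRUE) {
  structure(list(rotate = rotate, flip = flip, elastic = elastic,
                 elastic_amp = elastic_amp, noise = noise,
                 noise_sd = noise_sd, blur = blur, photometric = photometric),
            class = "bdsk_augment_config")
}

rot90m <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

rot90a <- function(a, k) {
  k <- k %% 4L
  if (k == 0L) return(a)
  if (is.matrix(a)) {
    for (i in seq_len(k)) a <- rot90m(a)
    return(a)
  }
  out <- a
  for (i in seq_len(k)) {
    d <- dim(out)
    new <- array(0, c(d[2], d[1], d[3]))
    for (c in seq_len(d[3])) new[, , c] <- rot90m(out[, , c])
    out <- new
  }
  out
}

flipa <- function(a, horizontal) {
  if (is.matrix(a)) {
    if (horizontal) a[, rev(seq_len(ncol(a))), drop = FALSE]
    else a[rev(seq_len(nrow(a))), , drop = FALSE]
  } else {
    if (horizontal) a[, rev(seq_len(ncol(a))), , drop = FALSE]
    else a[rev(seq_len(nrow(a))), , , drop = FALSE]
  }
}

# Sample a field at (row + dy, col + dx); bilinear for images, nearest for
# masks. Coordinates clamped to the raster.
warp_field <- function(m, dx, dy, nearest) {
  H <- nrow(m); W <- ncol(m)
  rows <- matrix(seq_len(H), H, W) + dy
  cols <- matrix(rep(seq_len(W), each = H), H, W) + dx
  rows <- pmin(pmax(rows, 1), H); cols <- pmin(pmax(cols, 1), W)
  if (nearest) {
    return(matrix(m[cbind(as.vector(round(rows)), as.vector(round(cols)))],
                  H, W))
  }
  r0 <- floor(rows); c0 <- floor(cols)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- rows - r0; fc <- cols - c0
  v00 <- m[cbind(as.vector(r0), as.vector(c0))]
  v01 <- m[cbind(as.vector(r0), as.vector(c1))]
  v10 <- m[cbind(as.vector(r1), as.vector(c0))]
  v11 <- m[cbind(as.vector(r1), as.vector(c1))]
  matrix(v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
           v10 * fr * (1 - fc) + v11 * fr * fc, H, W)
}

#' Paired augmentation of a tile and its label mask
#'
#' @param tile H x W x 3 array in \[0,1\].
#' @param mask H x W integer label matrix.
#' @param seed seed for the random draws.
#' @param config an [augment_config()]; with everything disabled the inputs
#'   are returned unchanged.
#' @return list with `tile` and `mask`.
#' @export
augment <- function(tile, mask, seed = 1L, config = augment_config()) {
  stopifnot(is_rgb_array(tile), is.matrix(mask),
            all(dim(tile)[1:2] == dim(mask)))
  if (!config$rotate && !config$flip && !config$elastic && !config$noise &&
      !config$blur && !config$photometric) {
    return(list(tile = tile, mask = mask))
  }
  with_seed(seed, {
    if (config$rotate) {
      k <- sample(0:3, 1)
      tile <- rot90a(tile, k); mask <- rot90a(mask, k)
    }
    if (config$flip) {
      if (runif(1) < 0.5) { tile <- flipa(tile, TRUE); mask <- flipa(mask, TRUE) }
      if (runif(1) < 0.5) { tile <- flipa(tile, FALSE); mask <- flipa(mask, FALSE) }
    }
    if (config$elastic && config$elastic_amp > 0) {
      H <- nrow(mask); W <- ncol(mask)
      dx <- as.matrix(EBImage::gblur(matrix(rnorm(H * W), H, W), 8))
      dy <- as.matrix(EBImage::gblur(matrix(rnorm(H * W), H, W), 8))
      sc <- config$elastic_amp / max(max(abs(dx)), max(abs(dy)), 1e-9)
      dx <- dx * sc; dy <- dy * sc
      for (c in 1:3) tile[, , c] <- warp_field(tile[, , c], dx, dy, FALSE)
      mask <- matrix(as.integer(warp_field(mask, dx, dy, TRUE)),
                     nrow(mask), ncol(mask))
    }
    if (config$blur && runif(1) < 0.5) {
      sg <- runif(1, 0.3, 0.8)
      for (c in 1:3) tile[, , c] <- as.matrix(EBImage::gblur(tile[, , c], sg))
    }
    if (config$photometric) {
      bright <- runif(1, 0.92, 1.08); contr <- runif(1, 0.92, 1.08)
      colsc <- runif(3, 0.96, 1.04)
      for (c in 1:3) {
        tile[, , c] <- ((tile[, , c] * colsc[c] - 0.5) * contr + 0.5) * bright
      }
    }
    if (config$noise && config$noise_sd > 0) {
      tile <- tile + array(rnorm(length(tile), 0, config$noise_sd), dim(tile))
    }
    tile <- clamp01(tile)
    list(tile = tile, mask = mask)
  })
}

# --- dataset construction & split -------------------------------------------

#' Build a tile dataset from a cohort manifest
#'
#' For every slide: detect tissue, extract sections, plan tiles at the
#' network's input side, and pair each tile with its focal-loss target (the
#' label mask block-max downsampled to the output stride).
#'
#' @param manifest manifest data frame (see [generate_cohort()]).
#' @param input_side tile/network input side in px.
#' @param min_overlap_um minimum tile overlap in microns.
#' @param min_section_area_mm2 section area filter.
#' @return list of samples, each `list(x, y, slide, section_id, coord)`.
#' @export
make_tile_dataset <- function(manifest, input_side = 256L,
                              min_overlap_um = 64,
                              min_section_area_mm2 = 0.01) {
  samples <- list()
  for (sp in unique(manifest$slide_path)) {
    rows <- manifest[manifest$slide_path == sp, ]
    mpp <- rows$mpp[1]
    img <- read_slide_image(sp)
    msk <- read_label_mask(rows$mask_path[1])
    tis <- detect_tissue(img, mpp)
    secs <- extract_sections(tis, min_section_area_mm2)
    cfg <- tiling_config(tile_size_um = input_side * mpp,
                         min_overlap_um = min_overlap_um, mpp = mpp)
    for (sec in secs) {
      plan <- plan_tiles(sec, cfg)
      for (i in seq_len(nrow(plan))) {
        x <- extract_tile(img, plan$x0[i], plan$y0[i], plan$side_px[i])
        m <- extract_tile(msk, plan$x0[i], plan$y0[i], plan$side_px[i])
        samples[[length(samples) + 1L]] <- list(
          x = x, y = downsample_labels(m), mask = m, slide = sp,
          section_id = sec$id, coord = c(plan$x0[i], plan$y0[i])
        )
      }
    }
  }
  samples
}

#' Slide-level train/validation split
#'
#' All tiles from the same slide end up on the same side of the split; the
#' tile fraction approximates the requested fraction within one slide's worth.
#'
#' @param dataset list of samples (each with a `slide` field) or a data frame
#'   with a `slide_path` column.
#' @param fraction training fraction in (0, 1).
#' @param seed seed for the slide shuffle.
#' @return list with `train` and `val` subsets of the input.
#' @export
split_by_slide <- function(dataset, fraction = 0.8, seed = 1L) {
  slides <- if (is.data.frame(dataset)) dataset$slide_path else
    vapply(dataset, function(s) s$slide, "")
  if (length(slides) == 0) stop("empty dataset")
  uniq <- unique(slides)
  if (length(uniq) < 2) stop("need at least two slides for a slide-level split")
  ord <- with_seed(seed, sample(uniq))
  counts <- vapply(ord, function(u) sum(slides == u), 0)
  cum <- cumsum(counts) / length(slides)
  k <- which.min(abs(cum - fraction))
  k <- min(max(k, 1L), length(uniq) - 1L)
  train_slides <- ord[seq_len(k)]
  sel <- slides %in% train_slides
  if (is.data.frame(dataset)) {
    list(train = dataset[sel, , drop = FALSE],
         val = dataset[!sel, , drop = FALSE])
  } else {
    list(train = dataset[sel], val = dataset[!sel])
  }
}

# --- optimiser & training loop ----------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(mw = p$w * 0, vw = p$w * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mw <- b1 * s$mw + (1 - b1) * g$w
    s$vw <- b2 * s$vw + (1 - b2) * g$w^2
    s$mb <- b1 * s$mb + (1 - b1) * g$b
    s$vb <- b2 * s$vb + (1 - b2) * g$b^2
    params[[nm]]$w <- params[[nm]]$w - lr * (s$mw / c1) / (sqrt(s$vw / c2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

eval_iou <- function(net, samples, threshold = 0.5) {
  if (length(samples) == 0) return(NA_real_)
  inter <- 0; uni <- 0
  for (s in samples) {
    p <- net_forward(net, s$x)$out >= threshold
    t0 <- s$y > 0.5
    inter <- inter + sum(p & t0)
    uni <- uni + sum(p | t0)
  }
  if (uni == 0) 1 else inter / uni
}

#' Train the segmentation network
#'
#' Adam optimisation of the focal loss with slide-level 80/20 splitting,
#' per-epoch IoU monitoring on both splits, and selection of the epoch with
#' the best validation IoU.
#'
#' @param dataset tile dataset from [make_tile_dataset()] (>= 2 slides), or a
#'   list with pre-split `train` and `val` components.
#' @param net a `bdsk_network` from [build_network()].
#' @param cfg a [training_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (the network carrying the best-validation
#'   weights) and `history` (data frame: epoch, loss, train_iou, val_iou).
#' @export
train <- function(dataset, net, cfg = training_config(), verbose = FALSE) {
  stopifnot(inherits(net, "bdsk_network"),
            inherits(cfg, "bdsk_training_config"))
  if (length(dataset) == 0) stop("empty dataset")
  if (!is.null(dataset$train)) {
    tr <- dataset$train; va <- dataset$val
  } else {
    sp <- split_by_slide(dataset, cfg$split_fraction, cfg$seed)
    tr <- sp$train; va <- sp$val
  }
  if (length(tr) == 0) stop("empty training split")
  params <- net$params
  state <- adam_init(params)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     train_iou = numeric(), val_iou = numeric())
  best <- list(iou = -Inf, params = params)
  t_step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    lr_ep <- if (cfg$lr_decay && cfg$epochs > 1) {
      cfg$lr * 0.5 * (1 + cos(pi * (ep - 1) / (cfg$epochs - 1)))
    } else cfg$lr
    ord <- with_seed(child_seed(cfg$seed, ep), sample(seq_along(tr)))
    losses <- c(); inter <- 0; uni <- 0
    i <- 1L
    while (i <= length(ord)) {
      idx <- ord[i:min(i + cfg$batch_size - 1L, length(ord))]
      grads <- NULL
      for (j in idx) {
        s <- tr[[j]]
        aug <- augment(s$x, s$mask, seed = child_seed(cfg$seed, ep * 100000L + j),
                       config = cfg$augment)
        x <- aug$tile
        y <- downsample_labels(aug$mask)
        net$params <- params
        fwd <- net_forward(net, x)
        losses <- c(losses, focal_loss(fwd$out, y, cfg$gamma))
        pb <- fwd$out >= 0.5; tb <- y > 0.5
        inter <- inter + sum(pb & tb); uni <- uni + sum(pb | tb)
        g <- net_backward(net, fwd, focal_grad(fwd$out, y, cfg$gamma))
        grads <- if (is.null(grads)) g else {
          for (nm in names(g)) {
            grads[[nm]]$w <- grads[[nm]]$w + g[[nm]]$w
            grads[[nm]]$b <- grads[[nm]]$b + g[[nm]]$b
          }
          grads
        }
      }
      for (nm in names(grads)) {
        grads[[nm]]$w <- grads[[nm]]$w / length(idx)
        grads[[nm]]$b <- grads[[nm]]$b / length(idx)
      }
      t_step <- t_step + 1L
      upd <- adam_step(params, grads, state, lr_ep, t_step)
      params <- upd$params; state <- upd$state
      i <- i + cfg$batch_size
    }
    net$params <- params
    viou <- eval_iou(net, va)
    triou <- if (uni == 0) 1 else inter / uni
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   train_iou = triou, val_iou = viou))
    if (!is.na(viou) && viou > best$iou) best <- list(iou = viou, params = params)
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f train IoU %.3f val IoU %.3f",
                      ep, mean(losses), triou, viou))
    }
  }
  net$params <- if (is.finite(best$iou)) best$params else params
  list(model = net, history = hist)
}

#' Save / load network weights
#'
#' Weights go to R's native serialisation; the architecture configuration is
#' written alongside as JSON so the file is self-describing.
#'
#' @param net a `bdsk_network`.
#' @param path weights path (`.rds`); the config is written to
#'   `paste0(path, ".json")`.
#' @return `save_network` the path invisibly; `load_network` the network.
#' @export
save_network <- function(net, path) {
  saveRDS(net, path)
  jsonlite::write_json(
    list(preset = net$cfg$preset, input_side = net$cfg$input_side,
         output_stride = net$cfg$output_stride,
         out_channels = net$cfg$out_channels,
         shapes = net$shapes),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  readRDS(path)
}
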