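# Synthetic pseudo-histology slides with known pixel- and section-level truth.
#
# The generator emulates multi-section H&E-like slides: a near-white background,
# star-convex tissue blobs filled with correlated pink/purple noise, and lesion
# regions whose texture statistics differ by class (elongated dark streaks for
# Bowen's disease, bright round "horn pseudocyst" dots for seborrheic
# keratosis). A separability knob in (0,1] scales the texture contrast between
# lesion and surrounding tissue. Everything is seeded and deterministic.

CLASS_LEVELS <- c("Normal", "BD", "SK", "SK_with_BD_focus")

#' Style parameters for synthetic slides
#'
#' Bounded photometric perturbations emulating stain/scanner variation between
#' laboratories. The identity style (all defaults) leaves pixels unchanged.
#'
#' @param hue_shift hue rotation as a fraction of a full turn, in \[-0.5, 0.5\].
#' @param sat_shift additive saturation shift in \[-1, 1\].
#' @param brightness multiplicative brightness scale in \[0, 2\].
#' @param contrast multiplicative contrast scale about mid-grey, in \[0, 2\].
#' @param tint length-3 additive tint, weighted by pixel luminance so the
#'   near-white background is tinted most; each component in \[-0.2, 0.2\].
#' @param noise_sd standard deviation of additive Gaussian pixel noise, in
#'   \[0, 0.2\].
#' @return an object of class `bdsk_style`.
#' @export
style_params <- function(hue_shift = 0, sat_shift = 0, brightness = 1,
                         contrast = 1, tint = c(0, 0, 0), noise_sd = 0) {
  stopifnot(
    abs(hue_shift) <= 0.5, abs(sat_shift) <= 1,
    brightness >= 0, brightness <= 2, contrast >= 0, contrast <= 2,
    length(tint) == 3, all(abs(tint) <= 0.2), noise_sd >= 0, noise_sd <= 0.2
  )
  structure(list(hue_shift = hue_shift, sat_shift = sat_shift,
                 brightness = brightness, contrast = contrast,
                 tint = as.numeric(tint), noise_sd = noise_sd),
            class = "bdsk_style")
}

is_identity_style <- function(s) {
  s$hue_shift == 0 && s$sat_shift == 0 && s$brightness == 1 &&
    s$contrast == 1 && all(s$tint == 0) && s$noise_sd == 0
}

#' Request one synthetic tissue section
#'
#' @param class one of `"Normal"`, `"BD"`, `"SK"`, `"SK_with_BD_focus"`.
#' @param lesion_area_mm2 target lesion area in mm^2 (ignored for Normal).
#' @param separability texture contrast between lesion and base tissue, in
#'   (0, 1].
#' @param footprint_area_mm2 tissue footprint area; default scales with the
#'   lesion so the lesion fills roughly 45 percent of the section.
#' @param focus_fraction for `"SK_with_BD_focus"`, fraction of the lesion area
#'   occupied by the small BD focus (irritated-SK / collision-tumour stand-in).
#' @return an object of class `bdsk_section_request`.
#' @export
section_request <- function(class = "BD", lesion_area_mm2 = 0.02,
                            separability = 0.9, footprint_area_mm2 = NULL,
                            focus_fraction = 0.05) {
  class <- match.arg(class, CLASS_LEVELS)
  stopifnot(lesion_area_mm2 >= 0, separability > 0, separability <= 1,
            focus_fraction > 0, focus_fraction < 1)
  if (is.null(footprint_area_mm2)) {
    footprint_area_mm2 <- max(lesion_area_mm2 / 0.45, 0.04)
  }
  stopifnot(footprint_area_mm2 >= lesion_area_mm2)
  structure(list(class = class, lesion_area_mm2 = lesion_area_mm2,
                 separability = separability,
                 footprint_area_mm2 = footprint_area_mm2,
                 focus_fraction = focus_fraction),
            class = "bdsk_section_request")
}

#' Specification of a synthetic slide
#'
#' @param canvas_size_px integer `(width, height)` of the slide raster.
#' @param mpp microns per pixel (default 1, emulating 10x magnification).
#' @param sections list of [section_request()] objects (may be empty).
#' @param style a [style_params()] object applied after rendering.
#' @param seed integer seed; a fixed spec + seed is bit-reproducible.
#' @return an object of class `bdsk_slide_spec`.
#' @export
synthetic_slide_spec <- function(canvas_size_px = c(512L, 512L), mpp = 1,
                                 sections = list(), style = style_params(),
                                 seed = 1L) {
  stopifnot(length(canvas_size_px) == 2, all(canvas_size_px >= 1), mpp > 0,
            inherits(style, "bdsk_style"))
  sections <- lapply(sections, function(s) {
    stopifnot(inherits(s, "bdsk_section_request"))
    s
  })
  canvas_mm2 <- pixels_to_mm2(prod(canvas_size_px), mpp)
  total <- sum(vapply(sections, function(s) s$footprint_area_mm2, 0))
  if (total > 0.6 * canvas_mm2) {
    stop("requested section areas do not fit inside the canvas")
  }
  structure(list(canvas_size_px = as.integer(canvas_size_px), mpp = mpp,
                 sections = sections, style = style, seed = as.integer(seed)),
            class = "bdsk_slide_spec")
}

# Star-convex radial profile with low-order harmonics; bounded away from zero
# so blobs stay connected.
radial_profile <- function(theta, harm) {
  f <- rep(1, length(theta))
  for (k in seq_along(harm$c)) {
    f <- f + harm$amp * (harm$c[k] * cos((k + 1) * theta) +
                           harm$s[k] * sin((k + 1) * theta))
  }
  pmax(f, 0.25)
}

new_harmonics <- function(n = 4, amp = 0.12) {
  list(c = rnorm(n, 0, 0.6), s = rnorm(n, 0, 0.6), amp = amp)
}

# Rasterize a star-convex blob centred at (cx, cy) (1-based, col/row), hitting
# the requested pixel area within ~2 percent by radius rescaling.
rasterize_blob <- function(cx, cy, target_px, H, W, harm) {
  R0 <- sqrt(target_px / pi)
  mask <- NULL; x0 <- y0 <- 1L
  for (iter in 1:4) {
    Rmax <- R0 * (1 + 3 * harm$amp)
    x0 <- max(1L, floor(cx - Rmax)); x1 <- min(W, ceiling(cx + Rmax))
    y0 <- max(1L, floor(cy - Rmax)); y1 <- min(H, ceiling(cy + Rmax))
    xs <- x0:x1; ys <- y0:y1
    dx <- matrix(xs - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    dy <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
    r <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    mask <- r <= R0 * radial_profile(th, harm)
    area <- sum(mask)
    if (abs(area - target_px) <= 0.02 * target_px) break
    R0 <- R0 * sqrt(target_px / max(area, 1))
  }
  list(mask = mask, x0 = x0, y0 = y0)
}

smooth_field <- function(h, w, sigma) {
  m <- matrix(rnorm(h * w), h, w)
  m <- as.matrix(EBImage::gblur(m, sigma))
  rng <- range(m)
  if (diff(rng) < 1e-12) return(matrix(0.5, h, w))
  (m - rng[1]) / diff(rng)
}

blend_color <- function(img_block, weight, col) {
  for (ch in 1:3) {
    img_block[, , ch] <- img_block[, , ch] * (1 - weight) + col[ch] * weight
  }
  img_block
}

# Palettes (RGB in [0,1]); H&E-like pinks/purples.
PAL <- list(
  base_light = c(0.92, 0.76, 0.87),
  base_dark  = c(0.78, 0.55, 0.76),
  bd_base    = c(0.72, 0.48, 0.70),
  bd_streak  = c(0.36, 0.16, 0.48),
  sk_base    = c(0.90, 0.64, 0.60),
  sk_dot     = c(0.99, 0.94, 0.78)
)

# Render lesion texture into img block (array over the section bbox).
# region: logical matrix of lesion pixels within the block.
paint_lesion <- function(block, region, class, sep) {
  h <- nrow(region); w <- ncol(region)
  if (class == "BD") {
    block <- blend_color_masked(block, region, 0.5 * sep, PAL$bd_base)
    seeds <- matrix(runif(h * w) < 0.008, h, w) & region
    brush <- EBImage::makeBrush(11, shape = "line", angle = runif(1, 0, 90))
    streaks <- EBImage::dilate(EBImage::Image(seeds * 1), brush) > 0.5
    streaks <- as.matrix(streaks) & region
    block <- blend_color_masked(block, streaks, 0.9 * sep, PAL$bd_streak)
  } else { # SK
    block <- blend_color_masked(block, region, 0.5 * sep, PAL$sk_base)
    seeds <- matrix(runif(h * w) < 0.010, h, w) & region
    brush <- EBImage::makeBrush(5, shape = "disc")
    dots <- EBImage::dilate(EBImage::Image(seeds * 1), brush) > 0.5
    dots <- as.matrix(dots) & region
    block <- blend_color_masked(block, dots, 0.9 * sep, PAL$sk_dot)
  }
  block
}

blend_color_masked <- function(block, region, weight, col) {
  for (ch in 1:3) {
    m <- block[, , ch]
    m[region] <- m[region] * (1 - weight) + col[ch] * weight
    block[, , ch] <- m
  }
  block
}

#' Generate one synthetic slide
#'
#' Renders the slide image, its integer label mask (0 = background/normal
#' tissue, 1 = BD, 2 = SK) and per-section ground truth. Lesion pixel areas
#' match the requested mm^2 areas within 10 percent relative tolerance.
#'
#' @param spec a [synthetic_slide_spec()].
#' @return a list of class `bdsk_slide` with elements `image` (H x W x 3 array
#'   in \[0,1\]), `mask` (H x W integer matrix), `sections` (list of per-section
#'   truth records), and `mpp`.
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "bdsk_slide_spec"))
  W <- spec$canvas_size_px[1]; H <- spec$canvas_size_px[2]
  with_seed(spec$seed, {
    img <- array(0, c(H, W, 3))
    bgnoise <- matrix(rnorm(H * W, 0, 0.008), H, W)
    img[, , 1] <- clamp01(0.965 + bgnoise)
    img[, , 2] <- clamp01(0.955 + bgnoise)
    img[, , 3] <- clamp01(0.965 + bgnoise)
    mask <- matrix(0L, H, W)
    truths <- list()

    n <- length(spec$sections)
    if (n > 0) {
      foot_px <- vapply(spec$sections,
                        function(s) mm2_to_pixels(s$footprint_area_mm2, spec$mpp), 0)
      rad <- sqrt(foot_px / pi)
      ncols <- ceiling(sqrt(n)); nrows <- ceiling(n / ncols)
      cw <- W / ncols; chh <- H / nrows
      if (any(2.6 * rad > min(cw, chh))) {
        stop("placement failure: requested section areas cannot be placed on the canvas")
      }
      order_cells <- seq_len(n)
      for (i in seq_len(n)) {
        req <- spec$sections[[i]]
        cell <- order_cells[i] - 1L
        cx <- (cell %% ncols + 0.5) * cw + runif(1, -0.05, 0.05) * cw
        cy <- (cell %/% ncols + 0.5) * chh + runif(1, -0.05, 0.05) * chh
        harm <- new_harmonics()
        blob <- rasterize_blob(cx, cy, foot_px[i], H, W, harm)
        fp <- blob$mask
        ys <- blob$y0:(blob$y0 + nrow(fp) - 1L)
        xs <- blob$x0:(blob$x0 + ncol(fp) - 1L)
        block <- img[ys, xs, , drop = FALSE]

        # base tissue texture
        field <- smooth_field(nrow(fp), ncol(fp), 4)
        for (ch in 1:3) {
          tex <- PAL$base_light[ch] * (1 - field) + PAL$base_dark[ch] * field
          m <- block[, , ch]
          m[fp] <- tex[fp]
          block[, , ch] <- m
        }

        area_bd <- 0; area_sk <- 0
        if (req$class != "Normal" && req$lesion_area_mm2 > 0) {
          lesion_px <- mm2_to_pixels(req$lesion_area_mm2, spec$mpp)
          lharm <- new_harmonics(amp = 0.10)
          # lesion centred on the footprint centre, in block coordinates
          lcx <- cx - blob$x0 + 1; lcy <- cy - blob$y0 + 1
          lblob <- rasterize_blob(lcx, lcy, lesion_px,
                                  nrow(fp), ncol(fp), lharm)
          lesion <- matrix(FALSE, nrow(fp), ncol(fp))
          lys <- lblob$y0:(lblob$y0 + nrow(lblob$mask) - 1L)
          lxs <- lblob$x0:(lblob$x0 + ncol(lblob$mask) - 1L)
          lesion[lys, lxs] <- lblob$mask
          lesion <- lesion & fp

          main_class <- if (req$class == "BD") "BD" else "SK"
          block <- paint_lesion(block, lesion, main_class, req$separability)
          mblock <- mask[ys, xs]
          mblock[lesion] <- if (main_class == "BD") 1L else 2L

          if (req$class == "SK_with_BD_focus") {
            focus_px <- req$focus_fraction * sum(lesion)
            fharm <- new_harmonics(amp = 0.08)
            # place focus off-centre inside the lesion
            cand <- which(lesion, arr.ind = TRUE)
            anchor <- cand[max(1L, round(nrow(cand) * 0.35)), ]
            fblob <- rasterize_blob(anchor[2], anchor[1], focus_px,
                                    nrow(fp), ncol(fp), fharm)
            focus <- matrix(FALSE, nrow(fp), ncol(fp))
            fys <- fblob$y0:(fblob$y0 + nrow(fblob$mask) - 1L)
            fxs <- fblob$x0:(fblob$x0 + ncol(fblob$mask) - 1L)
            focus[fys, fxs] <- fblob$mask
            focus <- focus & lesion
            block <- paint_lesion(block, focus, "BD", req$separability)
            mblock[focus] <- 1L
          }
          mask[ys, xs] <- mblock
          area_bd <- pixels_to_mm2(sum(mask[ys, xs][fp] == 1L), spec$mpp)
          area_sk <- pixels_to_mm2(sum(mask[ys, xs][fp] == 2L), spec$mpp)
        }

        img[ys, xs, ] <- block
        # 0-based half-open bbox of the footprint
        rr <- range(which(rowSums(fp) > 0)); cc <- range(which(colSums(fp) > 0))
        truths[[i]] <- list(
          section_id = i,
          class = req$class,
          bbox = c(x0 = xs[cc[1]] - 1L, y0 = ys[rr[1]] - 1L,
                   x1 = xs[cc[2]], y1 = ys[rr[2]]),
          area_bd_mm2 = area_bd,
          area_sk_mm2 = area_sk,
          footprint_area_mm2 = pixels_to_mm2(sum(fp), spec$mpp),
          separability = req$separability
        )
      }
    }
    img <- apply_style_shift(img, spec$style)
    structure(list(image = img, mask = mask, sections = truths,
                   mpp = spec$mpp),
              class = "bdsk_slide")
  })
}

# Vectorized HSV -> RGB (h, s, v in [0,1]); inverse of grDevices::rgb2hsv.
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Apply a photometric style shift to an RGB image
#'
#' Geometry and any associated label masks are unaffected; the identity style
#' returns the input unchanged.
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param style a [style_params()] object.
#' @param seed optional seed for the additive-noise component; when `NULL` the
#'   current RNG stream is used.
#' @return the shifted image, clamped to \[0,1\].
#' @export
apply_style_shift <- function(image, style, seed = NULL) {
  stopifnot(is_rgb_array(image), inherits(style, "bdsk_style"))
  if (is_identity_style(style)) return(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  r <- as.vector(image[, , 1]); g <- as.vector(image[, , 2])
  b <- as.vector(image[, , 3])
  if (style$hue_shift != 0 || style$sat_shift != 0) {
    hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1)
    h <- (hsv[1, ] + style$hue_shift) %% 1
    s <- clamp01(hsv[2, ] + style$sat_shift)
    rgb <- hsv_to_rgb(h, s, hsv[3, ])
    r <- rgb$r; g <- rgb$g; b <- rgb$b
  }
  if (style$brightness != 1) {
    r <- r * style$brightness; g <- g * style$brightness
    b <- b * style$brightness
  }
  if (style$contrast != 1) {
    r <- (r - 0.5) * style$contrast + 0.5
    g <- (g - 0.5) * style$contrast + 0.5
    b <- (b - 0.5) * style$contrast + 0.5
  }
  if (any(style$tint != 0)) {
    lum <- 0.299 * r + 0.587 * g + 0.114 * b
    r <- r + style$tint[1] * lum
    g <- g + style$tint[2] * lum
    b <- b + style$tint[3] * lum
  }
  if (style$noise_sd > 0) {
    addn <- function() rnorm(H * W, 0, style$noise_sd)
    if (!is.null(seed)) {
      with_seed(seed, { r <- r + addn(); g <- g + addn(); b <- b + addn() })
    } else {
      r <- r + addn(); g <- g + addn(); b <- b + addn()
    }
  }
  out <- array(0, c(H, W, 3))
  out[, , 1] <- clamp01(r); out[, , 2] <- clamp01(g); out[, , 3] <- clamp01(b)
  out
}

#' Write a slide image or label mask as PNG
#'
#' Images are 8-bit RGB; masks are single-channel PNGs storing the small
#' integer labels 0/1/2.
#'
#' @param slide a `bdsk_slide`.
#' @param image_path,mask_path output paths.
#' @return invisibly, the two paths.
#' @export
write_slide <- function(slide, image_path, mask_path) {
  png::writePNG(slide$image, image_path)
  png::writePNG(slide$mask / 255, mask_path)
  invisible(c(image_path, mask_path))
}

#' Read a slide image written by [write_slide()]
#' @param path PNG path.
#' @return H x W x 3 array in \[0,1\].
#' @export
read_slide_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Read a label mask written by [write_slide()]
#' @param path PNG path.
#' @return integer matrix of labels 0/1/2.
#' @export
read_label_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

# Exact integer allocation of n items to proportions (largest remainder).
allocate_counts <- function(n, mix) {
  stopifnot(abs(sum(mix) - 1) < 1e-8, all(mix >= 0))
  raw <- n * mix
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Generate a seeded cohort of synthetic slides on disk
#'
#' @param n_slides number of slides (>= 0).
#' @param class_mix named numeric vector of class proportions summing to 1;
#'   names from `"Normal"`, `"BD"`, `"SK"`, `"SK_with_BD_focus"`. Counts are
#'   exact up to rounding by largest remainder.
#' @param style a [style_params()] applied to every slide.
#' @param seed integer cohort seed.
#' @param dir output directory (created if needed).
#' @param canvas_size_px,mpp slide geometry (see [synthetic_slide_spec()]).
#' @param lesion_area_mm2 length-2 range; each lesion area is drawn uniformly.
#' @param separability texture separability passed to every section.
#' @param sections_per_slide sections per slide (all of the slide's class).
#' @param split value written to the manifest `split` column.
#' @param prefix file-name prefix.
#' @return the manifest as a data frame (one row per section) with columns
#'   `slide_path, mask_path, mpp, section_id, class, true_bd_area_mm2,
#'   true_sk_area_mm2, split`.
#' @export
generate_cohort <- function(n_slides, class_mix, style = style_params(),
                            seed = 1L, dir = tempfile("cohort"),
                            canvas_size_px = c(512L, 512L), mpp = 1,
                            lesion_area_mm2 = c(0.015, 0.03),
                            separability = 0.9, sections_per_slide = 1L,
                            split = "train", prefix = "slide") {
  if (n_slides < 0) stop("n_slides must be non-negative")
  stopifnot(!is.null(names(class_mix)),
            all(names(class_mix) %in% CLASS_LEVELS))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- allocate_counts(n_slides, as.numeric(class_mix))
  classes <- rep(names(class_mix), counts)
  rows <- list()
  with_seed(seed, {
    classes <- sample(classes)
    for (i in seq_len(n_slides)) {
      area <- runif(sections_per_slide, lesion_area_mm2[1], lesion_area_mm2[2])
      secs <- lapply(seq_len(sections_per_slide), function(j) {
        section_request(classes[i],
                        lesion_area_mm2 = if (classes[i] == "Normal") 0 else area[j],
                        separability = separability,
                        footprint_area_mm2 = if (classes[i] == "Normal")
                          max(0.04, mean(lesion_area_mm2) / 0.45) else NULL)
      })
      spec <- synthetic_slide_spec(canvas_size_px, mpp, secs, style,
                                   seed = child_seed(seed, i))
      slide <- generate_slide(spec)
      ip <- file.path(dir, sprintf("%s%03d.png", prefix, i))
      mp <- file.path(dir, sprintf("%s%03d_mask.png", prefix, i))
      write_slide(slide, ip, mp)
      for (s in slide$sections) {
        rows[[length(rows) + 1L]] <- data.frame(
          slide_path = ip, mask_path = mp, mpp = mpp,
          section_id = sprintf("%s%03d_s%d", prefix, i, s$section_id),
          class = s$class, true_bd_area_mm2 = s$area_bd_mm2,
          true_sk_area_mm2 = s$area_sk_mm2, split = split,
          stringsAsFactors = FALSE
        )
      }
    }
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slide_path = character(), mask_path = character(),
               mpp = numeric(), section_id = character(), class = character(),
               true_bd_area_mm2 = numeric(), true_sk_area_mm2 = numeric(),
               split = character(), stringsAsFactors = FALSE)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Write / read a cohort manifest
#'
#' CSV round trip is lossless for the manifest column types.
#'
#' @param manifest manifest data frame.
#' @param path CSV path.
#' @return `write_manifest` returns the path invisibly; `read_manifest`
#'   returns the data frame.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(slide_path = "character", mask_path = "character",
                          mpp = "numeric", section_id = "character",
                          class = "character", true_bd_area_mm2 = "numeric",
                          true_sk_area_mm2 = "numeric", split = "character"))
}
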