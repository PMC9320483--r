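# Tissue/background separation, section extraction and tile planning.
#
# Tiling works in physical units: tiles are `tile_size_um` on a side with at
# least `min_overlap_um` overlap between adjacent tiles on every axis; the
# microns-per-pixel value of the slide converts to pixels.

#' Tiling configuration
#'
#' @param tile_size_um tile side length in microns (default 1024).
#' @param min_overlap_um minimum overlap between adjacent tiles in microns
#'   (default 300).
#' @param mpp microns per pixel (default 1, i.e. 1 um = 1 px at 10x).
#' @return an object of class `bdsk_tiling_config`.
#' @export
tiling_config <- function(tile_size_um = 1024, min_overlap_um = 300, mpp = 1) {
  stopifnot(tile_size_um > min_overlap_um, min_overlap_um >= 0, mpp > 0)
  structure(list(tile_size_um = tile_size_um, min_overlap_um = min_overlap_um,
                 mpp = mpp),
            class = "bdsk_tiling_config")
}

#' Tissue-detection configuration
#'
#' The recipe combines a darkness channel (1 - luminance) with the saturation
#' channel, applies a global Otsu threshold (floored by `min_signal` so blank
#' slides stay empty), then a morphological opening followed by closing with a
#' disc, and finally fills enclosed holes smaller than `fill_holes_mm2`.
#'
#' @param disc_um diameter of the morphology disc in microns.
#' @param fill_holes_mm2 fill enclosed background holes below this area.
#' @param min_signal absolute floor on the tissue signal in \[0,1\].
#' @return an object of class `bdsk_tissue_config`.
#' @export
tissue_config <- function(disc_um = 32, fill_holes_mm2 = 0.01,
                          min_signal = 0.08) {
  stopifnot(disc_um > 0, fill_holes_mm2 >= 0, min_signal >= 0, min_signal < 1)
  structure(list(disc_um = disc_um, fill_holes_mm2 = fill_holes_mm2,
                 min_signal = min_signal),
            class = "bdsk_tissue_config")
}

odd_brush_size <- function(um, mpp) {
  n <- max(3L, as.integer(round(um / mpp)))
  if (n %% 2L == 0L) n <- n + 1L
  n
}

# Opening followed by closing with a disc; idempotent as a composite filter.
morphology_step <- function(mask, config, mpp) {
  brush <- EBImage::makeBrush(odd_brush_size(config$disc_um, mpp),
                              shape = "disc")
  m <- EBImage::Image(mask * 1)
  m <- EBImage::closing(EBImage::opening(m, brush), brush)
  as.matrix(m) > 0.5
}

fill_small_holes <- function(mask, max_hole_px) {
  if (max_hole_px <= 0) return(mask)
  bg <- !mask
  lab <- cpp_label8(bg)
  if (max(lab) == 0L) return(mask)
  # holes are background components not touching the border
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0L])
  for (k in seq_along(sizes)) {
    if (!(k %in% border) && sizes[k] > 0 && sizes[k] <= max_hole_px) {
      mask[lab == k] <- TRUE
    }
  }
  mask
}

#' Detect tissue on a slide
#'
#' @param image H x W x 3 RGB array in \[0,1\].
#' @param mpp microns per pixel.
#' @param config a [tissue_config()].
#' @return a list of class `bdsk_tissue_mask` with `mask` (logical H x W) and
#'   `mpp`.
#' @export
detect_tissue <- function(image, mpp = 1, config = tissue_config()) {
  stopifnot(is_rgb_array(image))
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  gray <- 0.299 * r + 0.587 * g + 0.114 * b
  sat <- pmax(r, g, b) - pmin(r, g, b)
  score <- pmax(1 - gray, sat)
  thr <- tryCatch(EBImage::otsu(EBImage::Image(clamp01(score))),
                  error = function(e) 1)
  mask <- score > max(thr, config$min_signal)
  if (any(mask)) {
    mask <- morphology_step(mask, config, mpp)
    mask <- fill_small_holes(mask, mm2_to_pixels(config$fill_holes_mm2, mpp))
  }
  structure(list(mask = mask, mpp = mpp), class = "bdsk_tissue_mask")
}

#' Extract tissue sections from a tissue mask
#'
#' Sections are 8-connected components of the tissue mask with area above
#' `min_section_area_mm2`, ordered by decreasing area. Very small fragments
#' are filtered out.
#'
#' @param tissue a `bdsk_tissue_mask` from [detect_tissue()] (or a logical
#'   matrix, in which case `mpp` must be given).
#' @param min_section_area_mm2 minimum section area (default 0.2).
#' @param mpp microns per pixel; taken from `tissue` when available.
#' @return list of `bdsk_section` objects with fields `id`, `mask` (logical
#'   over the bounding box), `bbox` (0-based half-open `x0,y0,x1,y1`),
#'   `area_mm2`, `mpp`, `slide_size` (`width,height`).
#' @export
extract_sections <- function(tissue, min_section_area_mm2 = 0.2, mpp = NULL) {
  if (inherits(tissue, "bdsk_tissue_mask")) {
    mask <- tissue$mask; mpp <- tissue$mpp
  } else {
    mask <- tissue
    stopifnot(!is.null(mpp))
  }
  lab <- cpp_label8(mask)
  n <- max(lab)
  out <- list()
  if (n > 0) {
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which(pixels_to_mm2(sizes, mpp) > min_section_area_mm2)
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    for (i in seq_along(keep)) {
      k <- keep[i]
      comp <- lab == k
      rr <- range(which(rowSums(comp) > 0))
      cc <- range(which(colSums(comp) > 0))
      out[[i]] <- structure(list(
        id = i,
        mask = comp[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE],
        bbox = c(x0 = cc[1] - 1L, y0 = rr[1] - 1L, x1 = cc[2], y1 = rr[2]),
        area_mm2 = pixels_to_mm2(sizes[k], mpp),
        mpp = mpp,
        slide_size = c(width = ncol(mask), height = nrow(mask))
      ), class = "bdsk_section")
    }
  }
  out
}

# Plan tile origins along one axis. extent/T/O in px; returns 0-based origins.
plan_axis <- function(start, extent, T, O, slide_extent) {
  if (extent <= T) {
    origin <- start + floor((extent - T) / 2)
    if (slide_extent >= T) origin <- min(max(origin, 0L), slide_extent - T)
    return(as.integer(origin))
  }
  n <- ceiling((extent - T) / (T - O)) + 1
  s <- ceiling((extent - T) / (n - 1))
  leftover <- (n - 1) * s - (extent - T)
  first <- start - floor(leftover / 2)
  origins <- first + (seq_len(n) - 1) * s
  if (slide_extent >= T) {
    origins <- pmin(pmax(origins, 0L), slide_extent - T)
  }
  as.integer(unique(origins))
}

#' Plan overlapping tiles over a section
#'
#' Tiles are `tile_size_um` squares covering the section's bounding box with at
#' least `min_overlap_um` overlap between adjacent tiles on each axis, using
#' the minimum number of tiles per axis. Tiles that do not intersect the
#' section's tissue mask are dropped; tiles are clamped inside the slide where
#' possible (a slide smaller than one tile yields a single tile whose
#' out-of-slide pixels are filled by reflection at extraction time).
#'
#' @param section a `bdsk_section` from [extract_sections()].
#' @param cfg a [tiling_config()]; its `mpp` must match the section's.
#' @return data frame with columns `x0, y0, side_px, section_id` (0-based
#'   half-open pixel coordinates).
#' @export
plan_tiles <- function(section, cfg = tiling_config()) {
  stopifnot(inherits(section, "bdsk_section"),
            inherits(cfg, "bdsk_tiling_config"))
  mpp <- section$mpp
  T <- as.integer(round(cfg$tile_size_um / mpp))
  O <- as.integer(ceiling(cfg$min_overlap_um / mpp))
  stopifnot(T > O)
  bb <- section$bbox
  xs <- plan_axis(bb["x0"], bb["x1"] - bb["x0"], T, O,
                  section$slide_size["width"])
  ys <- plan_axis(bb["y0"], bb["y1"] - bb["y0"], T, O,
                  section$slide_size["height"])
  grid <- expand.grid(x0 = xs, y0 = ys)
  keep <- vapply(seq_len(nrow(grid)), function(i) {
    tile_intersects_mask(section, grid$x0[i], grid$y0[i], T)
  }, logical(1))
  out <- grid[keep, , drop = FALSE]
  out$side_px <- T
  out$section_id <- section$id
  rownames(out) <- NULL
  out
}

tile_intersects_mask <- function(section, x0, y0, side) {
  bb <- section$bbox
  cx0 <- max(x0, bb["x0"]); cx1 <- min(x0 + side, bb["x1"])
  cy0 <- max(y0, bb["y0"]); cy1 <- min(y0 + side, bb["y1"])
  if (cx0 >= cx1 || cy0 >= cy1) return(FALSE)
  sub <- section$mask[(cy0 - bb["y0"] + 1):(cy1 - bb["y0"]),
                      (cx0 - bb["x0"] + 1):(cx1 - bb["x0"]), drop = FALSE]
  any(sub)
}

# Reflect 0-based indices into [0, n-1].
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  period <- 2L * (n - 1L)
  i <- i %% period
  i[i < 0] <- i[i < 0] + period
  ifelse(i >= n, period - i, i)
}

#' Extract tile pixels with reflection padding
#'
#' @param image H x W x C array (or H x W matrix).
#' @param x0,y0 0-based tile origin (may be negative or overhang the slide).
#' @param side tile side in px.
#' @return side x side (x C) array.
#' @export
extract_tile <- function(image, x0, y0, side) {
  d <- dim(image)
  rows <- reflect_index(y0 + 0:(side - 1L), d[1]) + 1L
  cols <- reflect_index(x0 + 0:(side - 1L), d[2]) + 1L
  if (length(d) == 3) image[rows, cols, , drop = FALSE] else
    image[rows, cols, drop = FALSE]
}

#' Export a tile plan as CSV
#'
#' @param plans data frame from [plan_tiles()] (possibly for several sections).
#' @param slide_path slide path recorded in the CSV.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_tile_plan <- function(plans, slide_path, path) {
  out <- data.frame(slide_path = slide_path, section_id = plans$section_id,
                    x0 = plans$x0, y0 = plans$y0, side_px = plans$side_px)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
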