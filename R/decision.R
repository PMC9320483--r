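# Section-level decisions: stitch tile heat maps over a section, smooth them
# with grayscale morphology, convert thresholded pixels to mm^2, and apply the
# diagnostic cascade (BD if area >= delta1; else SK if area >= delta2; else
# Normal) with an optional relative-area refinement r = 100*BD/(BD+SK),
# requiring r >= 20 for a BD call.

#' Decision parameters
#'
#' Defaults are the calibrated operating point: probability thresholds 0.5
#' (BD) and 0.6 (SK), minimum areas delta1 = 0.0256 mm^2 (BD) and
#' delta2 = 0.0333 mm^2 (SK), and a relative-area cutoff of 20 percent.
#'
#' @param threshold_bd,threshold_sk probability cutoffs in \[0,1\].
#' @param min_area_bd,min_area_sk minimum positive areas in mm^2.
#' @param relative_area_cutoff BD relative-area cutoff in percent, \[0,100\].
#' @param mode `"cascade"` (area thresholds only) or `"relative_area"`
#'   (additionally require `r >= relative_area_cutoff` for BD).
#' @return an object of class `bdsk_decision_params`.
#' @export
decision_params <- function(threshold_bd = 0.5, threshold_sk = 0.6,
                            min_area_bd = 0.0256, min_area_sk = 0.0333,
                            relative_area_cutoff = 20,
                            mode = c("cascade", "relative_area")) {
  mode <- match.arg(mode)
  stopifnot(threshold_bd >= 0, threshold_bd <= 1, threshold_sk >= 0,
            threshold_sk <= 1, min_area_bd >= 0, min_area_sk >= 0,
            relative_area_cutoff >= 0, relative_area_cutoff <= 100)
  structure(list(threshold_bd = threshold_bd, threshold_sk = threshold_sk,
                 min_area_bd = min_area_bd, min_area_sk = min_area_sk,
                 relative_area_cutoff = relative_area_cutoff, mode = mode),
            class = "bdsk_decision_params")
}

#' Stitch tile heat maps into a section heat map
#'
#' The section heat map lives on the section's bounding box at the output
#' stride (one pixel per 8 x 8 input block, `mpp_out = 8 * mpp`). Every output
#' pixel is the mean (or max) of all tile predictions covering its block
#' centre; pixels outside the tissue mask are set to 0.
#'
#' @param tile_maps list of `bdsk_tile_heatmap` objects with slide-global
#'   coords.
#' @param section the owning `bdsk_section`.
#' @param combine `"mean"` (default) or `"max"`.
#' @return an object of class `bdsk_section_heatmap`: `probs`
#'   (ny x nx x 2 array), `bbox`, `mpp_out`, `section_id`.
#' @export
stitch_heatmaps <- function(tile_maps, section, combine = c("mean", "max")) {
  combine <- match.arg(combine)
  stopifnot(length(tile_maps) > 0, inherits(section, "bdsk_section"))
  stride <- tile_maps[[1]]$stride_px
  bb <- section$bbox
  nx <- as.integer(ceiling(unname(bb["x1"] - bb["x0"]) / stride))
  ny <- as.integer(ceiling(unname(bb["y1"] - bb["y0"]) / stride))
  # global starts of the output blocks
  bx <- bb["x0"] + (seq_len(nx) - 1) * stride
  by <- bb["y0"] + (seq_len(ny) - 1) * stride
  acc <- array(0, c(ny, nx, 2))
  cnt <- matrix(0, ny, nx)
  for (tm in tile_maps) {
    side_out <- dim(tm$probs)[1]
    side_px <- side_out * stride
    # a tile contributes to every block its footprint intersects; the tile's
    # own output pixel is the one nearest the block (clamped at tile edges)
    okx <- which(bx < tm$coord[1] + side_px & bx + stride > tm$coord[1])
    oky <- which(by < tm$coord[2] + side_px & by + stride > tm$coord[2])
    if (!length(okx) || !length(oky)) next
    jx <- pmin(pmax(floor((bx[okx] + stride / 2 - tm$coord[1]) / stride) + 1,
                    1), side_out)
    jy <- pmin(pmax(floor((by[oky] + stride / 2 - tm$coord[2]) / stride) + 1,
                    1), side_out)
    for (ch in 1:2) {
      sub <- tm$probs[jy, jx, ch, drop = FALSE][, , 1]
      if (combine == "mean") {
        acc[oky, okx, ch] <- acc[oky, okx, ch] + sub
      } else {
        acc[oky, okx, ch] <- pmax(acc[oky, okx, ch], sub)
      }
    }
    cnt[oky, okx] <- cnt[oky, okx] + 1
  }
  # tissue coverage at output resolution (any tissue pixel in the block)
  tis <- section_mask_blocks(section, stride, ny, nx)
  if (any(tis & cnt == 0)) stop("tissue pixel not covered by any tile")
  probs <- array(0, c(ny, nx, 2))
  for (ch in 1:2) {
    m <- if (combine == "mean") {
      ifelse(cnt > 0, acc[, , ch] / pmax(cnt, 1), 0)
    } else {
      acc[, , ch]
    }
    m[!tis] <- 0
    probs[, , ch] <- m
  }
  structure(list(probs = probs, bbox = bb, mpp_out = stride * section$mpp,
                 section_id = section$id),
            class = "bdsk_section_heatmap")
}

# Block-any downsample of the section mask onto the output grid.
section_mask_blocks <- function(section, stride, ny, nx) {
  m <- section$mask
  H <- ny * stride; W <- nx * stride
  pad <- matrix(FALSE, H, W)
  pad[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  A <- kronecker(diag(ny), matrix(1, 1, stride))
  B <- kronecker(diag(nx), matrix(1, stride, 1))
  (A %*% pad %*% B) > 0
}

#' Post-process a section heat map
#'
#' Grayscale morphological opening followed by closing per channel with a disc
#' structuring element; smooths the maps and removes isolated speckles.
#' Idempotent: applying it twice equals applying it once.
#'
#' @param map a `bdsk_section_heatmap`.
#' @param disc_radius_px disc radius in output pixels (default 2, i.e. 16 um
#'   at mpp 1).
#' @return the post-processed `bdsk_section_heatmap`.
#' @export
postprocess <- function(map, disc_radius_px = 2) {
  stopifnot(inherits(map, "bdsk_section_heatmap"))
  if (disc_radius_px <= 0) return(map)
  size <- 2L * as.integer(disc_radius_px) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  for (ch in 1:2) {
    m <- map$probs[, , ch]
    if (nrow(m) < size || ncol(m) < size) next
    img <- EBImage::Image(m)
    img <- EBImage::closing(EBImage::opening(img, brush), brush)
    map$probs[, , ch] <- clamp01(as.matrix(img))
  }
  map
}

#' Thresholded positive area of a heat-map channel
#'
#' @param channel probability matrix in \[0,1\].
#' @param threshold probability cutoff in \[0,1\]; pixels `>= threshold` count.
#' @param mpp_out microns per output pixel.
#' @return area in mm^2.
#' @export
binarize_and_area <- function(channel, threshold, mpp_out) {
  stopifnot(threshold >= 0, threshold <= 1, mpp_out > 0)
  pixels_to_mm2(sum(channel >= threshold), mpp_out)
}

#' Relative BD area
#'
#' `r = 100 * area_bd / (area_bd + area_sk)` in percent; defined as 0 when
#' both areas are 0.
#'
#' @param area_bd,area_sk non-negative areas in mm^2.
#' @return r in \[0, 100\].
#' @export
relative_area <- function(area_bd, area_sk) {
  if (area_bd < 0 || area_sk < 0) stop("areas must be non-negative")
  if (area_bd + area_sk == 0) return(0)
  100 * area_bd / (area_bd + area_sk)
}

#' Classify one tissue section from its class areas
#'
#' Cascade mode: BD iff `area_bd >= min_area_bd`; else SK iff
#' `area_sk >= min_area_sk`; else Normal. Relative-area mode additionally
#' requires `r >= relative_area_cutoff` for the BD call; a section whose BD
#' area passes delta1 but whose r falls below the cutoff is called SK when its
#' SK area passes delta2, else Normal.
#'
#' @param area_bd,area_sk class areas in mm^2 (computed with the per-class
#'   probability thresholds in `params`).
#' @param params a [decision_params()].
#' @param section_id optional id carried into the call record.
#' @return an object of class `bdsk_section_call`: list with `section_id`,
#'   `area_bd_mm2`, `area_sk_mm2`, `r_percent`, `label`.
#' @export
classify_section <- function(area_bd, area_sk, params = decision_params(),
                             section_id = NA) {
  stopifnot(inherits(params, "bdsk_decision_params"))
  r <- relative_area(area_bd, area_sk)
  bd_area_ok <- area_bd >= params$min_area_bd
  sk_area_ok <- area_sk >= params$min_area_sk
  label <- if (params$mode == "cascade") {
    if (bd_area_ok) "BD" else if (sk_area_ok) "SK" else "Normal"
  } else {
    if (bd_area_ok && r >= params$relative_area_cutoff) "BD"
    else if (sk_area_ok) "SK"
    else "Normal"
  }
  structure(list(section_id = section_id, area_bd_mm2 = area_bd,
                 area_sk_mm2 = area_sk, r_percent = r, label = label),
            class = "bdsk_section_call")
}

#' @export
print.bdsk_section_call <- function(x, ...) {
  cat(sprintf("section %s: BD %.4f mm^2, SK %.4f mm^2, r = %.1f%% -> %s\n",
              as.character(x$section_id), x$area_bd_mm2, x$area_sk_mm2,
              x$r_percent, x$label))
  invisible(x)
}

#' Call one section from its (post-processed) heat map
#'
#' @param map a `bdsk_section_heatmap` (post-processed; see [postprocess()]).
#' @param params a [decision_params()].
#' @return a `bdsk_section_call`.
#' @export
call_section <- function(map, params = decision_params()) {
  stopifnot(inherits(map, "bdsk_section_heatmap"))
  area_bd <- binarize_and_area(map$probs[, , 1], params$threshold_bd,
                               map$mpp_out)
  area_sk <- binarize_and_area(map$probs[, , 2], params$threshold_sk,
                               map$mpp_out)
  classify_section(area_bd, area_sk, params, section_id = map$section_id)
}
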