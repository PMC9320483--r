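# Shared small helpers: physical-unit conversion, seeding, hashing.

#' Convert a pixel count to an area in mm^2
#'
#' @param n_pixels number of pixels.
#' @param mpp microns per pixel of the raster the pixels were counted on.
#' @return area in mm^2.
#' @export
pixels_to_mm2 <- function(n_pixels, mpp) {
  stopifnot(mpp > 0)
  n_pixels * mpp^2 / 1e6
}

#' Convert an area in mm^2 to a pixel count
#'
#' @param area_mm2 area in mm^2.
#' @param mpp microns per pixel.
#' @return (fractional) pixel count.
#' @export
mm2_to_pixels <- function(area_mm2, mpp) {
  stopifnot(mpp > 0)
  area_mm2 * 1e6 / mpp^2
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Derive a child seed from a base seed and an index; stays below 2^31.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 1299709) %% 2147483647L)
}

# FNV-1a hash of a serialized R object, as 8 hex characters. Used to stamp
# outputs with the configuration they were produced under.
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# matrix/array sanity
is_rgb_array <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L
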