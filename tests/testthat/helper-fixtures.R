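# Shared fixtures, built in code at test time.

# One 512x512 slide with a single BD section; reused across files.
fixture_bd_slide <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_slide_spec(
        c(512L, 512L), mpp = 1,
        sections = list(section_request("BD", lesion_area_mm2 = 0.02,
                                        separability = 1)),
        seed = 42L)
      cache <<- generate_slide(spec)
    }
    cache
  }
})

# A tiny trained-free network stub that predicts ~0 everywhere: head bias
# pushed far negative. Useful for plumbing tests that need deterministic,
# near-empty heat maps.
stub_network <- function(input_side = 256L, bias = -10) {
  net <- build_network(network_config(input_side, "small"), seed = 1L)
  net$params$head$w[] <- 0
  net$params$head$b[] <- bias
  net
}

# Construct a section heat map directly (bypassing any model) from a
# probability matrix; mpp_out defaults to 8 um per output pixel.
make_heatmap <- function(bd, sk = NULL, mpp_out = 8, section_id = 1L) {
  if (is.null(sk)) sk <- bd * 0
  probs <- array(0, c(nrow(bd), ncol(bd), 2))
  probs[, , 1] <- bd; probs[, , 2] <- sk
  structure(list(probs = probs,
                 bbox = c(x0 = 0L, y0 = 0L, x1 = ncol(bd) * 8L,
                          y1 = nrow(bd) * 8L),
                 mpp_out = mpp_out, section_id = section_id),
            class = "bdsk_section_heatmap")
}

# Plant a star-free circular blob of `n_px` pixels with value `p` at a free
# spot of matrix `m`; returns the updated matrix.
plant_blob <- function(m, n_px, p, centre) {
  r <- sqrt(n_px / pi)
  H <- nrow(m); W <- ncol(m)
  ys <- pmax(1, round(centre[1] - r - 1)):pmin(H, round(centre[1] + r + 1))
  xs <- pmax(1, round(centre[2] - r - 1)):pmin(W, round(centre[2] + r + 1))
  for (i in ys) for (j in xs) {
    if ((i - centre[1])^2 + (j - centre[2])^2 <= r^2) m[i, j] <- p
  }
  m
}

# Brute-force verifier for tile plans: every tissue pixel covered, and
# adjacent tiles along each grid axis overlap at least `min_overlap_px`.
verify_tile_plan <- function(plan, section, min_overlap_px) {
  bb <- section$bbox
  covered <- matrix(FALSE, nrow(section$mask), ncol(section$mask))
  for (i in seq_len(nrow(plan))) {
    ys <- max(plan$y0[i], bb["y0"]):min(plan$y0[i] + plan$side_px[i], bb["y1"]) -
      bb["y0"]
    xs <- max(plan$x0[i], bb["x0"]):min(plan$x0[i] + plan$side_px[i], bb["x1"]) -
      bb["x0"]
    ys <- ys[ys >= 1 & ys <= nrow(covered)]
    xs <- xs[xs >= 1 & xs <= ncol(covered)]
    covered[ys, xs] <- TRUE
  }
  coverage_ok <- !any(section$mask & !covered)
  overlap_ok <- TRUE
  side <- plan$side_px[1]
  for (y in unique(plan$y0)) {
    xs <- sort(unique(plan$x0[plan$y0 == y]))
    if (length(xs) > 1 && any(diff(xs) > side - min_overlap_px)) {
      overlap_ok <- FALSE
    }
  }
  for (x in unique(plan$x0)) {
    ys <- sort(unique(plan$y0[plan$x0 == x]))
    if (length(ys) > 1 && any(diff(ys) > side - min_overlap_px)) {
      overlap_ok <- FALSE
    }
  }
  list(coverage = coverage_ok, overlap = overlap_ok)
}

# O(n^2) concordance-probability oracle for the AUC (mid-rank tie handling).
auc_concordance_oracle <- function(scores, truth) {
  truth <- as.logical(truth)
  pos <- scores[truth]; neg <- scores[!truth]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
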