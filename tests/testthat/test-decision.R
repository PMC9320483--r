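make_section <- function(w, h, mask = NULL, mpp = 1) {
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  structure(list(id = 1L, mask = mask,
                 bbox = c(x0 = 0L, y0 = 0L, x1 = w, y1 = h),
                 area_mm2 = pixels_to_mm2(sum(mask), mpp), mpp = mpp,
                 slide_size = c(width = w, height = h)),
            class = "bdsk_section")
}

make_tile_map <- function(value, coord, side_px = 64L) {
  probs <- array(value, c(side_px / 8L, side_px / 8L, 2))
  structure(list(probs = probs, coord = as.integer(coord), stride_px = 8L),
            class = "bdsk_tile_heatmap")
}

test_that("a single covering tile stitches to its own map", {
  sec <- make_section(64L, 64L)
  tm <- make_tile_map(0.35, c(0L, 0L))
  st <- stitch_heatmaps(list(tm), sec)
  expect_equal(dim(st$probs), c(8, 8, 2))
  expect_true(all(abs(st$probs - 0.35) < 1e-12))
  expect_equal(st$mpp_out, 8)
})

test_that("overlapping tiles average and stay in the convex hull", {
  sec <- make_section(96L, 64L)
  t1 <- make_tile_map(0.2, c(0L, 0L))
  t2 <- make_tile_map(0.6, c(32L, 0L))
  st <- stitch_heatmaps(list(t1, t2), sec)
  # overlap region x in [32, 64): both tiles contribute -> mean 0.4
  expect_true(all(abs(st$probs[, 5:8, 1] - 0.4) < 1e-12))
  expect_true(all(abs(st$probs[, 1:4, 1] - 0.2) < 1e-12))
  expect_true(all(abs(st$probs[, 9:12, 1] - 0.6) < 1e-12))
  expect_true(all(st$probs >= 0.2 - 1e-12 & st$probs <= 0.6 + 1e-12))
  # max combination rule is available
  stm <- stitch_heatmaps(list(t1, t2), sec, combine = "max")
  expect_true(all(abs(stm$probs[, 5:8, 1] - 0.6) < 1e-12))
})

test_that("uncovered tissue raises an error", {
  sec <- make_section(200L, 64L)
  expect_error(stitch_heatmaps(list(make_tile_map(0.5, c(0L, 0L))), sec),
               "not covered")
})

test_that("post-processing is idempotent and speckle-removing", {
  const <- make_heatmap(matrix(0.7, 20, 20))
  pc <- postprocess(const)
  expect_equal(pc$probs, const$probs)

  speck <- matrix(0.05, 20, 20)
  speck[10, 10] <- 0.95  # single pixel, smaller than the disc
  sp <- postprocess(make_heatmap(speck))
  expect_lt(sp$probs[10, 10, 1], 0.2)

  noisy <- make_heatmap(matrix(runif(400), 20, 20))
  once <- postprocess(noisy)
  twice <- postprocess(once)
  expect_equal(once$probs, twice$probs, tolerance = 1e-12)
})

test_that("binarized areas follow the pixel arithmetic", {
  expect_equal(binarize_and_area(matrix(0, 10, 10), 0.5, 8), 0)
  m <- matrix(0, 25, 25)
  m[seq_len(400)] <- 0.9
  expect_equal(binarize_and_area(m, 0.5, 8), 0.0256)  # 400 px * 64 um^2
  # monotonicity in the threshold
  r <- matrix(runif(400), 20, 20)
  areas <- vapply(seq(0, 1, 0.1), binarize_and_area, 0, channel = r,
                  mpp_out = 8)
  expect_true(all(diff(areas) <= 0))
})

test_that("relative area follows its defining formula", {
  expect_equal(relative_area(0, 1), 0)
  expect_equal(relative_area(1, 3), 25)
  expect_equal(relative_area(2, 0), 100)
  expect_equal(relative_area(0, 0), 0)
  expect_error(relative_area(-1, 1), "non-negative")
})

test_that("the decision cascade reproduces the worked examples", {
  p <- decision_params(mode = "relative_area")
  # r = 67.7%: BD area above delta1 -> BD
  a_sk <- 0.1
  a_bd <- 67.7 / (100 - 67.7) * a_sk
  expect_equal(relative_area(a_bd, a_sk), 67.7, tolerance = 1e-10)
  expect_equal(classify_section(a_bd, a_sk, p)$label, "BD")
  # r = 5.7%: below the 20% cutoff, SK area above delta2 -> SK
  a_bd2 <- 5.7 / (100 - 5.7) * a_sk
  expect_equal(classify_section(a_bd2, a_sk, p)$label, "SK")
  # r = 77.04% -> BD
  a_bd3 <- 77.04 / (100 - 77.04) * a_sk
  expect_equal(classify_section(a_bd3, a_sk, p)$label, "BD")
})

test_that("cascade priority is BD > SK > Normal", {
  p <- decision_params()
  expect_equal(classify_section(0.03, 0.05, p)$label, "BD")
  expect_equal(classify_section(0.01, 0.05, p)$label, "SK")
  expect_equal(classify_section(0.01, 0.01, p)$label, "Normal")
  expect_equal(classify_section(0, 0, p)$label, "Normal")
})

test_that("relative-area mode never makes more BD calls than the cascade", {
  pc <- decision_params(mode = "cascade")
  pr <- decision_params(mode = "relative_area")
  withr::with_seed(21, {
    for (i in 1:200) {
      a_bd <- runif(1, 0, 0.1); a_sk <- runif(1, 0, 0.3)
      lab_c <- classify_section(a_bd, a_sk, pc)$label
      lab_r <- classify_section(a_bd, a_sk, pr)$label
      if (lab_r == "BD") expect_equal(lab_c, "BD")
    }
  })
})

test_that("section calls derive from post-processed map areas", {
  bd <- matrix(0, 40, 40)
  bd <- plant_blob(bd, 500, 0.9, c(20, 20))  # 500 px * 64 um^2 = 0.032 mm^2
  call <- call_section(make_heatmap(bd), decision_params())
  expect_equal(call$label, "BD")
  expect_gt(call$area_bd_mm2, 0.0256)
  expect_equal(call$r_percent, 100)
})
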