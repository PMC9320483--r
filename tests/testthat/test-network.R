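test_that("paper preset meets the printed geometry contract at 1024 px", {
  net <- build_network(network_config(1024L, "paper"), seed = 1L)
  expect_equal(net$shapes$bottleneck_side, 32L)
  expect_equal(net$shapes$output_side, 128L)
  expect_equal(net$shapes$input_side / net$shapes$output_side, 8)
  expect_equal(net$shapes$out_channels, 2L)
})

test_that("the shape contract holds for every input side divisible by 32", {
  for (side in c(32L, 64L, 96L, 256L)) {
    net <- build_network(network_config(side, "small"), seed = 1L)
    expect_equal(net$shapes$output_side, side %/% 8L)
    expect_equal(net$shapes$bottleneck_side, side %/% 32L)
  }
  expect_error(network_config(255L), "divisible by 32")
})

test_that("a real forward pass matches the traced shapes and stays in [0,1]", {
  net <- build_network(network_config(64L, "small"), seed = 2L)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  hm <- predict_tile(net, x)
  expect_equal(dim(hm$probs), c(8, 8, 2))
  expect_true(all(hm$probs >= 0 & hm$probs <= 1))
  # deterministic for fixed weights
  expect_identical(hm$probs, predict_tile(net, x)$probs)
  expect_error(predict_tile(net, array(0, c(32, 32, 3))), "tile must be")
})

test_that("focal loss matches hand-computed values and the gamma=0 limit", {
  # single pixel, target 1, p = 0.5, gamma = 2 -> 0.25 * ln 2
  expect_equal(focal_loss(array(0.5, c(1, 1, 1)), array(1, c(1, 1, 1)),
                          gamma = 2),
               0.25 * log(2), tolerance = 1e-12)
  # exact predictions -> ~0 loss
  y <- array(rbinom(64, 1, 0.5), c(8, 8, 1))
  expect_lt(focal_loss(y, y, gamma = 2), 1e-5)
  # gamma = 0 reduces to mean binary cross-entropy
  withr::with_seed(7, {
    p <- array(runif(200, 0.02, 0.98), c(10, 10, 2))
    yy <- array(rbinom(200, 1, 0.4), c(10, 10, 2))
  })
  bce <- mean(-(yy * log(p) + (1 - yy) * log(1 - p)))
  expect_equal(focal_loss(p, yy, gamma = 0), bce, tolerance = 1e-6)
  expect_error(focal_loss(array(0.5, c(2, 2, 1)), array(1, c(3, 3, 1))),
               "shapes differ")
})

test_that("analytic network gradients agree with finite differences", {
  net <- build_network(network_config(32L, "small"), seed = 3L)
  nf <- bdskseg:::net_forward; nb <- bdskseg:::net_backward
  withr::with_seed(4, {
    x <- array(runif(32 * 32 * 3), c(32, 32, 3))
    y <- array(rbinom(4 * 4 * 2, 1, 0.5), c(4, 4, 2))
  })
  fwd <- nf(net, x)
  g <- nb(net, fwd, bdskseg:::focal_grad(fwd$out, y, 2))
  eps <- 1e-4
  withr::with_seed(5, {
    for (nm in c("stem", "s3b", "d2b", "head")) {
      i <- sample(length(net$params[[nm]]$w), 1)
      up <- net; up$params[[nm]]$w[i] <- up$params[[nm]]$w[i] + eps
      dn <- net; dn$params[[nm]]$w[i] <- dn$params[[nm]]$w[i] - eps
      num <- (focal_loss(nf(up, x)$out, y, 2) -
                focal_loss(nf(dn, x)$out, y, 2)) / (2 * eps)
      # single-precision kernels: expect agreement to a few percent of scale
      expect_lt(abs(g[[nm]]$w[i] - num), 5e-2 * max(abs(num), 1e-3) + 1e-5)
    }
  })
})

test_that("iou follows set arithmetic", {
  a <- matrix(c(1, 1, 0, 0), 2)
  b <- matrix(c(0, 0, 1, 1), 2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, b), 0)
  half <- matrix(c(1, 1, 1, 0), 2)  # |A|=|B|=2 overlap 1 -> 1/3
  expect_equal(iou(matrix(c(1, 1, 0, 0), 2), matrix(c(0, 1, 1, 0), 2)), 1 / 3)
  expect_equal(iou(a * 0, b * 0), 1)
})

test_that("augmentation respects the paired-transform contract", {
  sl <- fixture_bd_slide()
  tile <- extract_tile(sl$image, 128L, 128L, 256L)
  mask <- extract_tile(sl$mask, 128L, 128L, 256L)
  off <- augment_config(rotate = FALSE, flip = FALSE, elastic = FALSE,
                        noise = FALSE, blur = FALSE, photometric = FALSE)
  idn <- augment(tile, mask, seed = 1L, config = off)
  expect_identical(idn$tile, tile)
  expect_identical(idn$mask, mask)

  geo <- augment_config(rotate = TRUE, flip = TRUE, elastic = FALSE,
                        noise = FALSE, blur = FALSE, photometric = FALSE)
  for (s in 1:5) {
    out <- augment(tile, mask, seed = s, config = geo)
    expect_equal(sum(out$mask == 1L), sum(mask == 1L))  # area preserved
  }

  ela <- augment_config(rotate = FALSE, flip = FALSE, elastic = TRUE,
                        elastic_amp = 2, noise = FALSE, blur = FALSE,
                        photometric = FALSE)
  n0 <- sum(mask == 1L)
  for (s in 1:3) {
    out <- augment(tile, mask, seed = s, config = ela)
    expect_lt(abs(sum(out$mask == 1L) - n0) / n0, 0.05)
  }

  # seeded: same seed, same result
  a1 <- augment(tile, mask, seed = 11L)
  a2 <- augment(tile, mask, seed = 11L)
  expect_identical(a1, a2)
})

test_that("slide-level splits are leakage-free and reproducible", {
  samples <- list()
  for (sl in 1:10) for (k in 1:3) {
    samples[[length(samples) + 1L]] <- list(slide = sprintf("s%02d", sl))
  }
  sp <- split_by_slide(samples, 0.8, seed = 1L)
  tr_slides <- unique(vapply(sp$train, function(s) s$slide, ""))
  va_slides <- unique(vapply(sp$val, function(s) s$slide, ""))
  expect_length(tr_slides, 8)
  expect_length(va_slides, 2)
  expect_length(intersect(tr_slides, va_slides), 0)
  sp2 <- split_by_slide(samples, 0.8, seed = 1L)
  expect_identical(sp, sp2)
  expect_error(split_by_slide(list(list(slide = "only")), 0.8, 1L),
               "two slides")
})
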