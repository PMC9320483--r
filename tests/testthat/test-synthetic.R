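test_that("degenerate spec yields a blank slide with empty truth", {
  spec <- synthetic_slide_spec(c(64L, 48L), sections = list(), seed = 1L)
  sl <- generate_slide(spec)
  expect_equal(dim(sl$image), c(48, 64, 3))
  expect_true(all(sl$mask == 0L))
  expect_length(sl$sections, 0)
  expect_true(all(sl$image > 0.85))  # near-white background
})

test_that("generation is bit-deterministic for a fixed spec and seed", {
  spec <- synthetic_slide_spec(
    c(320L, 320L),
    sections = list(section_request("SK", 0.01)), seed = 9L)
  a <- generate_slide(spec)
  b <- generate_slide(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
})

test_that("lesion pixel areas match the requested mm^2 within 10 percent", {
  spec <- synthetic_slide_spec(
    c(512L, 512L), mpp = 1,
    sections = list(section_request("BD", 0.0256)), seed = 3L)
  sl <- generate_slide(spec)
  n_bd <- sum(sl$mask == 1L)
  expect_gt(n_bd, 25600 - 2560)
  expect_lt(n_bd, 25600 + 2560)
  # and at a different mpp the pixel count rescales accordingly
  spec2 <- synthetic_slide_spec(
    c(512L, 512L), mpp = 2,
    sections = list(section_request("BD", 0.0256)), seed = 3L)
  n_bd2 <- sum(generate_slide(spec2)$mask == 1L)
  expect_lt(abs(n_bd2 - 6400), 640)
})

test_that("impossible placements raise an explicit error", {
  expect_error(
    generate_slide(synthetic_slide_spec(
      c(128L, 128L),
      sections = list(section_request("BD", 0.005),
                      section_request("SK", 0.005),
                      section_request("BD", 0.005),
                      section_request("SK", 0.005)),
      seed = 1L)),
    "placement|fit inside")
})

test_that("labelled pixels lie inside section footprints", {
  spec <- synthetic_slide_spec(
    c(768L, 512L),
    sections = list(section_request("SK_with_BD_focus", 0.02),
                    section_request("BD", 0.015)),
    seed = 5L)
  sl <- generate_slide(spec)
  lab <- which(sl$mask > 0L, arr.ind = TRUE)
  inside <- rep(FALSE, nrow(lab))
  for (s in sl$sections) {
    bb <- s$bbox
    inside <- inside | (lab[, "col"] > bb["x0"] & lab[, "col"] <= bb["x1"] &
                          lab[, "row"] > bb["y0"] & lab[, "row"] <= bb["y1"])
  }
  expect_true(all(inside))
  # the collision section reports both a BD focus and the SK remainder
  cs <- sl$sections[[1]]
  expect_gt(cs$area_bd_mm2, 0)
  expect_gt(cs$area_sk_mm2, cs$area_bd_mm2)
})

test_that("cohort class counts follow the mix exactly and round-trip", {
  dir <- withr::local_tempdir()
  man <- generate_cohort(10, c(BD = 0.5, SK = 0.5), seed = 2L, dir = dir,
                         canvas_size_px = c(320L, 320L),
                         lesion_area_mm2 = c(0.008, 0.012))
  expect_equal(unname(table(man$class)["BD"]), 5L)
  expect_equal(unname(table(man$class)["SK"]), 5L)
  back <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(back, man)
})

test_that("a Normal-only cohort has empty label masks", {
  dir <- withr::local_tempdir()
  man <- generate_cohort(3, c(Normal = 1.0), seed = 4L, dir = dir,
                         canvas_size_px = c(320L, 320L),
                         lesion_area_mm2 = c(0.008, 0.012))
  for (mp in unique(man$mask_path)) {
    expect_true(all(read_label_mask(mp) == 0L))
  }
  expect_true(all(man$true_bd_area_mm2 == 0))
  expect_true(all(man$true_sk_area_mm2 == 0))
})

test_that("style shifts change pixels but never masks", {
  dir_a <- withr::local_tempdir(); dir_b <- withr::local_tempdir()
  a <- generate_cohort(2, c(BD = 1.0), seed = 7L, dir = dir_a,
                       canvas_size_px = c(320L, 320L),
                       lesion_area_mm2 = c(0.008, 0.012))
  b <- generate_cohort(2, c(BD = 1.0), seed = 7L, dir = dir_b,
                       canvas_size_px = c(320L, 320L),
                       lesion_area_mm2 = c(0.008, 0.012),
                       style = style_params(hue_shift = 0.06,
                                            brightness = 0.9,
                                            tint = c(0.05, 0, -0.02)))
  for (i in seq_len(nrow(a))) {
    expect_identical(read_label_mask(a$mask_path[i]),
                     read_label_mask(b$mask_path[i]))
    ma <- apply(read_slide_image(a$slide_path[i]), 3, mean)
    mb <- apply(read_slide_image(b$slide_path[i]), 3, mean)
    expect_gt(max(abs(ma - mb)), 0.01)
  }
})

test_that("identity style is a no-op and brightness 0 blacks out", {
  img <- fixture_bd_slide()$image
  expect_identical(apply_style_shift(img, style_params()), img)
  black <- apply_style_shift(img, style_params(brightness = 0))
  expect_true(all(black == 0))
})

test_that("hue rotation inverts within 8-bit rounding", {
  img <- fixture_bd_slide()$image[1:64, 1:64, , drop = FALSE]
  fwd <- apply_style_shift(img, style_params(hue_shift = 0.12))
  back <- apply_style_shift(fwd, style_params(hue_shift = -0.12))
  expect_lt(max(abs(back - img)), 1 / 255)
})
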