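test_that("TPR/FPR follow their definitions and identities", {
  r <- tpr_fpr(tp = 3, fp = 0, tn = 5, fn = 1)
  expect_equal(unname(r["tpr"]), 0.75)
  expect_equal(unname(r["fpr"]), 0)
  r2 <- tpr_fpr(tp = 4, fp = 0, tn = 6, fn = 0)
  expect_equal(unname(r2), c(1, 0))
  # TPR is the sensitivity; 1 - FPR is the specificity
  r3 <- tpr_fpr(tp = 8, fp = 3, tn = 7, fn = 2)
  expect_equal(unname(r3["tpr"]), 8 / 10)
  expect_equal(unname(1 - r3["fpr"]), 7 / 10)
  expect_error(tpr_fpr(0, 1, 1, 0), "TPR undefined")
  expect_error(tpr_fpr(1, 0, 0, 1), "FPR undefined")
})

test_that("F-beta matches the weighted harmonic mean", {
  for (b in c(0.5, 1, 2, 5)) expect_equal(fbeta(0.7, 0.7, b), 0.7)
  expect_equal(fbeta(0.5, 1, 2), 5 * 0.5 / (1 + 4 * 0.5))  # 0.8333...
  expect_equal(fbeta(0.3, 0.8, 1), fbeta(0.8, 0.3, 1))     # F1 symmetric
  expect_equal(fbeta(0, 0, 2), 0)
  # beta -> infinity approaches recall
  expect_equal(fbeta(0.4, 0.9, 100), 0.9, tolerance = 1e-3)
  # monotone in both arguments
  withr::with_seed(3, {
    p <- runif(50); r <- runif(50); d <- runif(50, 0, 1 - pmax(p, r))
  })
  for (i in 1:50) {
    expect_gte(fbeta(min(p[i] + d[i], 1), r[i], 2), fbeta(p[i], r[i], 2))
    expect_gte(fbeta(p[i], min(r[i] + d[i], 1), 2), fbeta(p[i], r[i], 2))
  }
})

test_that("section scores are the largest threshold passing the area test", {
  expect_equal(section_score(make_heatmap(matrix(0, 10, 10)), 0.001), 0)
  const <- make_heatmap(matrix(0.7, 20, 20))  # area 0.0256 mm^2 at any t<=0.7
  expect_equal(section_score(const, 0.01), 0.7)
  # requesting more area than the map holds gives 0
  expect_equal(section_score(const, 1), 0)
  # adding probability mass never lowers the score
  m <- matrix(runif(400), 20, 20)
  s1 <- section_score(make_heatmap(m), 0.005)
  s2 <- section_score(make_heatmap(pmin(m + 0.1, 1)), 0.005)
  expect_gte(s2, s1)
})

test_that("trapezoid AUC equals the pairwise concordance oracle", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(10:100, 1)
      # draws with heavy ties to exercise the mid-rank convention
      scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
      truth <- rbinom(n, 1, 0.5)
      if (length(unique(truth)) < 2) next
      expect_equal(roc_auc(scores, truth)$auc,
                   auc_concordance_oracle(scores, truth),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(12, {
    scores <- c(rnorm(60, 1), rnorm(60, 0))
    truth <- rep(c(1, 0), each = 60)
  })
  ours <- roc_auc(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ROC endpoints and monotonicity hold", {
  withr::with_seed(13, {
    scores <- runif(50); truth <- rbinom(50, 1, 0.4)
  })
  roc <- roc_auc(scores, truth)
  expect_equal(roc$curve$tpr[1], 0)
  expect_equal(roc$curve$fpr[1], 0)
  expect_equal(roc$curve$tpr[nrow(roc$curve)], 1)
  expect_equal(roc$curve$fpr[nrow(roc$curve)], 1)
  # tpr/fpr non-increasing as the threshold increases
  ord <- order(roc$curve$threshold)
  expect_true(all(diff(roc$curve$tpr[ord]) <= 0))
  expect_true(all(diff(roc$curve$fpr[ord]) <= 0))
  expect_equal(roc_auc(c(2, 3, 0, 1), c(1, 1, 0, 0))$auc, 1)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("labels independent of scores give AUC near one half", {
  withr::with_seed(14, {
    scores <- runif(4000); truth <- rbinom(4000, 1, 0.5)
  })
  expect_lt(abs(roc_auc(scores, truth)$auc - 0.5), 0.03)
})

test_that("minimum-area selection maximises AUC, smallest area on ties", {
  # positives: big confident lesions; negatives: small confident speckles
  withr::with_seed(15, {
    maps <- list(); truth <- logical()
    for (i in 1:8) {
      m <- matrix(runif(3600, 0, 0.1), 60, 60)
      m <- plant_blob(m, 1200, 0.85, c(30, 30))  # 0.0768 mm^2 lesion
      maps[[length(maps) + 1L]] <- make_heatmap(m); truth <- c(truth, TRUE)
    }
    for (i in 1:8) {
      m <- matrix(runif(3600, 0, 0.1), 60, 60)
      m <- plant_blob(m, 50, 0.9, c(15 + 3 * i, 20))  # 0.0032 mm^2 speckle
      maps[[length(maps) + 1L]] <- make_heatmap(m); truth <- c(truth, FALSE)
    }
  })
  sel <- select_min_area(maps, truth)
  expect_gt(sel$min_area_mm2, 0.0032)
  expect_lt(sel$min_area_mm2, 0.0768)
  expect_equal(sel$auc, 1)
  # single candidate is returned as-is
  one <- select_min_area(maps, truth, candidates = 0.01)
  expect_equal(one$min_area_mm2, 0.01)
  # explicit tie: both candidates separate perfectly -> smaller wins
  tie <- select_min_area(maps, truth, candidates = c(0.02, 0.01))
  expect_equal(tie$min_area_mm2, 0.01)
})

test_that("threshold selection maximises F-beta, largest threshold on ties", {
  withr::with_seed(16, {
    maps <- list(); truth <- logical()
    for (i in 1:6) {
      maps[[length(maps) + 1L]] <- make_heatmap(matrix(0.8, 30, 30))
      truth <- c(truth, TRUE)
    }
    for (i in 1:6) {
      maps[[length(maps) + 1L]] <- make_heatmap(matrix(0.2, 30, 30))
      truth <- c(truth, FALSE)
    }
  })
  sel <- select_threshold(maps, truth, min_area_mm2 = 0.01, beta = 1)
  # every threshold in (0.2, 0.8] separates perfectly; ties resolve upward
  expect_equal(sel$threshold, 0.8)
  expect_equal(sel$fbeta, 1)
  # argmax contract
  expect_true(all(sel$grid$fbeta <= sel$fbeta + 1e-12))
})

test_that("recall-weighted selection never exceeds the balanced threshold", {
  # construct a precision/recall trade-off: higher thresholds lose recall,
  # gain precision
  withr::with_seed(17, {
    maps <- list(); truth <- logical()
    for (i in 1:12) {  # positives spread over score levels
      maps[[length(maps) + 1L]] <- make_heatmap(matrix(0.2 + 0.06 * i, 30, 30))
      truth <- c(truth, TRUE)
    }
    for (i in 1:12) {  # negatives overlap the lower positive scores
      maps[[length(maps) + 1L]] <- make_heatmap(matrix(0.05 + 0.04 * i, 30, 30))
      truth <- c(truth, FALSE)
    }
  })
  t2 <- select_threshold(maps, truth, 0.01, beta = 2)$threshold
  t1 <- select_threshold(maps, truth, 0.01, beta = 1)$threshold
  expect_lte(t2, t1)
})

test_that("evaluate_calls matches a hand-computed confusion table", {
  truths <- c("BD", "BD", "BD", "SK", "SK", "SK_with_BD_focus", "Normal",
              "Normal", "SK", "BD")
  calls <- c("BD", "BD", "SK", "SK", "BD", "SK", "Normal", "BD", "SK", "BD")
  # BD vs all: TP 3 FN 1; FP 2 TN 4
  r <- evaluate_calls(calls, truths, "BD vs all")
  expect_equal(r$sensitivity, 3 / 4)
  expect_equal(r$specificity, 4 / 6)
  # BD vs SK excludes Normal sections
  r2 <- evaluate_calls(calls, truths, "BD vs SK")
  expect_equal(r2$n, 8)
  expect_equal(r2$sensitivity, 3 / 4)   # same positives -> same sensitivity
  expect_equal(r2$specificity, 3 / 4)
  # shared operating point: sensitivity constant across BD-vs-* rows
  r3 <- evaluate_calls(calls, truths, "BD vs Normal")
  expect_equal(r3$sensitivity, r$sensitivity)
  # SK vs Normal treats irritated SK as SK
  r4 <- evaluate_calls(calls, truths, "SK vs Normal")
  expect_equal(r4$n, 6)
  expect_error(evaluate_calls("BD", "BD", "SK vs Normal"), "empty")
  # perfect calls give perfect rates
  r5 <- evaluate_calls(truths, truths, "BD vs all")
  expect_equal(r5$sensitivity, 1)
  expect_equal(r5$specificity, 1)
})

test_that("calibration recovery separates planted speckle and lesion scales", {
  hits <- 0
  n_seeds <- 8
  for (seed in seq_len(n_seeds)) {
    withr::with_seed(100 + seed, {
      maps <- list(); truth <- logical()
      speckle_max <- 0; lesion_min <- Inf
      for (i in 1:6) {
        m <- matrix(runif(3600, 0, 0.1), 60, 60)
        px <- sample(900:1400, 1)           # > 0.05 mm^2
        lesion_min <- min(lesion_min, pixels_to_mm2(px, 8))
        m <- plant_blob(m, px, runif(1, 0.75, 0.9), c(30, 30))
        maps[[length(maps) + 1L]] <- make_heatmap(m); truth <- c(truth, TRUE)
      }
      for (i in 1:6) {
        m <- matrix(runif(3600, 0, 0.1), 60, 60)
        px <- sample(30:60, 1)              # < 0.005 mm^2
        speckle_max <- max(speckle_max, pixels_to_mm2(px, 8))
        m <- plant_blob(m, px, runif(1, 0.8, 0.95), c(30, 30))
        maps[[length(maps) + 1L]] <- make_heatmap(m); truth <- c(truth, FALSE)
      }
      sel <- select_min_area(maps, truth)
      if (sel$min_area_mm2 > speckle_max && sel$min_area_mm2 < lesion_min) {
        hits <- hits + 1
      }
    })
  }
  expect_gte(hits / n_seeds, 0.9)
})
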