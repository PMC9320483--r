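# Operating-point calibration and evaluation statistics: TPR/FPR, F-beta,
# per-section scores, ROC/AUC, the minimum-area line search (maximise AUC,
# smallest area on ties) and the probability-threshold selection (maximise
# F-beta, largest threshold on ties).

#' True- and false-positive rates from confusion counts
#'
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @return named vector `c(tpr, fpr)`; TPR equals sensitivity and 1 - FPR
#'   equals specificity.
#' @export
tpr_fpr <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn == 0) stop("no positive examples: TPR undefined")
  if (fp + tn == 0) stop("no negative examples: FPR undefined")
  c(tpr = tp / (tp + fn), fpr = fp / (fp + tn))
}

#' F-beta score
#'
#' Weighted harmonic mean of precision and recall,
#' \eqn{F_\beta = (1+\beta^2) \, R \, P / (R + \beta^2 P)}; beta = 2 weights
#' recall (sensitivity) higher, beta = 1 is the symmetric F1.
#'
#' @param precision,recall values in \[0,1\].
#' @param beta non-negative weight; defined as 0 when precision and recall are
#'   both 0.
#' @return score in \[0,1\].
#' @export
fbeta <- function(precision, recall, beta = 1) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1,
            beta >= 0)
  if (precision == 0 && recall == 0) return(0)
  (1 + beta^2) * recall * precision / (recall + beta^2 * precision)
}

#' Per-section continuous score for the ROC sweep
#'
#' The largest probability threshold at which the channel's positive area
#' still reaches `min_area_mm2` (0 if no threshold does). Sweeping a cutoff t
#' over this score reproduces the per-threshold positive/negative section
#' calls: the section is called positive at threshold t iff its score >= t.
#'
#' @param map a `bdsk_section_heatmap` (post-processed).
#' @param min_area_mm2 minimum positive area for the call.
#' @param channel 1 (BD) or 2 (SK).
#' @return scalar score in \[0,1\].
#' @export
section_score <- function(map, min_area_mm2, channel = 1L) {
  stopifnot(inherits(map, "bdsk_section_heatmap"))
  v <- as.vector(map$probs[, , channel])
  n_min <- max(1L, ceiling(mm2_to_pixels(min_area_mm2, map$mpp_out)))
  if (length(v) < n_min) return(0)
  sort(v, decreasing = TRUE)[n_min]
}

#' ROC curve and AUC
#'
#' Curve points are computed at every distinct score cutoff (plus the
#' extremes); the AUC is the trapezoidal integral, which with the mid-rank
#' tie convention equals the pairwise concordance probability.
#'
#' @param scores numeric scores (higher = more positive).
#' @param truth logical (or 0/1) true class per score.
#' @return an object of class `bdsk_roc`: data frame `curve` with columns
#'   `threshold, tpr, fpr`, and attribute-style element `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth))
  npos <- sum(truth); nneg <- sum(!truth)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(cuts, function(t) sum(scores >= t & truth) / npos, 0)
  fpr <- vapply(cuts, function(t) sum(scores >= t & !truth) / nneg, 0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(curve = data.frame(threshold = cuts, tpr = tpr, fpr = fpr),
                 auc = auc),
            class = "bdsk_roc")
}

#' @export
print.bdsk_roc <- function(x, ...) {
  cat(sprintf("ROC curve with %d points, AUC = %.4f\n", nrow(x$curve), x$auc))
  invisible(x)
}

#' Minimum-area line search by AUC
#'
#' For each candidate minimum area the per-section scores are computed and the
#' ROC AUC against the truth is evaluated; the smallest area among those with
#' the highest AUC is selected.
#'
#' @param maps list of post-processed `bdsk_section_heatmap`s.
#' @param truth logical vector: true positive class per section.
#' @param candidates candidate areas in mm^2 (default 20 log-spaced values in
#'   \[0.001, 0.1\]).
#' @param channel heat-map channel for the call (1 = BD, 2 = SK).
#' @return list of class `bdsk_calibration_area`: `min_area_mm2`, `auc`, and
#'   the full `grid` (data frame area/auc).
#' @export
select_min_area <- function(maps, truth, candidates = area_grid(),
                            channel = 1L) {
  stopifnot(length(candidates) >= 1, length(maps) == length(truth))
  aucs <- vapply(candidates, function(a) {
    sc <- vapply(maps, section_score, 0, min_area_mm2 = a, channel = channel)
    roc_auc(sc, truth)$auc
  }, 0)
  best <- which(aucs >= max(aucs) - 1e-12)
  pick <- best[which.min(candidates[best])]
  list(min_area_mm2 = candidates[pick], auc = aucs[pick],
       grid = data.frame(area_mm2 = candidates, auc = aucs))
}

#' Default candidate grids
#'
#' @param n number of grid points.
#' @param range area range in mm^2.
#' @return numeric grid.
#' @export
area_grid <- function(n = 20, range = c(0.001, 0.1)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' @rdname area_grid
#' @param step threshold step size.
#' @export
threshold_grid <- function(step = 0.05) {
  seq(0, 1, by = step)
}

#' Probability-threshold selection by F-beta
#'
#' With the minimum area fixed, every grid threshold t induces section calls
#' (positive iff the section score reaches t); the threshold with the highest
#' F-beta of those calls is selected (largest threshold on ties).
#'
#' @param maps list of post-processed `bdsk_section_heatmap`s.
#' @param truth logical truth per section.
#' @param min_area_mm2 the selected minimum area.
#' @param beta F-beta weight (2 for the BD call, 1 for SK).
#' @param grid candidate thresholds in \[0,1\].
#' @param channel heat-map channel.
#' @return list of class `bdsk_calibration_threshold`: `threshold`, `fbeta`,
#'   `grid` (data frame threshold/fbeta).
#' @export
select_threshold <- function(maps, truth, min_area_mm2, beta = 1,
                             grid = threshold_grid(), channel = 1L) {
  stopifnot(all(grid >= 0 & grid <= 1), length(maps) == length(truth))
  truth <- as.logical(truth)
  sc <- vapply(maps, section_score, 0, min_area_mm2 = min_area_mm2,
               channel = channel)
  fb <- vapply(grid, function(t) {
    pos <- sc >= t
    tp <- sum(pos & truth); fp <- sum(pos & !truth); fn <- sum(!pos & truth)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    fbeta(prec, rec, beta)
  }, 0)
  best <- which(fb >= max(fb) - 1e-12)
  pick <- best[which.max(grid[best])]
  list(threshold = grid[pick], fbeta = fb[pick],
       grid = data.frame(threshold = grid, fbeta = fb))
}

#' Evaluate section calls for one diagnostic comparison
#'
#' Filters the sections to the comparison's subset, then computes the
#' confusion counts of the predicted labels, sensitivity, specificity, and
#' (when scores are supplied) the ROC AUC.
#'
#' @param calls character vector of predicted labels (`BD`/`SK`/`Normal`).
#' @param truths character vector of true classes (`BD`, `SK`,
#'   `SK_with_BD_focus`, `Normal`).
#' @param call_spec one of `"BD vs all"`, `"BD vs SK"`,
#'   `"BD vs SK (non-irrit.)"`, `"BD vs SK (irrit.)"`, `"BD vs Normal"`,
#'   `"SK vs Normal"`.
#' @param scores optional numeric section scores for the positive class, used
#'   for the AUC.
#' @return one-row data frame: call, n, auc, sensitivity, specificity.
#' @export
evaluate_calls <- function(calls, truths, call_spec = "BD vs all",
                           scores = NULL) {
  stopifnot(length(calls) == length(truths))
  spec <- match.arg(call_spec, c("BD vs all", "BD vs SK",
                                 "BD vs SK (non-irrit.)", "BD vs SK (irrit.)",
                                 "BD vs Normal", "SK vs Normal"))
  sk_like <- c("SK", "SK_with_BD_focus")
  subset <- switch(spec,
    "BD vs all" = rep(TRUE, length(truths)),
    "BD vs SK" = truths %in% c("BD", sk_like),
    "BD vs SK (non-irrit.)" = truths %in% c("BD", "SK"),
    "BD vs SK (irrit.)" = truths %in% c("BD", "SK_with_BD_focus"),
    "BD vs Normal" = truths %in% c("BD", "Normal"),
    "SK vs Normal" = truths %in% c(sk_like, "Normal")
  )
  if (!any(subset)) stop("empty evaluation subset for ", spec)
  pos_class <- if (spec == "SK vs Normal") "SK" else "BD"
  truth_pos <- if (pos_class == "BD") truths[subset] == "BD" else
    truths[subset] %in% sk_like
  call_pos <- calls[subset] == pos_class
  tp <- sum(call_pos & truth_pos); fp <- sum(call_pos & !truth_pos)
  fn <- sum(!call_pos & truth_pos); tn <- sum(!call_pos & !truth_pos)
  rates <- tpr_fpr(tp, fp, tn, fn)
  auc <- if (!is.null(scores)) {
    roc_auc(scores[subset], truth_pos)$auc
  } else NA_real_
  data.frame(call = spec, n = sum(subset), auc = auc,
             sensitivity = unname(rates["tpr"]),
             specificity = unname(1 - rates["fpr"]))
}

#' Calibrate one diagnostic call end to end
#'
#' Runs the minimum-area line search (AUC) followed by the threshold selection
#' (F-beta) on the same sections, mirroring the two-stage hyper-parameter
#' procedure.
#'
#' @param maps list of post-processed `bdsk_section_heatmap`s
#'   (training + validation sections combined).
#' @param truth logical truth for the call's positive class.
#' @param call name recorded in the result (e.g. `"BD vs all"`).
#' @param channel heat-map channel (1 = BD, 2 = SK).
#' @param beta F-beta weight.
#' @param areas,thresholds candidate grids.
#' @return an object of class `bdsk_calibration`: call, beta, selected
#'   `min_area_mm2` with its `auc`, selected `threshold` with its `fbeta`, and
#'   both search grids.
#' @export
calibrate_call <- function(maps, truth, call = "BD vs all", channel = 1L,
                           beta = 2, areas = area_grid(),
                           thresholds = threshold_grid()) {
  a <- select_min_area(maps, truth, areas, channel)
  t <- select_threshold(maps, truth, a$min_area_mm2, beta, thresholds, channel)
  structure(list(call = call, channel = channel, beta = beta,
                 min_area_mm2 = a$min_area_mm2, auc = a$auc,
                 threshold = t$threshold, fbeta = t$fbeta,
                 area_grid = a$grid, threshold_grid = t$grid),
            class = "bdsk_calibration")
}

#' @export
print.bdsk_calibration <- function(x, ...) {
  cat(sprintf(
    "%s: min area %.4f mm^2 (AUC %.4f), threshold %.2f (F%g = %.4f)\n",
    x$call, x$min_area_mm2, x$auc, x$threshold, x$beta, x$fbeta))
  invisible(x)
}
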