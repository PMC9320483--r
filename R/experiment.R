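# Reproducible desk-scale end-to-end experiment: synthetic cohorts, training,
# calibration, held-out section-level evaluation.

#' Desk-scale BD-vs-SK benchmark on synthetic cohorts
#'
#' Generates a training and a held-out test cohort of synthetic slides
#' (equal BD/SK mix), fits the small-preset model on 256 px tiles with the
#' two-stage operating-point calibration, and evaluates the section-level
#' BD-vs-SK call on the test cohort.
#'
#' @param seed integer seed driving cohort generation, network initialisation
#'   and training.
#' @param n_train,n_test cohort sizes in slides (defaults 30 and 20).
#' @param separability lesion texture separability (default 0.9).
#' @param epochs training epochs (default 10).
#' @param input_side tile side in px (default 256).
#' @param lr,batch_size optimiser settings for the small preset.
#' @param dir working directory for the cohorts (a temporary directory by
#'   default; removed afterwards unless supplied).
#' @param verbose print training progress.
#' @return list with `auc`, `sensitivity`, `specificity` (BD vs SK on the
#'   test cohort), `val_iou` (best validation IoU), `model` (the fitted
#'   `bdsk_model`) and `sections` (per-section test results).
#' @export
bd_sk_benchmark <- function(seed = 1L, n_train = 30L, n_test = 20L,
                            separability = 0.9, epochs = 10L,
                            input_side = 256L, lr = 1e-3, batch_size = 1L,
                            dir = NULL, verbose = FALSE) {
  cleanup <- is.null(dir)
  if (is.null(dir)) dir <- tempfile("bdsk_bench")
  on.exit(if (cleanup) unlink(dir, recursive = TRUE), add = TRUE)
  man_train <- generate_cohort(
    n_train, c(BD = 0.5, SK = 0.5), seed = child_seed(seed, 1L),
    dir = file.path(dir, "train"), separability = separability)
  man_test <- generate_cohort(
    n_test, c(BD = 0.5, SK = 0.5), seed = child_seed(seed, 2L),
    dir = file.path(dir, "test"), separability = separability,
    split = "test")
  fit <- bdsk_fit(
    man_train, input_side = input_side, preset = "small",
    training = training_config(
      gamma = 2, lr = lr, batch_size = batch_size, epochs = epochs,
      augment = augment_config(elastic = FALSE, blur = FALSE), seed = seed),
    seed = seed, verbose = verbose)
  ev <- evaluate_model(fit, man_test, call_specs = "BD vs SK")
  list(auc = ev$metrics$auc, sensitivity = ev$metrics$sensitivity,
       specificity = ev$metrics$specificity,
       val_iou = max(fit$history$val_iou, na.rm = TRUE),
       model = fit, sections = ev$sections)
}
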