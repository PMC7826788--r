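# Overlap metrics from pixel confusion counts: Dice, sensitivity (recall of
# the lung), positive predictive value (precision), plus mean +/- sd
# aggregation across cross-validation folds.

#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth H x W binary matrices of identical shape.
#' @return List with integer fields `tp`, `fp`, `fn`, `tn` summing to the
#'   pixel count. `tn` is tracked for completeness; the overlap metrics never
#'   use it.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop("prediction (", paste(dim(pred), collapse = "x"), ") and truth (",
         paste(dim(truth), collapse = "x"), ") shapes differ")
  }
  if (!all(pred %in% c(0L, 1L)) || !all(truth %in% c(0L, 1L))) {
    stop("masks must be binary")
  }
  p <- pred == 1L
  t <- truth == 1L
  list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t))
}

#' Dice, sensitivity and PPV from confusion counts
#'
#' Dice = 2 TP / ((TP+FP) + (TP+FN)), sensitivity = TP / (TP+FN),
#' PPV = TP / (TP+FP). Degenerate denominators follow the standard
#' convention: with TP = FP = FN = 0 (empty truth, empty prediction) all
#' three metrics are 1; otherwise a metric whose denominator is 0 is 0.
#'
#' @param counts A list with fields `tp`, `fp`, `fn` (as from
#'   [confusion_counts()]).
#' @return List with numeric fields `dice`, `sensitivity`, `ppv`, each in
#'   unit range.
#' @export
segmentation_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp == 0 && fp == 0 && fn == 0) {
    return(list(dice = 1, sensitivity = 1, ppv = 1))
  }
  list(
    dice = 2 * tp / ((tp + fp) + (tp + fn)),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
    ppv = if (tp + fp > 0) tp / (tp + fp) else 0
  )
}

#' Compare two masks directly
#'
#' Convenience wrapper: [confusion_counts()] followed by
#' [segmentation_metrics()].
#'
#' @inheritParams confusion_counts
#' @return As [segmentation_metrics()].
#' @export
mask_metrics <- function(pred, truth) {
  segmentation_metrics(confusion_counts(pred, truth))
}

#' Aggregate per-fold metrics into mean and standard deviation
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of each
#' metric across folds, the convention used to report five-fold
#' cross-validation results. A single fold reports sd 0.
#'
#' @param folds List of metric results (each with `dice`, `sensitivity`,
#'   `ppv`).
#' @return Data frame with one row per metric and columns `metric`, `mean`,
#'   `sd`, `formatted` (e.g. `"0.982 ± 0.002"`).
#' @export
aggregate_metrics <- function(folds) {
  if (length(folds) == 0L) stop("no folds to aggregate")
  metrics <- c("dice", "sensitivity", "ppv")
  rows <- lapply(metrics, function(m) {
    v <- vapply(folds, function(f) as.numeric(f[[m]]), numeric(1))
    mu <- mean(v)
    s <- if (length(v) > 1L) stats::sd(v) else 0
    data.frame(metric = m, mean = mu, sd = s,
               formatted = format_mean_sd(mu, s), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Format a mean and standard deviation for reporting
#'
#' @param mean,sd Numeric scalars.
#' @param digits Decimal places (default 3, the convention for Dice tables).
#' @return Character scalar like `"0.982 ± 0.002"`.
#' @export
format_mean_sd <- function(mean, sd, digits = 3L) {
  sprintf("%.*f ± %.*f", digits, mean, digits, sd)
}
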