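#' Confusion counts for binary predictions
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param positive_label The label counted as positive (minority class).
#' @return A \code{costlearn_confusion} list with fields \code{tp},
#'   \code{fp}, \code{tn}, \code{fn}; the four counts always sum to the
#'   number of evaluated instances.
#' @export
confusion_counts <- function(true_labels, predicted_labels, positive_label) {
  if (length(true_labels) != length(predicted_labels))
    stop("true and predicted label vectors must have equal length")
  tp <- sum(true_labels == positive_label & predicted_labels == positive_label)
  fn <- sum(true_labels == positive_label & predicted_labels != positive_label)
  fp <- sum(true_labels != positive_label & predicted_labels == positive_label)
  tn <- sum(true_labels != positive_label & predicted_labels != positive_label)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "costlearn_confusion")
}

#' Imbalance-aware performance metrics from confusion counts
#'
#' Computes sensitivity (TP rate), specificity (TN rate), precision, the
#' Matthews correlation coefficient
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)},}
#' the G-mean \eqn{\sqrt{sensitivity \cdot specificity}} and the F-measure
#' (harmonic mean of sensitivity and precision). Zero-denominator
#' conventions: MCC is 0 when any marginal is zero; sensitivity,
#' specificity and precision are 0 when their denominator is zero;
#' F-measure is 0 when sensitivity + precision is zero.
#'
#' @param counts A [confusion_counts()] object, or a list with fields
#'   \code{tp}, \code{fp}, \code{tn}, \code{fn}.
#' @return Named numeric vector with elements \code{mcc}, \code{g_mean},
#'   \code{f_measure}, \code{sensitivity}, \code{specificity},
#'   \code{precision}.
#' @examples
#' compute_metrics(list(tp = 20, fp = 10, tn = 65, fn = 5))
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fp + tn + fn <= 0) stop("empty confusion table")
  safe_div <- function(num, den) if (den > 0) num / den else 0
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else 0
  g <- sqrt(sens * spec)
  f <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
  c(mcc = mcc, g_mean = g, f_measure = f,
    sensitivity = sens, specificity = spec, precision = prec)
}

#' Repeated stratified cross-validation plan
#'
#' Builds the partition scheme used for every evaluation in the package:
#' \code{repeats} independent rounds of stratified \code{folds}-fold
#' cross-validation (default 5 folds x 4 repeats = 20 train/test
#' partitions, each with 80\%/20\% of the records). Within a repeat, each
#' class's indices are shuffled with the plan RNG and dealt round-robin into
#' folds, so every fold's class proportions match the whole dataset within
#' rounding and the test folds of a repeat partition the instances exactly.
#'
#' @param data A [dataset()].
#' @param folds Folds per repeat (default 5); every class must have at
#'   least this many instances.
#' @param repeats Number of repeats (default 4).
#' @param seed Integer seed; identical seeds give identical plans.
#' @return A \code{costlearn_cv_plan}: list with \code{partitions} (each a
#'   list with \code{train}, \code{test}, \code{repeat_id}, \code{fold}),
#'   plus \code{folds}, \code{repeats}, \code{seed}, \code{n}.
#' @export
make_cv_plan <- function(data, folds = 5L, repeats = 4L, seed = 1L) {
  stopifnot(inherits(data, "costlearn_dataset"), folds >= 2, repeats >= 1)
  I <- n_instances(data)
  pos <- is_positive(data)
  if (min(sum(pos), sum(!pos)) < folds)
    stop("each class needs at least `folds` = ", folds,
         " instances; use fewer folds for this dataset")
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  partitions <- list()
  for (r in seq_len(repeats)) {
    fold_of <- integer(I)
    for (cls in list(which(pos), which(!pos))) {
      sh <- sample(cls)
      fold_of[sh] <- rep_len(seq_len(folds), length(sh))
    }
    for (f in seq_len(folds)) {
      test <- which(fold_of == f)
      partitions[[length(partitions) + 1L]] <-
        list(train = which(fold_of != f), test = test,
             repeat_id = r, fold = f)
    }
  }
  structure(list(partitions = partitions, folds = as.integer(folds),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 n = I),
            class = "costlearn_cv_plan")
}

#' @export
print.costlearn_cv_plan <- function(x, ...) {
  cat(sprintf("<costlearn_cv_plan> %d-fold x %d repeats on %d instances (seed %d)\n",
              x$folds, x$repeats, x$n, x$seed))
  invisible(x)
}

# Save/restore the global RNG state around seeded internal draws.
preserve_rng <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
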