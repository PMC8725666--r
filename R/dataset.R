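#' Two-class expression-style dataset
#'
#' The canonical in-memory container used throughout the package: a numeric
#' matrix of continuous feature values (instances in rows, features in
#' columns) plus a binary class label per instance. By the usual convention
#' in imbalanced learning, the minority class is the *positive* class.
#'
#' @param features Numeric matrix, instances x features. Column names are
#'   taken as feature names; unnamed columns are named \code{V1..Vn}.
#' @param labels Character vector (or factor) of per-instance class labels;
#'   exactly two distinct values must be present.
#' @param positive_label Which label is the positive (minority) class. If
#'   \code{NULL}, the rarer label is chosen; ties are broken in favour of the
#'   label that occurs first in \code{labels}.
#'
#' @return An object of class \code{"costlearn_dataset"}: a list with
#'   elements \code{features}, \code{labels} (character), and
#'   \code{positive_label}.
#' @examples
#' x <- matrix(rnorm(20), nrow = 5)
#' d <- dataset(x, c("a", "a", "b", "b", "b"))
#' d$positive_label  # "a" (minority)
#' @export
dataset <- function(features, labels, positive_label = NULL) {
  if (!is.matrix(features) || !is.numeric(features))
    stop("`features` must be a numeric matrix")
  if (anyNA(features))
    stop("`features` contains missing values; complete matrices are required")
  labels <- as.character(labels)
  if (length(labels) != nrow(features))
    stop("length(labels) must equal nrow(features)")
  lv <- unique(labels)
  if (length(lv) != 2L)
    stop("exactly two class labels are required, found ", length(lv),
         " (binary classification only)")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("V", seq_len(ncol(features)))
  if (anyDuplicated(colnames(features)))
    stop("duplicate feature names are not allowed")
  if (is.null(positive_label)) {
    counts <- table(factor(labels, levels = lv))  # levels in first-seen order
    positive_label <- names(counts)[which.min(counts)]  # tie -> first seen
  } else {
    positive_label <- as.character(positive_label)
    if (!positive_label %in% lv)
      stop("positive_label '", positive_label, "' does not occur in the data")
    if (sum(labels == positive_label) > sum(labels != positive_label))
      warning("designated positive class is the majority class")
  }
  structure(
    list(features = features, labels = labels,
         positive_label = positive_label),
    class = "costlearn_dataset"
  )
}

#' @export
print.costlearn_dataset <- function(x, ...) {
  np <- sum(x$labels == x$positive_label)
  cat(sprintf(
    "<costlearn_dataset> %d instances x %d features | positive = '%s' (%d, %.1f%%)\n",
    nrow(x$features), ncol(x$features), x$positive_label, np,
    100 * np / nrow(x$features)))
  invisible(x)
}

#' Number of instances / features in a dataset
#' @param data A \code{costlearn_dataset}.
#' @return Integer count.
#' @export
n_instances <- function(data) nrow(data$features)

#' @rdname n_instances
#' @export
n_features <- function(data) ncol(data$features)

#' Logical vector marking positive (minority-class) instances
#' @param data A \code{costlearn_dataset}.
#' @return Logical vector of length \code{n_instances(data)}.
#' @export
is_positive <- function(data) data$labels == data$positive_label

#' Restrict a dataset to a subset of instances and/or features
#'
#' Used by the cross-validation harness to build per-fold training and test
#' splits, and by the learning strategies to restrict to selected features.
#' Both classes need not be present in the result (a test fold may
#' occasionally lack positives); downstream operations that require both
#' classes validate their own inputs.
#'
#' @param data A \code{costlearn_dataset}.
#' @param instances Integer indices of instances to keep (default all).
#' @param features Integer indices of features to keep (default all).
#' @return A \code{costlearn_dataset} (built without re-deriving the positive
#'   label, which is inherited).
#' @export
subset_dataset <- function(data, instances = NULL, features = NULL) {
  if (is.null(instances)) instances <- seq_len(n_instances(data))
  if (is.null(features)) features <- seq_len(n_features(data))
  out <- list(
    features = data$features[instances, features, drop = FALSE],
    labels = data$labels[instances],
    positive_label = data$positive_label
  )
  structure(out, class = "costlearn_dataset")
}

# Internal: 0/1 indicator of the positive class.
class_indicator <- function(data) as.numeric(is_positive(data))

# Internal: validate instance weights against a dataset; NULL -> uniform.
check_weights <- function(weights, I) {
  if (is.null(weights)) weights <- rep(1, I)
  if (!is.numeric(weights) || length(weights) != I)
    stop("instance weights must be a numeric vector of length ", I)
  if (any(weights < 0)) stop("instance weights must be non-negative")
  if (sum(weights) <= 0) stop("at least one instance weight must be positive")
  weights
}

# Internal: both classes must carry positive weight.
check_two_classes <- function(data, weights) {
  pos <- is_positive(data)
  if (sum(weights[pos]) <= 0 || sum(weights[!pos]) <= 0)
    stop("degenerate input: both classes must be represented with positive weight")
  invisible(TRUE)
}
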