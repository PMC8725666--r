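#' Random-forest configuration
#'
#' The base learner used throughout: a forest of 100 trees in which each
#' split chooses the best of \code{floor(log2(n)) + 1} randomly drawn
#' candidate features, n being the number of features the model is trained
#' on (i.e. after any selection). Trees are grown to purity
#' (\code{min.node.size = 1}) and class probabilities are averaged leaf
#' class proportions across trees.
#'
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed making training deterministic.
#' @return A \code{forest_config} list.
#' @export
forest_config <- function(n_trees = 100L, seed = 1L) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "forest_config")
}

#' Train a random forest on a selected feature subset
#'
#' @param data A [dataset()] (the training split).
#' @param selected Integer indices of the features to train on (default: all
#'   features). Must be non-empty and within range.
#' @param weights Optional non-negative instance weights (e.g. from
#'   [weights_from_costs()]); only their relative sizes matter. Uniform
#'   weights are always passed explicitly to the backend so that runs with
#'   proportional weight vectors and the same seed are identical.
#' @param config A [forest_config()].
#' @return A \code{costlearn_forest} exposing probability estimation via
#'   [predict_prob()].
#' @export
train_forest <- function(data, selected = NULL, weights = NULL,
                         config = forest_config()) {
  stopifnot(inherits(data, "costlearn_dataset"),
            inherits(config, "forest_config"))
  n_all <- n_features(data)
  if (is.null(selected)) selected <- seq_len(n_all)
  selected <- as.integer(selected)
  if (length(selected) == 0L) stop("empty feature selection")
  if (any(selected < 1L | selected > n_all))
    stop("selected feature indices out of range 1..", n_all)
  w <- check_weights(weights, n_instances(data))
  check_two_classes(data, w)

  X <- data$features[, selected, drop = FALSE]
  neg_label <- setdiff(unique(data$labels), data$positive_label)
  y <- factor(data$labels, levels = c(data$positive_label, neg_label))
  mtry <- min(floor(log2(ncol(X))) + 1L, ncol(X))
  fit <- ranger::ranger(
    x = as.data.frame(X), y = y,
    num.trees = config$n_trees, mtry = mtry,
    probability = TRUE, min.node.size = 1,
    case.weights = w, seed = config$seed, num.threads = 1
  )
  structure(
    list(fit = fit, selected = selected, n_input_features = n_all,
         positive_label = data$positive_label, negative_label = neg_label,
         config = config),
    class = "costlearn_forest"
  )
}

#' Positive-class probability estimates
#'
#' @param model A \code{costlearn_forest}.
#' @param newdata A [dataset()] or numeric matrix. A matrix may carry either
#'   the full original feature set (the model's selection is applied) or
#'   exactly the selected features.
#' @return Numeric vector of P(positive | x), one entry per instance.
#' @export
predict_prob <- function(model, newdata) {
  stopifnot(inherits(model, "costlearn_forest"))
  X <- if (inherits(newdata, "costlearn_dataset")) newdata$features else newdata
  if (!is.matrix(X)) stop("newdata must be a dataset or numeric matrix")
  if (ncol(X) == model$n_input_features) {
    X <- X[, model$selected, drop = FALSE]
  } else if (ncol(X) != length(model$selected)) {
    stop("dimension mismatch: newdata has ", ncol(X), " features; expected ",
         model$n_input_features, " (full) or ", length(model$selected),
         " (selected)")
  }
  pr <- stats::predict(model$fit, data = as.data.frame(X),
                       num.threads = 1)$predictions
  as.numeric(pr[, model$positive_label])
}

#' Cost-blind label prediction
#'
#' Classifies positive iff P(positive | x) >= 0.5 (a tie goes to positive,
#' matching the minimum-expected-cost rule at symmetric costs, to which this
#' is identical for c = 1).
#'
#' @inheritParams predict_prob
#' @return Character vector of predicted labels.
#' @export
predict_default <- function(model, newdata) {
  p <- predict_prob(model, newdata)
  ifelse(p >= 0.5, model$positive_label, model$negative_label)
}

#' Minimum-expected-cost label prediction
#'
#' Classifies positive iff P(positive | x) >= pth, with pth from
#' [threshold_from_costs()]; equivalently, picks the label minimizing the
#' conditional risk of [expected_costs()].
#'
#' @inheritParams predict_prob
#' @param costs A [cost_matrix()].
#' @return Character vector of predicted labels.
#' @export
predict_min_cost <- function(model, newdata, costs) {
  p <- predict_prob(model, newdata)
  pth <- threshold_from_costs(costs)
  ifelse(p >= pth, model$positive_label, model$negative_label)
}
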