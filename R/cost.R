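#' Misclassification cost matrix
#'
#' Two-class cost matrix C(i, j): the cost of classifying a true-class-i
#' instance as class j. Correct predictions cost 0; the false-negative cost
#' (a positive classified negative) is \code{fn_cost}, conventionally the
#' tunable parameter c, and the false-positive cost is fixed at
#' \code{fp_cost} (unit by convention). Both off-diagonal costs must be
#' strictly positive; negative-diagonal "rewards" are not supported.
#'
#' @param fn_cost Cost C(+,-) of a false negative (default 1).
#' @param fp_cost Cost C(-,+) of a false positive (default 1).
#' @return A \code{costlearn_costs} object.
#' @examples
#' cost_matrix(fn_cost = 4)   # penalize missed minority instances 4x
#' @export
cost_matrix <- function(fn_cost = 1, fp_cost = 1) {
  stopifnot(is.numeric(fn_cost), is.numeric(fp_cost),
            length(fn_cost) == 1L, length(fp_cost) == 1L)
  if (fn_cost <= 0 || fp_cost <= 0)
    stop("off-diagonal costs must be strictly positive")
  structure(list(fn_cost = fn_cost, fp_cost = fp_cost),
            class = "costlearn_costs")
}

#' @export
print.costlearn_costs <- function(x, ...) {
  cat(sprintf("<costlearn_costs> C(+,-) = %g (false negative), C(-,+) = %g (false positive)\n",
              x$fn_cost, x$fp_cost))
  invisible(x)
}

#' Minimum-expected-cost probability threshold
#'
#' The threshold pth = C(-,+) / (C(-,+) + C(+,-)) above (or at) which an
#' instance should be classified positive to minimize expected cost. With
#' symmetric costs pth = 0.5; raising the false-negative cost c lowers the
#' threshold, admitting more positive predictions.
#'
#' @param costs A [cost_matrix()].
#' @return Threshold in (0, 1).
#' @examples
#' threshold_from_costs(cost_matrix(fn_cost = 4))  # 0.2
#' @export
threshold_from_costs <- function(costs) {
  stopifnot(inherits(costs, "costlearn_costs"))
  costs$fp_cost / (costs$fp_cost + costs$fn_cost)
}

#' Per-class expected costs and the minimum-cost label
#'
#' Conditional risk of each decision given the positive-class probability:
#' R(negative | x) = P(+|x) C(+,-) and R(positive | x) = (1 - P(+|x)) C(-,+).
#' The minimum-cost label is the argmin; an exact tie goes to positive,
#' consistent with the ">= pth" threshold rule, to which this decision is
#' equivalent for every valid cost matrix.
#'
#' @param p_pos Probability (or vector of probabilities) of the positive
#'   class, in [0, 1].
#' @param costs A [cost_matrix()].
#' @return A data.frame with columns \code{r_positive}, \code{r_negative}
#'   (expected cost of predicting positive / negative) and \code{label}
#'   ("positive" or "negative").
#' @examples
#' expected_costs(0.3, cost_matrix(fn_cost = 4))  # R(-)=1.2, R(+)=0.7 -> positive
#' @export
expected_costs <- function(p_pos, costs) {
  stopifnot(inherits(costs, "costlearn_costs"),
            all(p_pos >= 0), all(p_pos <= 1))
  r_neg <- p_pos * costs$fn_cost
  r_pos <- (1 - p_pos) * costs$fp_cost
  data.frame(
    r_positive = r_pos,
    r_negative = r_neg,
    label = ifelse(r_pos <= r_neg, "positive", "negative"),
    stringsAsFactors = FALSE
  )
}

#' Cost-proportional instance weights
#'
#' Assigns each instance the misclassification cost of its class -- C(+,-)
#' for positives, C(-,+) for negatives -- then rescales so the total weight
#' equals the number of instances I (total-mass preservation, keeping the
#' learner's effective sample size comparable across cost settings).
#' Symmetric costs give uniform unit weights, and scaling both off-diagonal
#' costs jointly leaves the weights unchanged.
#'
#' @param data A [dataset()].
#' @param costs A [cost_matrix()].
#' @return Numeric weight vector of length \code{n_instances(data)},
#'   summing to I.
#' @examples
#' d <- dataset(matrix(rnorm(20), 10), rep(c("p", "n"), c(2, 8)))
#' weights_from_costs(d, cost_matrix(fn_cost = 4))  # positives 2.5, negatives 0.625
#' @export
weights_from_costs <- function(data, costs) {
  stopifnot(inherits(data, "costlearn_dataset"),
            inherits(costs, "costlearn_costs"))
  raw <- ifelse(is_positive(data), costs$fn_cost, costs$fp_cost)
  raw * n_instances(data) / sum(raw)
}
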