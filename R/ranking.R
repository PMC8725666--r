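#' Ranked feature lists
#'
#' All six ranking heuristics return a \code{costlearn_ranking}: the feature
#' indices ordered from most to least relevant, with the per-feature scores
#' aligned to that order. Equal scores are broken by the lower original
#' feature index (stable ordering), so every ranker is deterministic and
#' invariant to instance order.
#'
#' @param scores Per-feature relevance scores in original feature order.
#' @param method Label of the heuristic that produced the scores.
#' @param feature_names Optional feature names.
#' @return A \code{costlearn_ranking} with elements \code{order} (permutation
#'   of \code{1..n}), \code{scores} (non-increasing, aligned to
#'   \code{order}), \code{method}, \code{feature_names}.
#' @keywords internal
#' @export
ranked_list <- function(scores, method, feature_names = NULL) {
  scores <- unname(scores)
  ord <- order(-scores, seq_along(scores), method = "radix")
  structure(
    list(order = ord, scores = scores[ord], method = method,
         feature_names = feature_names),
    class = "costlearn_ranking"
  )
}

#' @export
print.costlearn_ranking <- function(x, n = 5L, ...) {
  cat(sprintf("<costlearn_ranking> %s over %d features; top %d:\n",
              x$method, length(x$order), min(n, length(x$order))))
  top <- seq_len(min(n, length(x$order)))
  nm <- if (!is.null(x$feature_names)) x$feature_names[x$order[top]] else x$order[top]
  print(data.frame(feature = nm, score = x$scores[top]))
  invisible(x)
}

rank_preamble <- function(data, weights) {
  stopifnot(inherits(data, "costlearn_dataset"))
  w <- check_weights(weights, n_instances(data))
  if (sum(w > 0) < 2L) stop("degenerate input: need at least 2 positively weighted instances")
  check_two_classes(data, w)
  w
}

#' Rank features by weighted Pearson correlation with the class
#'
#' Scores each feature by the absolute value of its weighted Pearson
#' correlation with the 0/1 positive-class indicator. Moments are weighted by
#' the (normalized) instance weights, so integer weights behave exactly like
#' replicated instances and uniform weights give the classic unweighted
#' correlation. Constant features score 0.
#'
#' @param data A [dataset()].
#' @param weights Optional non-negative per-instance weights (default
#'   uniform), e.g. from [weights_from_costs()] for cost-sensitive selection.
#' @return A \code{costlearn_ranking}.
#' @export
rank_correlation <- function(data, weights = NULL) {
  w <- rank_preamble(data, weights)
  wn <- w / sum(w)
  y <- class_indicator(data)
  X <- data$features
  mx <- as.numeric(crossprod(X, wn))           # weighted column means
  my <- sum(wn * y)
  Xc <- sweep(X, 2L, mx)
  yc <- y - my
  cov_xy <- as.numeric(crossprod(Xc, wn * yc))
  var_x <- as.numeric(crossprod(Xc^2, wn))
  var_y <- sum(wn * yc^2)
  denom <- sqrt(var_x * var_y)
  score <- ifelse(denom > 0, abs(cov_xy / denom), 0)
  ranked_list(score, "corr", colnames(X))
}

#' Rank features by information gain (MDL-discretized)
#'
#' Each continuous feature is first discretized by recursive MDL-accepted
#' binary splits (see [mdl_cut_points()]); the score is the reduction in
#' class entropy (bits), H(Y) - H(Y|X), computed from weighted counts.
#' Features with no accepted cut point collapse to one bin and score 0.
#'
#' @inheritParams rank_correlation
#' @return A \code{costlearn_ranking}.
#' @export
rank_info_gain <- function(data, weights = NULL) {
  ranked_list(ig_gr_scores(data, weights)[, "ig"], "ig", colnames(data$features))
}

#' Rank features by gain ratio (MDL-discretized)
#'
#' Information gain divided by the split information
#' \eqn{-\sum_i (|X_i|/I) \log_2 (|X_i|/I)} of the same MDL discretization,
#' which compensates the gain's bias toward features that fragment the data
#' into many bins. Single-bin features (no accepted cut) score 0 by
#' convention.
#'
#' @inheritParams rank_correlation
#' @return A \code{costlearn_ranking}.
#' @export
rank_gain_ratio <- function(data, weights = NULL) {
  s <- ig_gr_scores(data, weights)
  gr <- ifelse(s[, "split_info"] > 0, s[, "ig"] / s[, "split_info"], 0)
  ranked_list(gr, "gr", colnames(data$features))
}

ig_gr_scores <- function(data, weights = NULL) {
  w <- rank_preamble(data, weights)
  y <- class_indicator(data)
  keep <- w > 0
  out <- t(vapply(seq_len(n_features(data)), function(j) {
    x <- data$features[keep, j]
    cuts <- mdl_cut_points(x, y[keep], w[keep])
    if (!length(cuts)) return(c(ig = 0, split_info = 0))
    binned_ig_split(assign_bins(x, cuts), y[keep], w[keep])
  }, numeric(2)))
  colnames(out) <- c("ig", "split_info")
  out
}

#' Rank features by ReliefF
#'
#' Classic two-class ReliefF: every instance is used once as the probe
#' \eqn{R_i} (m = I), its k nearest hits (same class) and k nearest misses
#' (opposite class) are located by Manhattan distance on range-normalized
#' features, and each feature's weight is decreased by the average hit
#' difference and increased by the average miss difference, both scaled by
#' 1/m. Numeric differences are |a - b| / (max - min) over the dataset, so a
#' constant feature always scores 0.
#'
#' Instance weights are interpreted as multiplicities: a probe contributes
#' proportionally to its weight, and neighbor mass is accumulated along the
#' distance ordering up to k (the boundary neighbor enters fractionally; a
#' probe with weight above 1 contributes mass w - 1 of itself at distance 0
#' to its own hit pool). With integer weights this reproduces, exactly, the
#' unweighted computation on the instance-replicated dataset with the same
#' k; with unit weights it is the classic algorithm.
#'
#' @inheritParams rank_correlation
#' @param k_neighbors Number of hits/misses averaged per probe (default 10,
#'   the customary choice); clamped to the available per-class neighbor mass.
#' @return A \code{costlearn_ranking}.
#' @export
rank_relieff <- function(data, weights = NULL, k_neighbors = 10) {
  w <- rank_preamble(data, weights)
  stopifnot(k_neighbors >= 1)
  keep <- which(w > 0)
  X <- data$features[keep, , drop = FALSE]
  wv <- w[keep]
  pos <- is_positive(data)[keep]
  I <- length(keep)
  n <- ncol(X)

  rng <- apply(X, 2L, function(col) diff(range(col)))
  ok <- rng > 0
  Xn <- X[, ok, drop = FALSE]
  Xn <- sweep(Xn, 2L, rng[ok], "/")
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))

  score <- numeric(n)
  total_w <- sum(wv)
  idx_pos <- which(pos); idx_neg <- which(!pos)
  for (i in seq_len(I)) {
    same <- if (pos[i]) idx_pos else idx_neg
    opp  <- if (pos[i]) idx_neg else idx_pos
    same <- setdiff(same, i)

    # hit pool: self-copies first (distance 0), then same-class neighbors
    hit_idx <- same[order(D[i, same], same, method = "radix")]
    hit_mass <- wv[hit_idx]
    self_extra <- max(wv[i] - 1, 0)
    if (self_extra > 0) {
      hit_idx <- c(i, hit_idx)
      hit_mass <- c(self_extra, hit_mass)
    }
    miss_idx <- opp[order(D[i, opp], opp, method = "radix")]
    miss_mass <- wv[miss_idx]

    take <- function(mass, k) {
      cum <- cumsum(mass)
      kk <- min(k, cum[length(cum)])
      nfull <- sum(cum <= kk)
      c_take <- mass
      if (nfull < length(mass)) {
        c_take[(nfull + 1L):length(mass)] <- 0
        got <- if (nfull > 0) cum[nfull] else 0
        if (got < kk) c_take[nfull + 1L] <- kk - got
      }
      list(take = c_take, k_eff = kk)
    }
    h <- take(hit_mass, k_neighbors)
    m <- take(miss_mass, k_neighbors)

    diffs_for <- function(idx, take) {
      use <- take > 0
      if (!any(use)) return(numeric(n))
      d_feat <- abs(X[idx[use], , drop = FALSE] -
                    matrix(X[i, ], nrow = sum(use), ncol = n, byrow = TRUE))
      d_feat <- sweep(d_feat, 2L, ifelse(ok, rng, Inf), "/")
      as.numeric(crossprod(d_feat, take[use]))
    }
    hit_term  <- if (h$k_eff > 0) diffs_for(hit_idx, h$take) / h$k_eff else numeric(n)
    miss_term <- if (m$k_eff > 0) diffs_for(miss_idx, m$take) / m$k_eff else numeric(n)
    score <- score + wv[i] * (miss_term - hit_term)
  }
  ranked_list(score / total_w, "relieff", colnames(data$features))
}

#' Rank features by linear-SVM attribute weights (SVM-AW)
#'
#' Fits a weighted linear maximum-margin classifier (L2-regularized squared
#' hinge, solved in the span of the training rows) on internally
#' standardized features and scores each feature by |w_j|, the absolute
#' component of the separating hyperplane's weight vector. Instance weights
#' are normalized to mean 1, so jointly rescaling all weights leaves the
#' ranking unchanged.
#'
#' @inheritParams rank_correlation
#' @param reg Regularization strength C of the misclassification penalty
#'   (default 1).
#' @return A \code{costlearn_ranking}.
#' @export
rank_svm_aw <- function(data, weights = NULL, reg = 1) {
  w <- rank_preamble(data, weights)
  fit <- fit_linear_svm(data$features, class_indicator(data), w, reg)
  ranked_list(abs(fit$w), "svm_aw", colnames(data$features))
}

#' Rank features by SVM recursive feature elimination (SVM-RFE)
#'
#' Repeatedly fits the linear SVM of [rank_svm_aw()] and removes the
#' \code{ceiling(p_eliminate/100 * remaining)} features (at least one) with
#' the smallest |w|, placing them at the tail of the ranking; features
#' removed in the same round are ordered by the |w| of that round. With
#' \code{p_eliminate = 100} the whole ranking is produced by a single fit
#' and coincides with the SVM-AW ranking.
#'
#' Because weights from different rounds are not on a common scale, the
#' reported score of a feature eliminated in round r (counting from the
#' first fit) is \code{(rounds survived) + |w|/(1 + max |w| of its round)}:
#' a monotone encoding of the elimination order that keeps the ranked scores
#' non-increasing.
#'
#' @inheritParams rank_svm_aw
#' @param p_eliminate Percentage of the remaining features eliminated per
#'   round, in (0, 100].
#' @return A \code{costlearn_ranking}.
#' @export
rank_svm_rfe <- function(data, weights = NULL, reg = 1, p_eliminate = 50) {
  w <- rank_preamble(data, weights)
  stopifnot(p_eliminate > 0, p_eliminate <= 100)
  y <- class_indicator(data)
  active <- seq_len(n_features(data))
  order_out <- integer(0)
  score_out <- numeric(0)
  round_idx <- 0L
  blocks <- list()
  while (length(active) > 0L) {
    round_idx <- round_idx + 1L
    fit <- fit_linear_svm(data$features[, active, drop = FALSE], y, w, reg)
    aw <- abs(fit$w)
    desc <- order(-aw, active, method = "radix")   # stable: lower index wins ties
    n_rem <- length(active)
    batch <- max(1L, ceiling(p_eliminate / 100 * n_rem))
    batch <- min(batch, n_rem)
    drop_pos <- desc[(n_rem - batch + 1L):n_rem]   # worst `batch`, best-first
    frac <- aw[drop_pos] / (1 + max(aw))
    blocks[[round_idx]] <- list(idx = active[drop_pos],
                                score = (round_idx - 1L) + frac)
    active <- active[-drop_pos]
  }
  # later rounds eliminated better features -> they rank earlier; but the
  # survived-rounds count grows with round index, so reverse the blocks
  for (b in rev(seq_along(blocks))) {
    order_out <- c(order_out, blocks[[b]]$idx)
    score_out <- c(score_out, blocks[[b]]$score)
  }
  structure(
    list(order = order_out, scores = score_out, method = "svm_rfe",
         feature_names = colnames(data$features)),
    class = "costlearn_ranking"
  )
}

#' Cut a ranked list to a feature subset
#'
#' @param ranked A \code{costlearn_ranking}.
#' @param retain Either a fraction in (0, 1] (the first
#'   \code{ceiling(retain * n)} features are kept) or a whole number of
#'   features in [1, n]. \code{retain = 1} is read as the fraction 1 (all
#'   features).
#' @return Integer vector of selected feature indices, in ranking order.
#' @examples
#' r <- ranked_list(c(0.2, 0.9, 0.5), "corr")
#' cut_ranking(r, 2)      # top-2: features 2 and 3
#' cut_ranking(r, 2 / 3)  # same via a fraction
#' @export
cut_ranking <- function(ranked, retain) {
  stopifnot(inherits(ranked, "costlearn_ranking"), is.numeric(retain),
            length(retain) == 1L)
  n <- length(ranked$order)
  if (retain <= 0 || retain > n)
    stop("retain must be a fraction in (0,1] or a count in [1, ", n, "]")
  k <- if (retain <= 1) ceiling(retain * n) else {
    if (retain != round(retain)) stop("a retain count must be a whole number")
    as.integer(retain)
  }
  ranked$order[seq_len(k)]
}
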