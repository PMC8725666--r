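#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired comparison used to contrast learning strategies across
#' the cross-validation partitions. Zero differences are discarded (with the
#' effective n reduced, the classic treatment) and tied absolute differences
#' receive mid-ranks. For up to 25 informative pairs the p-value is exact,
#' computed from the tie-aware null distribution of the positive-rank sum by
#' enumerating all sign assignments through a generating-function
#' convolution; beyond that, the normal approximation with continuity and
#' tie correction is used. If every difference is zero the test is
#' degenerate and p = 1 is returned with a warning.
#'
#' @param paired_a,paired_b Equal-length numeric vectors of paired
#'   observations (e.g. per-partition G-mean of two strategies).
#' @return A list with \code{p_value}, \code{statistic} (positive-rank sum
#'   W), \code{n_effective} (informative pairs) and \code{method}.
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))$p_value  # 0.03125
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b))
    stop("paired samples must have equal length")
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; returning p = 1")
    return(list(p_value = 1, statistic = 0, n_effective = 0L,
                method = "degenerate (all differences zero)"))
  }
  if (n < 5L)
    warning("fewer than 5 informative pairs (n = ", n,
            "); the test has very little power")
  r <- rank(abs(d))                       # mid-ranks for ties
  W <- sum(r[d > 0])
  if (n <= 25L) {
    # exact null: each |difference| keeps its rank and gets a random sign
    r2 <- as.integer(round(2 * r))        # doubled ranks are integers
    probs <- 1
    offset <- 0L                          # probs[i+1] = P(2W = i)
    for (rr in r2) {
      padded <- c(probs, rep(0, rr)) / 2
      padded[(rr + 1L):(rr + length(probs))] <-
        padded[(rr + 1L):(rr + length(probs))] + probs / 2
      probs <- padded
    }
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with continuity correction"
  }
  list(p_value = p, statistic = W, n_effective = n, method = method)
}

#' Holm-Bonferroni step-down multiple-testing correction
#'
#' Orders the raw p-values from most to least significant and compares them
#' to alpha/k, alpha/(k-1), ...: each hypothesis is rejected while its
#' sorted p-value is at most its threshold, and the procedure stops at the
#' first failure, so the rejections always form a prefix of the
#' significance-ordered list. Holm rejections are a subset of the
#' uncorrected (p < alpha) rejections and a superset of the plain
#' Bonferroni (p < alpha/k) ones.
#'
#' @param p_values Raw p-values in [0, 1].
#' @param alpha Family-wise error rate (default 0.05).
#' @return A \code{costlearn_holm} report: \code{p_values} (as given),
#'   \code{order} (indices sorted by significance), \code{sorted_p},
#'   \code{thresholds} (alpha/k, alpha/(k-1), ...), \code{rejected}
#'   (logical, in the original order), \code{n_rejected}, \code{alpha},
#'   \code{k}.
#' @examples
#' holm_bonferroni(c(0.0006, 0.0024, 0.0085, 0.0131, 0.0267, 0.30))$n_rejected  # 4
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  stopifnot(length(p_values) >= 1L, all(p_values >= 0), all(p_values <= 1),
            alpha > 0, alpha < 1)
  k <- length(p_values)
  ord <- order(p_values, seq_len(k), method = "radix")
  sp <- p_values[ord]
  thresholds <- alpha / (k - seq_len(k) + 1)
  ok <- sp <= thresholds
  n_rej <- if (all(ok)) k else which(!ok)[1L] - 1L
  rejected <- logical(k)
  if (n_rej > 0) rejected[ord[seq_len(n_rej)]] <- TRUE
  structure(list(p_values = p_values, order = ord, sorted_p = sp,
                 thresholds = thresholds, rejected = rejected,
                 n_rejected = n_rej, alpha = alpha, k = k),
            class = "costlearn_holm")
}

#' @export
print.costlearn_holm <- function(x, ...) {
  cat(sprintf("<costlearn_holm> k = %d hypotheses at alpha = %g: %d rejected\n",
              x$k, x$alpha, x$n_rejected))
  print(data.frame(hypothesis = x$order, p = x$sorted_p,
                   threshold = x$thresholds,
                   rejected = x$rejected[x$order]))
  invisible(x)
}
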