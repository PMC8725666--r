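#' Configuration for the synthetic imbalanced benchmark generator
#'
#' Describes a two-class Gaussian dataset shaped like the gene-expression
#' benchmarks targeted by the package: tens-to-hundreds of instances,
#' thousands of continuous features, a small minority (positive) class, and
#' a small subset of truly informative features whose class-conditional means
#' differ.
#'
#' @param n_pos Number of positive (minority) instances.
#' @param n_neg Number of negative (majority) instances; must be >=
#'   \code{n_pos}.
#' @param n_features Total number of features D.
#' @param n_informative Number of informative features d (<= D).
#' @param effect_size Mean shift delta applied to the informative features of
#'   positive instances, in units of the within-class standard deviation.
#' @param noise_sd Within-class standard deviation sigma (default 1).
#' @param block_rho Equicorrelation rho in [0, 1) among the informative
#'   features (0 = independent).
#' @param seed Integer seed; identical configurations generate identical
#'   datasets.
#' @return A \code{synth_config} list.
#' @seealso [generate_dataset()]
#' @export
synth_config <- function(n_pos, n_neg, n_features, n_informative,
                         effect_size = 1, noise_sd = 1, block_rho = 0,
                         seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1, n_features >= 1,
            n_informative >= 0, n_informative <= n_features,
            effect_size >= 0, noise_sd > 0,
            block_rho >= 0, block_rho < 1)
  if (n_pos > n_neg)
    stop("n_pos must not exceed n_neg (positive class is the minority)")
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         n_features = as.integer(n_features),
         n_informative = as.integer(n_informative),
         effect_size = effect_size, noise_sd = noise_sd,
         block_rho = block_rho, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic high-dimensional imbalanced dataset
#'
#' Class-conditional Gaussian model: the d informative features have mean
#' \code{effect_size * noise_sd} for positives and 0 for negatives, with an
#' optional equicorrelation structure \code{block_rho} inside the informative
#' block; the remaining D - d features are class-independent N(0, sigma^2)
#' noise. The positive class is placed in the first \code{n_pos} rows and
#' the informative features in the first \code{n_informative} columns, and
#' the ground truth is returned explicitly so selection methods can be scored
#' against it.
#'
#' One RNG stream is consumed per call, in a fixed documented order
#' (informative block first, then the noise block), so the noise draw for a
#' given seed does not depend on, e.g., \code{effect_size}.
#'
#' @param config A [synth_config()].
#' @return A [dataset()] with extra fields \code{informative} (integer
#'   indices of the truly informative features) and \code{config}.
#' @examples
#' d <- generate_dataset(synth_config(8, 92, 1000, 20, effect_size = 1.5, seed = 7))
#' d$informative
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  I <- config$n_pos + config$n_neg
  D <- config$n_features
  d <- config$n_informative
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(config$seed)

  feat <- matrix(0, nrow = I, ncol = D)
  if (d > 0) {
    z <- matrix(stats::rnorm(I * d), nrow = I, ncol = d)
    if (config$block_rho > 0) {
      # equicorrelated Gaussian via a shared factor per instance
      shared <- stats::rnorm(I)
      z <- sqrt(config$block_rho) * shared + sqrt(1 - config$block_rho) * z
    }
    block <- z * config$noise_sd
    block[seq_len(config$n_pos), ] <-
      block[seq_len(config$n_pos), , drop = FALSE] +
      config$effect_size * config$noise_sd
    feat[, seq_len(d)] <- block
  }
  if (D > d)
    feat[, (d + 1L):D] <- matrix(stats::rnorm(I * (D - d), sd = config$noise_sd),
                                 nrow = I)
  colnames(feat) <- c(sprintf("inf%03d", seq_len(d)),
                      sprintf("noise%05d", seq_len(D - d)))[seq_len(D)]
  labels <- c(rep("pos", config$n_pos), rep("neg", config$n_neg))
  out <- dataset(feat, labels, positive_label = "pos")
  out$informative <- seq_len(d)
  out$config <- config
  out
}
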