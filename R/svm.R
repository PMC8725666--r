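# Weighted linear SVM used by the embedded rankers.
#
# Solves the L2-regularized squared-hinge primal
#   min_{w,b} 0.5 ||w||^2 + C * sum_i v_i * max(0, 1 - y_i (w.x_i + b))^2
# with per-instance weights v_i (normalized to mean 1 so that jointly
# rescaling all weights leaves the solution unchanged). Since the optimal w
# lies in the span of the training rows, the problem is solved over the
# coefficients alpha of w = X' alpha, which costs O(I^2) per gradient
# instead of O(n) -- decisive when features vastly outnumber instances, as
# in expression data. The smooth squared hinge makes the objective
# differentiable, so a quasi-Newton solve is exact and deterministic.
#
# Features are standardized internally to zero weighted mean and unit
# weighted variance (|w_j| is scale-sensitive); constant features are left
# at zero and receive weight 0.

fit_linear_svm <- function(X, y01, weights, reg = 1, maxit = 1000L) {
  stopifnot(reg > 0)
  v <- weights / mean(weights)
  keep <- v > 0
  Xk <- X[keep, , drop = FALSE]
  vk <- v[keep]
  y <- ifelse(y01[keep] > 0, 1, -1)
  I <- nrow(Xk)

  wn <- vk / sum(vk)
  mu <- as.numeric(crossprod(Xk, wn))
  Xc <- sweep(Xk, 2L, mu)
  sdv <- sqrt(as.numeric(crossprod(Xc^2, wn)))
  ok <- sdv > 0
  Xs <- Xc
  Xs[, ok] <- sweep(Xc[, ok, drop = FALSE], 2L, sdv[ok], "/")
  Xs[, !ok] <- 0

  K <- tcrossprod(Xs)
  obj <- function(par) {
    a <- par[seq_len(I)]; b <- par[I + 1L]
    u <- as.numeric(K %*% a) + b
    xi <- pmax(0, 1 - y * u)
    0.5 * sum(a * (K %*% a)) + reg * sum(vk * xi^2)
  }
  grad <- function(par) {
    a <- par[seq_len(I)]; b <- par[I + 1L]
    u <- as.numeric(K %*% a) + b
    xi <- pmax(0, 1 - y * u)
    g_u <- -2 * reg * vk * y * xi
    c(as.numeric(K %*% (a + g_u)), sum(g_u))
  }
  fit <- stats::optim(rep(0, I + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  if (fit$convergence != 0)
    stop("linear SVM solver failed to converge (code ", fit$convergence,
         "): ", if (is.null(fit$message)) "no message" else fit$message)
  alpha <- fit$par[seq_len(I)]
  w <- as.numeric(crossprod(Xs, alpha))
  list(w = w, b = fit$par[I + 1L], reg = reg, value = fit$value)
}
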