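# Supervised discretization of a continuous feature by recursive binary
# splitting with the MDL (minimum description length) acceptance rule of
# Fayyad & Irani, generalized to weighted instances: every count is a sum of
# instance weights, so integer weights behave exactly like replicated
# instances. Candidate cut points are the midpoints between consecutive
# distinct sorted values; the split maximizing weighted information gain is
# accepted iff
#   gain > log2(N - 1)/N + [log2(3^k - 2) - (k*H(S) - k1*H(S1) - k2*H(S2))]/N
# with N the total weight in the segment and k the number of classes present.
# Ties on gain are broken toward the lowest cut value. A feature with no
# accepted cut collapses to a single bin (and scores 0 for IG/GR).

# Weighted binary entropy (bits) from the two class masses; 0*log0 = 0.
entropy2 <- function(a, b) {
  tot <- a + b
  out <- numeric(length(tot))
  ok <- tot > 0
  pa <- ifelse(ok, a / pmax(tot, .Machine$double.eps), 0)
  pb <- ifelse(ok, b / pmax(tot, .Machine$double.eps), 0)
  term <- function(p) ifelse(p > 0, -p * log2(p), 0)
  out[ok] <- (term(pa) + term(pb))[ok]
  out
}

#' MDL cut points for a continuous feature
#'
#' @param x Numeric feature values.
#' @param y Class indicator (0/1 or logical).
#' @param w Non-negative instance weights (default uniform). Zero-weight
#'   instances are ignored.
#' @return Sorted numeric vector of accepted cut points (possibly empty).
#' @keywords internal
#' @export
mdl_cut_points <- function(x, y, w = NULL) {
  w <- check_weights(w, length(x))
  keep <- w > 0
  x <- x[keep]; y <- as.integer(as.logical(y))[keep]; w <- w[keep]
  o <- order(x)
  sort(mdl_segment(x[o], y[o], w[o]))
}

mdl_segment <- function(xs, ys, ws) {
  n <- length(xs)
  if (n < 2L) return(numeric(0))
  W <- sum(ws)
  cw1 <- cumsum(ws * (ys == 1L))
  cw0 <- cumsum(ws * (ys == 0L))
  tot1 <- cw1[n]; tot0 <- cw0[n]
  cand <- which(xs[-n] < xs[-1L])
  if (!length(cand)) return(numeric(0))

  l1 <- cw1[cand]; l0 <- cw0[cand]
  r1 <- tot1 - l1; r0 <- tot0 - l0
  ent_s <- entropy2(tot1, tot0)
  ent_l <- entropy2(l1, l0)
  ent_r <- entropy2(r1, r0)
  gain <- ent_s - ((l1 + l0) * ent_l + (r1 + r0) * ent_r) / W

  best <- which.max(gain)  # first maximum -> lowest cut value
  if (W <= 1) return(numeric(0))
  k  <- (tot1 > 0) + (tot0 > 0)
  k1 <- (l1[best] > 0) + (l0[best] > 0)
  k2 <- (r1[best] > 0) + (r0[best] > 0)
  delta <- log2(3^k - 2) - (k * ent_s - k1 * ent_l[best] - k2 * ent_r[best])
  if (gain[best] <= (log2(W - 1) + delta) / W) return(numeric(0))

  i <- cand[best]
  cut <- (xs[i] + xs[i + 1L]) / 2
  c(mdl_segment(xs[seq_len(i)], ys[seq_len(i)], ws[seq_len(i)]),
    cut,
    mdl_segment(xs[(i + 1L):n], ys[(i + 1L):n], ws[(i + 1L):n]))
}

# Assign bin ids (1-based) given sorted cut points; no cuts -> single bin.
assign_bins <- function(x, cuts) {
  if (!length(cuts)) return(rep(1L, length(x)))
  findInterval(x, cuts) + 1L
}

# Weighted information gain and split information (bits) of a binned feature
# against a binary class. Returns c(ig, split_info).
binned_ig_split <- function(bins, y, w) {
  y <- as.integer(as.logical(y))
  tot1 <- sum(w * (y == 1L)); tot0 <- sum(w * (y == 0L))
  W <- tot1 + tot0
  h_y <- entropy2(tot1, tot0)
  ub <- sort(unique(bins))
  wb1 <- vapply(ub, function(b) sum(w[bins == b & y == 1L]), numeric(1))
  wb0 <- vapply(ub, function(b) sum(w[bins == b & y == 0L]), numeric(1))
  wb <- wb1 + wb0
  h_cond <- sum(wb / W * entropy2(wb1, wb0))
  p <- wb[wb > 0] / W
  split_info <- -sum(p * log2(p))
  c(ig = h_y - h_cond, split_info = split_info)
}
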