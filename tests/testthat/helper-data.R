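# Shared fixture builders: everything is generated in code at test time.

# Tiny fixed dataset: 6 instances, 5 features, 2 positives.
toy6 <- function(seed = 7) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  X <- matrix(rnorm(6 * 5), 6, 5,
              dimnames = list(NULL, paste0("g", 1:5)))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  dataset(X, c("p", "p", "n", "n", "n", "n"))
}

# Instance-replicated copy of a dataset under integer weights.
replicate_dataset <- function(data, w) {
  stopifnot(all(w == round(w)), all(w >= 0))
  idx <- rep(seq_len(n_instances(data)), times = w)
  dataset(data$features[idx, , drop = FALSE], data$labels[idx],
          positive_label = data$positive_label)
}

# Write a small ARFF text file and return its path.
write_arff_text <- function(lines) {
  path <- tempfile(fileext = ".arff")
  writeLines(lines, path)
  path
}

toy_arff_lines <- c(
  "@relation toy",
  "@attribute f1 numeric",
  "@attribute f2 numeric",
  "@attribute class {pos,neg}",
  "@data",
  "1.5,2.0,pos",
  "1.2,1.8,pos",
  "0.1,0.2,neg",
  "0.0,0.3,neg",
  "0.2,0.1,neg"
)

# Independent single-pass recursive MDL discretizer used as oracle: plain
# loops, entropies computed from scratch, no shared code with the package.
oracle_mdl_cuts <- function(x, y, w = rep(1, length(x))) {
  ent <- function(cw) {
    p <- cw[cw > 0] / sum(cw)
    -sum(p * log2(p))
  }
  rec <- function(xs, ys, ws) {
    o <- order(xs); xs <- xs[o]; ys <- ys[o]; ws <- ws[o]
    n <- length(xs)
    vals <- unique(xs)
    if (length(vals) < 2) return(numeric(0))
    cands <- (vals[-length(vals)] + vals[-1]) / 2
    W <- sum(ws)
    cls <- sort(unique(ys))
    mass <- function(sel) vapply(cls, function(cl) sum(ws[sel & ys == cl]), numeric(1))
    hS <- ent(mass(rep(TRUE, n)))
    best_gain <- -Inf; best_cut <- NA; bl <- NULL; br <- NULL
    for (cut in cands) {
      left <- xs < cut
      mL <- mass(left); mR <- mass(!left)
      g <- hS - (sum(mL) * ent(mL) + sum(mR) * ent(mR)) / W
      if (g > best_gain + 1e-12) {
        best_gain <- g; best_cut <- cut; bl <- mL; br <- mR
      }
    }
    k <- sum(mass(rep(TRUE, n)) > 0)
    k1 <- sum(bl > 0); k2 <- sum(br > 0)
    delta <- log2(3^k - 2) - (k * hS - k1 * ent(bl) - k2 * ent(br))
    if (W <= 1 || best_gain <= (log2(W - 1) + delta) / W) return(numeric(0))
    left <- xs < best_cut
    c(rec(xs[left], ys[left], ws[left]), best_cut,
      rec(xs[!left], ys[!left], ws[!left]))
  }
  sort(rec(x, y, w))
}

# Exhaustive-enumeration Wilcoxon signed-rank oracle (two-sided), for small n.
oracle_wilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  Ws <- apply(expand.grid(rep(list(c(FALSE, TRUE)), n)), 1,
              function(s) sum(r[as.logical(s)]))
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# 0/1 positive-class indicator (exported-surface-only helper).
class_indicator_test <- function(d) as.numeric(is_positive(d))
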