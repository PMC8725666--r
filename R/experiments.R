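#' Learning-strategy specification
#'
#' The six strategies compared by the package, combining feature selection
#' (FS), model induction (MI) and the two cost-sensitivity mechanisms:
#' \describe{
#'   \item{BASELINE}{all features, cost-blind forest.}
#'   \item{FS_MI}{rank (uniform weights) on the training split, cut, train,
#'     predict with the default 0.5 threshold.}
#'   \item{WFS_MI}{cost-sensitive selection: rank with cost-proportional
#'     instance weights, then train and predict cost-blind.}
#'   \item{FS_WMI}{cost-sensitive induction by reweighting: rank uniform,
#'     train the forest with cost-proportional weights, default threshold.}
#'   \item{FS_MCMI}{cost-sensitive induction by threshold moving: rank
#'     uniform, train uniform, predict at the minimum-expected-cost
#'     threshold.}
#'   \item{ALLFEAT_MCMI}{no selection, minimum-expected-cost prediction.}
#' }
#'
#' @param strategy One of \code{"BASELINE"}, \code{"FS_MI"}, \code{"WFS_MI"},
#'   \code{"FS_WMI"}, \code{"FS_MCMI"}, \code{"ALLFEAT_MCMI"}.
#' @param selector Ranking heuristic, one of \code{"corr"}, \code{"ig"},
#'   \code{"gr"}, \code{"relieff"}, \code{"svm_aw"}, \code{"svm_rfe"}
#'   (unused, and must be omitted, for BASELINE / ALLFEAT_MCMI).
#' @param retain Retained fraction of features in (0, 1] (or a count),
#'   passed to [cut_ranking()]; unused for BASELINE / ALLFEAT_MCMI.
#' @param fn_cost False-negative cost c (unit false-positive cost); unused
#'   for BASELINE and FS_MI, where it must stay at its default 1.
#' @return A \code{costlearn_strategy} list.
#' @export
strategy_spec <- function(strategy, selector = NULL, retain = NULL,
                          fn_cost = 1) {
  strategy <- match.arg(strategy, c("BASELINE", "FS_MI", "WFS_MI", "FS_WMI",
                                    "FS_MCMI", "ALLFEAT_MCMI"))
  uses_fs <- !strategy %in% c("BASELINE", "ALLFEAT_MCMI")
  uses_cost <- !strategy %in% c("BASELINE", "FS_MI")
  if (uses_fs) {
    if (is.null(selector) || is.null(retain))
      stop(strategy, " requires `selector` and `retain`")
    selector <- match.arg(selector, c("corr", "ig", "gr", "relieff",
                                      "svm_aw", "svm_rfe"))
    if (is.numeric(retain) && retain <= 1 && retain <= 0)
      stop("retain must be positive")
  } else if (!is.null(selector) || !is.null(retain)) {
    stop(strategy, " does not use a selector or retained fraction")
  }
  if (!uses_cost && fn_cost != 1)
    stop(strategy, " is cost-blind; fn_cost must stay 1")
  stopifnot(fn_cost > 0)
  structure(list(strategy = strategy, selector = selector, retain = retain,
                 fn_cost = fn_cost),
            class = "costlearn_strategy")
}

#' @export
print.costlearn_strategy <- function(x, ...) {
  cat(sprintf("<costlearn_strategy> %s%s%s\n", x$strategy,
              if (!is.null(x$selector))
                sprintf(" | %s, retain %g", x$selector, x$retain) else "",
              if (x$fn_cost != 1) sprintf(" | c = %g", x$fn_cost) else ""))
  invisible(x)
}

#' Apply one ranking heuristic by name
#'
#' Thin dispatcher over the six rankers, used by [run_strategy()] and the
#' command-line interface.
#'
#' @inheritParams rank_correlation
#' @param method One of \code{"corr"}, \code{"ig"}, \code{"gr"},
#'   \code{"relieff"}, \code{"svm_aw"}, \code{"svm_rfe"}.
#' @param ... Passed to the underlying ranker (e.g. \code{k_neighbors},
#'   \code{reg}, \code{p_eliminate}).
#' @return A \code{costlearn_ranking}.
#' @export
rank_features <- function(data, method, weights = NULL, ...) {
  method <- match.arg(method, c("corr", "ig", "gr", "relieff",
                                "svm_aw", "svm_rfe"))
  switch(method,
         corr = rank_correlation(data, weights),
         ig = rank_info_gain(data, weights),
         gr = rank_gain_ratio(data, weights),
         relieff = rank_relieff(data, weights, ...),
         svm_aw = rank_svm_aw(data, weights, ...),
         svm_rfe = rank_svm_rfe(data, weights, ...))
}

#' Run one learning strategy over a cross-validation plan
#'
#' For every train/test partition of the plan, feature ranking (when the
#' strategy selects features) is computed on the training split only -- the
#' test instances are never inspected before prediction -- then the forest
#' is induced and the test split scored with all six metrics. The forest
#' seed of partition t is derived from the plan seed as
#' \code{plan_seed + 7919 * t}, so the whole run is reproducible from the
#' plan alone and paired strategies share partitioning but use independent
#' forest randomness per partition.
#'
#' @param data A [dataset()].
#' @param spec A [strategy_spec()].
#' @param plan A [make_cv_plan()] built on the same dataset.
#' @param n_trees Trees per forest (default 100).
#' @param ... Extra arguments for the ranker (via [rank_features()]).
#' @return A \code{costlearn_run}: \code{per_partition} (data.frame, one row
#'   of metrics per partition), \code{means} (named vector),
#'   \code{selections} (per-partition selected feature indices, \code{NULL}
#'   entries for strategies without selection), \code{spec}, and plan
#'   provenance.
#' @export
run_strategy <- function(data, spec, plan, n_trees = 100L, ...) {
  stopifnot(inherits(data, "costlearn_dataset"),
            inherits(spec, "costlearn_strategy"),
            inherits(plan, "costlearn_cv_plan"))
  if (plan$n != n_instances(data))
    stop("plan was built for ", plan$n, " instances; data has ",
         n_instances(data))
  costs <- cost_matrix(fn_cost = spec$fn_cost)
  uses_fs <- !spec$strategy %in% c("BASELINE", "ALLFEAT_MCMI")

  rows <- vector("list", length(plan$partitions))
  selections <- vector("list", length(plan$partitions))
  for (t in seq_along(plan$partitions)) {
    part <- plan$partitions[[t]]
    train <- subset_dataset(data, instances = part$train)

    selected <- if (uses_fs) {
      fs_weights <- if (spec$strategy == "WFS_MI")
        weights_from_costs(train, costs) else NULL
      cut_ranking(rank_features(train, spec$selector, fs_weights, ...),
                  spec$retain)
    } else NULL
    selections[[t]] <- selected

    mi_weights <- if (spec$strategy == "FS_WMI")
      weights_from_costs(train, costs) else NULL
    model <- train_forest(train, selected = selected, weights = mi_weights,
                          config = forest_config(
                            n_trees = n_trees,
                            seed = plan$seed + 7919L * t))

    test <- subset_dataset(data, instances = part$test)
    pred <- if (spec$strategy %in% c("FS_MCMI", "ALLFEAT_MCMI"))
      predict_min_cost(model, test, costs)
    else
      predict_default(model, test)

    cc <- confusion_counts(test$labels, pred, data$positive_label)
    rows[[t]] <- c(repeat_id = part$repeat_id, fold = part$fold,
                   compute_metrics(cc))
  }
  per_partition <- as.data.frame(do.call(rbind, rows))
  metric_cols <- c("mcc", "g_mean", "f_measure", "sensitivity",
                   "specificity", "precision")
  structure(
    list(per_partition = per_partition,
         means = colMeans(per_partition[, metric_cols]),
         selections = selections,
         spec = spec,
         plan_seed = plan$seed, folds = plan$folds, repeats = plan$repeats,
         n = plan$n),
    class = "costlearn_run"
  )
}

#' @export
print.costlearn_run <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %d partitions (%d-fold x %d repeats), mean metrics:\n",
              nrow(x$per_partition), x$folds, x$repeats))
  print(round(x$means, 3))
  invisible(x)
}

#' Paired statistical comparison of strategies against a reference
#'
#' For each requested metric, every candidate run is compared to the
#' reference run with the Wilcoxon signed-rank test paired across the
#' cross-validation partitions, and the resulting p-values are
#' Holm-Bonferroni corrected with k = number of candidates (the protocol of
#' the package's benchmark analyses: k = 6 when the six selectors are
#' compared to the no-selection baseline, k = 3 when three cost settings
#' are compared to selection alone).
#'
#' @param results List of \code{costlearn_run} candidates.
#' @param baseline The reference \code{costlearn_run}.
#' @param metrics Metric names to compare (default MCC, G-mean, F-measure).
#' @param alpha Family-wise error rate (default 0.05).
#' @return A \code{costlearn_comparison}: per metric, a data.frame with the
#'   candidate and reference means, raw p-values, Holm thresholds and
#'   rejection decisions, plus the underlying \code{costlearn_holm} report.
#' @export
compare_strategies <- function(results, baseline,
                               metrics = c("mcc", "g_mean", "f_measure"),
                               alpha = 0.05) {
  stopifnot(inherits(baseline, "costlearn_run"), length(results) >= 1L)
  for (r in results) {
    stopifnot(inherits(r, "costlearn_run"))
    if (r$plan_seed != baseline$plan_seed || r$folds != baseline$folds ||
        r$repeats != baseline$repeats || r$n != baseline$n)
      stop("all runs must share the same cross-validation plan (paired design)")
  }
  labels <- vapply(results, function(r) {
    s <- r$spec
    paste0(s$strategy,
           if (!is.null(s$selector)) paste0("/", s$selector, "@", s$retain) else "",
           if (s$fn_cost != 1) paste0("/c=", s$fn_cost) else "")
  }, character(1))
  out <- lapply(metrics, function(m) {
    p <- vapply(results, function(r)
      wilcoxon_signed_rank(r$per_partition[[m]],
                           baseline$per_partition[[m]])$p_value,
      numeric(1))
    holm <- holm_bonferroni(p, alpha)
    tab <- data.frame(
      strategy = labels,
      mean = vapply(results, function(r) unname(r$means[m]), numeric(1)),
      baseline_mean = unname(baseline$means[m]),
      p_value = p,
      rejected = holm$rejected,
      stringsAsFactors = FALSE
    )
    list(table = tab, holm = holm)
  })
  names(out) <- metrics
  structure(list(metrics = out, alpha = alpha, k = length(results)),
            class = "costlearn_comparison")
}

#' @export
print.costlearn_comparison <- function(x, ...) {
  cat(sprintf("<costlearn_comparison> k = %d candidates, alpha = %g\n",
              x$k, x$alpha))
  for (m in names(x$metrics)) {
    cat("--", m, "--\n")
    tab <- x$metrics[[m]]$table
    tab$mean <- round(tab$mean, 3)
    tab$baseline_mean <- round(tab$baseline_mean, 3)
    tab$p_value <- signif(tab$p_value, 3)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}
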