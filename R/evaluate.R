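# Panel evaluation: leave-one-out cross-validated classification metrics,
# the accuracy-versus-panel-size curve over the ranked gene list, and the
# random-gene-panel benchmark.

# Leave-one-out kNN class predictions for a fixed panel, written in plain R
# (a deliberately independent route from the compiled search kernel; the
# two are cross-checked in the test suite). Ties at the k-th neighbour are
# broken by stable (distance, sample index) order, as in the kernel.
loo_knn_labels <- function(expr, labels, panel, k = 5L) {
  panel <- resolve_genes(expr, panel)
  n <- ncol(expr)
  if (n < k + 1L) stop("need at least k + 1 samples")
  x <- expr[panel, , drop = FALSE]
  d2 <- as.matrix(stats::dist(t(x)))^2
  labels <- as.character(labels)
  vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    nn <- others[order(d2[i, others], others)][seq_len(k)]
    votes <- table(labels[nn])
    names(votes)[which.max(votes)]
  }, character(1L))
}

#' Leave-one-out cross-validated panel metrics
#'
#' Classifies every sample from the remaining samples by kNN restricted to
#' the panel's genes, and summarises the confusion counts with AIS as the
#' positive class: accuracy = correct/total, sensitivity = TP/(TP+FN)
#' (fraction of AIS called AIS), specificity = TN/(TN+FP).
#'
#' @param expr Z-scored genes x samples matrix.
#' @param labels Two-class label vector.
#' @param panel Gene ids (matching rownames) or integer indices; must be
#'   non-empty.
#' @param k Number of neighbours (odd).
#' @param positive Positive class (default `"AIS"` when present).
#' @return A list of class `"panel_metrics"`: `accuracy`, `sensitivity`,
#'   `specificity`, `n_correct`, `n_total`, `tp`, `fp`, `tn`, `fn`,
#'   `predicted`.
#' @export
loocv_metrics <- function(expr, labels, panel, k = 5L, positive = NULL) {
  if (!length(panel)) stop("empty panel")
  y <- binary_labels(labels, positive = positive)
  positive <- attr(y, "positive")
  pred <- loo_knn_labels(expr, labels, panel, k)
  truth <- as.character(labels)
  tp <- sum(pred == positive & truth == positive)
  fn <- sum(pred != positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  fp <- sum(pred == positive & truth != positive)
  structure(list(accuracy = (tp + tn) / length(truth),
                 sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
                 n_correct = tp + tn, n_total = length(truth),
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 positive = positive, predicted = pred),
            class = "panel_metrics")
}

#' @export
print.panel_metrics <- function(x, ...) {
  cat(sprintf("LOOCV kNN: %d/%d correct (accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%)\n",
              x$n_correct, x$n_total, 100 * x$accuracy, 100 * x$sensitivity,
              100 * x$specificity))
  invisible(x)
}

#' Accuracy as a function of panel size
#'
#' Computes [loocv_metrics()] for the top-m ranked genes, for every
#' m = 1..`max_m`. Accuracy is not assumed monotone in m.
#'
#' @param expr Z-scored genes x samples matrix.
#' @param labels Two-class label vector.
#' @param ranking A `"gene_ranking"` (or a vector of gene ids, best first).
#' @param max_m Largest panel size (default 50).
#' @param k Number of neighbours.
#' @return A data.frame with one row per panel size: `m`, `accuracy`,
#'   `sensitivity`, `specificity`, `n_correct`, `n_total`.
#' @export
accuracy_by_panel_size <- function(expr, labels, ranking, max_m = 50L, k = 5L) {
  genes <- ranking_genes(ranking)
  if (length(genes) < max_m)
    stop("ranking has fewer than max_m = ", max_m, " genes")
  rows <- lapply(seq_len(max_m), function(m) {
    met <- loocv_metrics(expr, labels, genes[seq_len(m)], k)
    data.frame(m = m, accuracy = met$accuracy, sensitivity = met$sensitivity,
               specificity = met$specificity, n_correct = met$n_correct,
               n_total = met$n_total)
  })
  do.call(rbind, rows)
}

ranking_genes <- function(ranking) {
  if (inherits(ranking, "gene_ranking")) ranking$gene_id
  else if (is.character(ranking)) ranking
  else stop("ranking must be a gene_ranking or a character vector of gene ids")
}

#' Benchmark the ranked panel against random gene panels
#'
#' Draws `n_sets` random panels of `set_size` genes from each supplied pool
#' (genes are drawn without replacement within a panel, independently
#' across panels), computes every random panel's LOOCV accuracy at each
#' panel size m, and compares the ranked panel's accuracy at m against the
#' random accuracies at m with a one-sample two-sided t-test: the ranked
#' panel's accuracy is the tested constant, the `n_sets` random accuracies
#' are the sample. If the random accuracies have zero variance the p-value
#' is reported as an exact 0 (means differ) or 1 (means equal) with
#' `degenerate = TRUE`.
#'
#' @param expr Z-scored genes x samples matrix.
#' @param labels Two-class label vector.
#' @param ranking Ranked genes (see [accuracy_by_panel_size()]).
#' @param pools Named list of gene-id character vectors to draw random
#'   panels from, e.g. `list(genome_wide = rownames(expr), fold_filtered =
#'   kept)`. Each pool must be larger than `set_size`.
#' @param n_sets Number of random panels per pool (default 50).
#' @param set_size Genes per random panel (default 50).
#' @param sizes Panel sizes m at which to compare (default `c(10, set_size)`
#'   capped at `set_size`).
#' @param k Number of neighbours.
#' @return A data.frame with one row per (pool, m): the ranked panel's
#'   accuracy, the random mean and sd, the t statistic, df, p-value and a
#'   `degenerate` flag.
#' @export
random_panel_benchmark <- function(expr, labels, ranking, pools,
                                   n_sets = 50L, set_size = 50L,
                                   sizes = unique(pmin(c(10L, set_size), set_size)),
                                   k = 5L) {
  stopifnot(is.list(pools), length(names(pools)) == length(pools))
  genes <- ranking_genes(ranking)
  stopifnot(max(sizes) <= set_size, length(genes) >= max(sizes))
  ga_acc <- vapply(sizes, function(m)
    loocv_metrics(expr, labels, genes[seq_len(m)], k)$accuracy, numeric(1L))
  y <- binary_labels(labels)
  out <- list()
  for (pn in names(pools)) {
    pool <- pools[[pn]]
    if (length(pool) <= set_size)
      stop("pool '", pn, "' must be larger than set_size")
    panels <- vapply(seq_len(n_sets), function(s)
      resolve_genes(expr, sample(pool, set_size)), integer(set_size))
    acc <- vapply(seq_along(sizes), function(j)
      .loo_fitness_batch(expr,
                         panels[seq_len(sizes[j]), , drop = FALSE],
                         as.integer(y), as.integer(k)),
      numeric(n_sets))
    acc <- matrix(acc, n_sets, length(sizes))
    for (j in seq_along(sizes)) {
      mu <- mean(acc[, j]); sdev <- sd(acc[, j])
      if (sdev == 0) {
        degenerate <- TRUE
        tstat <- if (mu == ga_acc[j]) 0 else sign(mu - ga_acc[j]) * Inf
        p <- if (mu == ga_acc[j]) 1 else 0
      } else {
        degenerate <- FALSE
        tstat <- (mu - ga_acc[j]) / (sdev / sqrt(n_sets))
        p <- 2 * pt(-abs(tstat), df = n_sets - 1L)
      }
      out[[length(out) + 1L]] <- data.frame(
        pool = pn, m = sizes[j], panel_accuracy = ga_acc[j],
        random_mean = mu, random_sd = sdev, t = tstat,
        df = n_sets - 1L, p = p, degenerate = degenerate,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
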