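# Pre-filtering and standardisation applied before the GA/kNN search:
# absolute fold differences between the two discovery classes, a strict
# >1.7-fold retention filter, and per-gene z-transformation.

#' Per-gene absolute fold differences between two classes
#'
#' For each gene, computes the case and control group means on the linear
#' intensity scale and the absolute fold difference
#' `max(m_case/m_control, m_control/m_case)`, which is `>= 1` whenever both
#' group means are positive. Genes with a non-positive group mean cannot be
#' expressed as a fold ratio; they are flagged (`fold_defined = FALSE`,
#' `abs_fold = NA`) rather than dropped.
#'
#' Mimic samples are not part of discovery filtering: `labels` must contain
#' exactly the two discovery classes (AIS and control); subset the matrix
#' first if a third group is present.
#'
#' @param expr Genes x samples numeric matrix (linear scale).
#' @param labels Per-sample class vector (character or factor) containing
#'   exactly two distinct classes; `"AIS"` is the case class if present,
#'   otherwise the second level.
#' @param case,control Optional explicit class names.
#' @return A data.frame with columns `gene_id`, `mean_case`, `mean_control`,
#'   `abs_fold`, `fold_defined`, in the input gene order.
#' @export
compute_fold_changes <- function(expr, labels, case = NULL, control = NULL) {
  stopifnot(is.matrix(expr), ncol(expr) == length(labels))
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L)
    stop("labels must contain exactly two classes, got: ",
         paste(classes, collapse = ", "))
  if (is.null(case)) case <- if ("AIS" %in% classes) "AIS" else classes[2L]
  if (is.null(control)) control <- setdiff(classes, case)
  if (!all(c(case, control) %in% classes) || case == control)
    stop("case/control must name the two classes present")
  n_case <- sum(labels == case); n_ctl <- sum(labels == control)
  if (n_case == 0L || n_ctl == 0L) stop("a class has zero samples")
  m_case <- rowMeans(expr[, labels == case, drop = FALSE])
  m_ctl <- rowMeans(expr[, labels == control, drop = FALSE])
  defined <- m_case > 0 & m_ctl > 0
  abs_fold <- ifelse(defined, pmax(m_case / m_ctl, m_ctl / m_case), NA_real_)
  data.frame(gene_id = rownames(expr) %||% as.character(seq_len(nrow(expr))),
             mean_case = m_case, mean_control = m_ctl,
             abs_fold = abs_fold, fold_defined = defined,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Retain genes above an absolute fold-difference threshold
#'
#' Strict inequality: a gene at exactly the threshold is excluded. Genes
#' with an undefined fold (non-positive group mean) are never retained.
#' Original row order is preserved.
#'
#' @param fold_table Output of [compute_fold_changes()].
#' @param threshold Fold threshold, must be > 1 (default 1.7).
#' @return Character vector of retained gene ids (possibly empty, with a
#'   warning).
#' @export
filter_by_fold_change <- function(fold_table, threshold = 1.7) {
  stopifnot(is.data.frame(fold_table), threshold > 1)
  keep <- fold_table$fold_defined & !is.na(fold_table$abs_fold) &
    fold_table$abs_fold > threshold
  out <- fold_table$gene_id[keep]
  if (!length(out))
    warning("no genes exceed the ", threshold, "-fold threshold")
  out
}

#' Z-transform each gene across samples
#'
#' Centres and scales every gene row to mean 0 and unit standard deviation
#' (sample, n-1 denominator) across all samples of the analysed cohort.
#' Constant rows carry no distance information and are dropped with a
#' warning.
#'
#' @param expr Genes x samples numeric matrix with >= 2 samples.
#' @return Matrix of the same shape minus any constant rows.
#' @export
z_transform <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2L)
  mu <- rowMeans(expr)
  s <- apply(expr, 1L, sd)
  constant <- s == 0 | !is.finite(s)
  if (all(constant)) stop("all genes are constant; nothing to z-transform")
  if (any(constant)) {
    warning(sum(constant), " constant gene(s) dropped: ",
            paste(utils::head(rownames(expr)[constant], 5L), collapse = ", "),
            if (sum(constant) > 5L) ", ..." else "")
    expr <- expr[!constant, , drop = FALSE]
    mu <- mu[!constant]; s <- s[!constant]
  }
  (expr - mu) / s
}
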