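# Composite expression score: the first principal component of a gene
# panel's standardized expression, used as a single per-sample summary of
# the panel's coordinate expression pattern.

#' Fit a composite expression score for a panel
#'
#' PC1 of the gene-gene correlation matrix of the panel (for z-scored input
#' the correlation and covariance matrices coincide; PCA is defined on the
#' correlation matrix to remove the ambiguity). Loadings are the leading
#' eigenvector (unit norm); per-sample scores are the loading-weighted sums
#' of the z-scored rows, so they have zero mean; the variance explained is
#' the leading eigenvalue over the trace.
#'
#' @param panel_matrix Z-scored panel genes x samples matrix (>= 2 genes,
#'   >= 3 samples, no constant rows).
#' @return An object of class `"composite_expression"`: `loadings` (named),
#'   `scores` (named), `var_explained`, `orientation` (`"unoriented"` until
#'   [orient_composite()] is applied).
#' @export
fit_composite <- function(panel_matrix) {
  stopifnot(is.matrix(panel_matrix), nrow(panel_matrix) >= 2L,
            ncol(panel_matrix) >= 3L)
  sds <- apply(panel_matrix, 1L, sd)
  if (any(sds == 0)) stop("panel contains constant gene(s)")
  z <- (panel_matrix - rowMeans(panel_matrix)) / sds
  cmat <- stats::cor(t(z))
  eig <- eigen(cmat, symmetric = TRUE)
  if (eig$values[1L] <= 0) stop("panel correlation matrix has no positive eigenvalue")
  loadings <- eig$vectors[, 1L]
  names(loadings) <- rownames(panel_matrix)
  scores <- drop(crossprod(z, loadings))
  names(scores) <- colnames(panel_matrix)
  structure(list(loadings = loadings, scores = scores,
                 var_explained = eig$values[1L] / sum(eig$values),
                 orientation = "unoriented"),
            class = "composite_expression")
}

#' Orient a composite score towards the positive class
#'
#' PC directions are defined only up to sign; by repository convention the
#' composite is flipped, if necessary, so that the mean score of the AIS
#' group exceeds the mean score of the reference (control) group. The
#' operation is idempotent. If the two group means are exactly equal the
#' sign is left unchanged and the orientation is flagged.
#'
#' @param ce A `"composite_expression"` from [fit_composite()].
#' @param labels Per-sample class vector aligned with `ce$scores`.
#' @param positive Class whose mean score should be higher (default
#'   `"AIS"` when present).
#' @return The composite with possibly negated loadings/scores and
#'   `orientation` set.
#' @export
orient_composite <- function(ce, labels, positive = NULL) {
  stopifnot(inherits(ce, "composite_expression"),
            length(labels) == length(ce$scores))
  y <- binary_labels(labels, positive = positive)
  positive <- attr(y, "positive")
  diff <- mean(ce$scores[y == 1L]) - mean(ce$scores[y == 0L])
  if (diff < 0) {
    ce$loadings <- -ce$loadings
    ce$scores <- -ce$scores
    ce$orientation <- paste0("flipped: higher in ", positive)
  } else if (diff > 0) {
    ce$orientation <- paste0("higher in ", positive)
  } else {
    ce$orientation <- "ambiguous: equal group means, sign unchanged"
  }
  ce
}

#' @export
print.composite_expression <- function(x, ...) {
  cat(sprintf("Composite expression score over %d genes, %d samples\n",
              length(x$loadings), length(x$scores)))
  cat(sprintf("  PC1 variance explained: %.1f%%; orientation: %s\n",
              100 * x$var_explained, x$orientation))
  invisible(x)
}

#' Correlation of each panel gene with the composite score
#'
#' Spearman's rho between every gene's expression and the per-sample
#' composite score, with two-sided p-values from the t approximation (see
#' [spearman_test()]). Constant genes have undefined rho and are reported
#' as `NA`.
#'
#' @param panel_matrix Panel genes x samples matrix.
#' @param scores Per-sample composite scores.
#' @return A data.frame with columns `gene_id`, `rho`, `p`.
#' @export
gene_component_correlations <- function(panel_matrix, scores) {
  stopifnot(is.matrix(panel_matrix), ncol(panel_matrix) == length(scores))
  rows <- lapply(seq_len(nrow(panel_matrix)), function(i) {
    g <- panel_matrix[i, ]
    if (sd(g) == 0 || sd(scores) == 0)
      return(data.frame(rho = NA_real_, p = NA_real_))
    st <- spearman_test(g, scores)
    data.frame(rho = st$statistic["rho"], p = st$p)
  })
  out <- do.call(rbind, rows)
  data.frame(gene_id = rownames(panel_matrix) %||%
               as.character(seq_len(nrow(panel_matrix))),
             rho = out$rho, p = out$p, row.names = NULL,
             stringsAsFactors = FALSE)
}
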