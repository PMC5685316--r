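# The statistical toolkit behind the confounder and cohort analyses:
# ordinary least squares with per-coefficient tests, Lindeman-Merenda-Gold
# (LMG) relative-importance decomposition, two-sample t tests (Welch by
# default, from raw data or printed summaries), Pearson chi-square for 2x2
# tables, Spearman correlation, Holm step-down adjustment, and the cohort
# characteristics table.

new_test_result <- function(statistic, df, p, method, two_sided = TRUE,
                            flags = character()) {
  structure(list(statistic = statistic, df = df, p = p, method = method,
                 two_sided = two_sided, flags = flags),
            class = "gaknn_test")
}

#' @export
print.gaknn_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, df = %s, p = %.4g%s\n", x$method,
              paste(signif(x$statistic, 4), collapse = ", "),
              paste(signif(x$df, 4), collapse = ", "), x$p,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "), "]")
              else ""))
  invisible(x)
}

#' Summary statistics for a group
#'
#' Container for a (mean, sd, n) triple, so [welch_t()] can be driven by
#' published summary statistics as well as raw data.
#'
#' @param mean,sd,n Group mean, standard deviation and size.
#' @return A list of class `"summary_stats"`.
#' @export
summary_stats <- function(mean, sd, n) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0, n >= 1)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "summary_stats")
}

as_summary <- function(x) {
  if (inherits(x, "summary_stats")) return(x)
  if (is.numeric(x) && length(x) >= 2L)
    return(summary_stats(mean(x), sd(x), length(x)))
  stop("expected a numeric sample of length >= 2 or summary_stats(mean, sd, n)")
}

#' Two-sample t test (Welch by default)
#'
#' Computes `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value; with
#' `pooled = TRUE` the classical equal-variance form is used instead.
#' Either argument may be a raw sample or a [summary_stats()] triple, so
#' statistics printed in cohort tables can be recomputed directly. When one
#' group has zero variance the Welch df reduces to `n_other - 1`. If both
#' variances are zero the statistic is 0 (equal means, flag `degenerate`)
#' or signed infinity (flag `degenerate`), with `p` 1 or 0 respectively.
#'
#' @param x,y Numeric samples or `summary_stats` objects.
#' @param pooled Use the pooled-variance Student form.
#' @return A `"gaknn_test"` with `statistic = c(t = ...)`.
#' @export
welch_t <- function(x, y, pooled = FALSE) {
  a <- as_summary(x); b <- as_summary(y)
  flags <- character()
  v1 <- a$sd^2 / a$n; v2 <- b$sd^2 / b$n
  if (a$sd == 0 && b$sd == 0) {
    flags <- "degenerate: both variances zero"
    tstat <- if (a$mean == b$mean) 0 else sign(a$mean - b$mean) * Inf
    return(new_test_result(c(t = tstat), df = NA_real_,
                           p = if (a$mean == b$mean) 1 else 0,
                           method = "two-sample t (degenerate)", flags = flags))
  }
  if (pooled) {
    if (a$n + b$n <= 2L) stop("pooled t needs n1 + n2 > 2")
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    tstat <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
    method <- "Student t (pooled)"
  } else {
    se2 <- v1 + v2
    tstat <- (a$mean - b$mean) / sqrt(se2)
    df <- se2^2 / (ifelse(a$n > 1, v1^2 / (a$n - 1), 0) +
                     ifelse(b$n > 1, v2^2 / (b$n - 1), 0))
    method <- "Welch t"
  }
  new_test_result(c(t = tstat), df = df, p = 2 * pt(-abs(tstat), df),
                  method = method, flags = flags)
}

#' Pearson chi-square test for a 2x2 table
#'
#' `chi2 = N (ad - bc)^2 / (r1 r2 c1 c2)` with 1 degree of freedom and an
#' upper-tail p-value; no continuity correction is applied (this is the
#' form that reproduces published cohort-table statistics). A zero row or
#' column margin is an error.
#'
#' @param table A 2x2 matrix of non-negative integer counts, rows = groups,
#'   columns = outcome present/absent.
#' @return A `"gaknn_test"` with `statistic = c(chi_square = ...)`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("2x2 table has a zero margin; chi-square is undefined")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  new_test_result(c(chi_square = unname(ct$statistic)), df = 1,
                  p = unname(ct$p.value), method = "Pearson chi-square")
}

#' Helper: 2x2 table from per-group yes-counts
#' @param yes1,n1 Count with the attribute and group size, first group.
#' @param yes2,n2 Likewise for the second group.
#' @return A 2x2 integer matrix (rows = groups, columns = yes/no).
#' @export
counts_2x2 <- function(yes1, n1, yes2, n2) {
  matrix(c(yes1, yes2, n1 - yes1, n2 - yes2), 2L, 2L,
         dimnames = list(group = c("g1", "g2"), outcome = c("yes", "no")))
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties);
#' the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (exact +/-1 gives p = 0). Constant input leaves rho undefined
#' (`NA`, flag `degenerate`).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A `"gaknn_test"` with `statistic = c(rho = ...)`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(new_test_result(c(rho = NA_real_), df = NA_real_, p = NA_real_,
                           method = "Spearman rho",
                           flags = "degenerate: constant input"))
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  new_test_result(c(rho = rho), df = n - 2, p = p, method = "Spearman rho")
}

#' Holm step-down adjustment
#'
#' Classic Holm-Bonferroni: sort ascending, multiply the i-th smallest
#' p-value by `m - i + 1`, enforce monotone non-decrease, cap at 1, return
#' in the original order (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "holm")
}

#' Ordinary least squares with coefficient tests
#'
#' Least-squares fit of `response ~ design` (intercept added), with
#' two-sided t p-values per coefficient and the model R-squared. Rank
#' deficiency is an error naming the collinear columns rather than a
#' silent `NA` coefficient.
#'
#' @param design Numeric matrix or data.frame of regressors with named
#'   columns (n rows, p columns; requires `n > p + 1`).
#' @param response Numeric vector of length n.
#' @return A list of class `"ols_fit"`: `coefficients` (data.frame with
#'   `term`, `estimate`, `se`, `t`, `p`), `r_squared`, `df_residual`,
#'   `sigma`, `fitted`, `residuals`.
#' @export
ols_fit <- function(design, response) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(response) == n)
  if (n <= p + 1L) stop("need n > p + 1 observations")
  fit <- lm.fit(cbind(`(Intercept)` = 1, X), response)
  if (fit$rank < p + 1L) {
    bad <- colnames(cbind(1, X))[is.na(fit$coefficients)]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  df_res <- n - p - 1L
  rss <- sum(fit$residuals^2)
  tss <- sum((response - mean(response))^2)
  sigma2 <- rss / df_res
  XtXinv <- solve(crossprod(cbind(1, X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  est <- fit$coefficients
  tval <- est / se
  structure(list(
    coefficients = data.frame(term = names(est), estimate = unname(est),
                              se = unname(se), t = unname(tval),
                              p = unname(2 * pt(-abs(tval), df_res)),
                              row.names = NULL, stringsAsFactors = FALSE),
    r_squared = 1 - rss / tss, df_residual = df_res,
    sigma = sqrt(sigma2), fitted = fit$fitted.values,
    residuals = fit$residuals), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: R-squared %.4f on %d residual df\n", x$r_squared,
              x$df_residual))
  print(x$coefficients, digits = 4)
  invisible(x)
}

# R-squared of the regression of y on the subset S of regressors, computed
# from the (centered) covariance matrix C of cbind(y, X). S indexes into
# the regressor block.
r2_from_cov <- function(C, S) {
  if (!length(S)) return(0)
  syy <- C[1L, 1L]
  sxy <- C[S + 1L, 1L, drop = FALSE]
  Sxx <- C[S + 1L, S + 1L, drop = FALSE]
  drop(crossprod(sxy, solve(Sxx, sxy))) / syy
}

lmg_shares_from_cov <- function(C) {
  p <- nrow(C) - 1L
  # R^2 for every regressor subset, indexed by bitmask.
  r2 <- numeric(2^p)
  for (mask in seq_len(2^p - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    r2[mask + 1L] <- r2_from_cov(C, S)
  }
  # Subset-weight reformulation of the average over all p! orderings:
  # share_j = sum over S not containing j of s!(p-1-s)!/p! * increment.
  wts <- vapply(0:(p - 1L), function(s)
    exp(lfactorial(s) + lfactorial(p - 1L - s) - lfactorial(p)), numeric(1L))
  shares <- numeric(p)
  for (j in seq_len(p)) {
    bitj <- bitwShiftL(1L, j - 1L)
    for (mask in 0:(2^p - 1L)) {
      if (bitwAnd(mask, bitj) != 0L) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
      shares[j] <- shares[j] +
        wts[s + 1L] * (r2[bitwOr(mask, bitj) + 1L] - r2[mask + 1L])
    }
  }
  shares
}

#' LMG relative-importance decomposition
#'
#' Decomposes the model R-squared of `response ~ design` over the
#' regressors by the Lindeman-Merenda-Gold method: a regressor's share is
#' its sequential R-squared increment averaged over all `p!` orderings in
#' which the regressors can enter the model. Up to `max_exact` regressors
#' the average is computed exactly through the subset reformulation
#' (increments weighted by `s!(p-1-s)!/p!` over all subsets); beyond that,
#' a seeded random sample of orderings is averaged.
#'
#' @param design Regressor matrix/data.frame with named columns.
#' @param response Numeric response vector.
#' @param max_exact Largest p for exact enumeration (default 10).
#' @param n_orderings Number of sampled orderings when `p > max_exact`.
#' @param seed Seed for the sampled mode; required when sampling so the
#'   decomposition is reproducible.
#' @return A list of class `"lmg_result"`: `shares` (data.frame with
#'   `term`, `share_raw`, `share_fraction`), `r_squared`, `mode`
#'   (`"exact"` or `"sampled"`), `n_orderings`.
#' @export
lmg_decomposition <- function(design, response, max_exact = 10L,
                              n_orderings = 10000L, seed = NULL) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  fit <- ols_fit(X, response)  # validates rank and n
  C <- stats::cov(cbind(response, X))
  if (p <= max_exact) {
    shares <- lmg_shares_from_cov(C)
    mode <- "exact"; n_orderings <- NA_integer_
  } else {
    if (is.null(seed))
      stop("p > max_exact: sampled orderings require an explicit seed")
    shares <- withr_seed(seed, {
      acc <- numeric(p)
      for (b in seq_len(n_orderings)) {
        ord <- sample.int(p)
        prev <- 0
        S <- integer(0)
        for (j in ord) {
          S <- c(S, j)
          cur <- r2_from_cov(C, S)
          acc[j] <- acc[j] + (cur - prev)
          prev <- cur
        }
      }
      acc / n_orderings
    })
    mode <- "sampled"
  }
  structure(list(shares = data.frame(term = colnames(X), share_raw = shares,
                                     share_fraction = shares / sum(shares),
                                     row.names = NULL, stringsAsFactors = FALSE),
                 r_squared = fit$r_squared, mode = mode,
                 n_orderings = n_orderings),
            class = "lmg_result")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' LMG shares from a covariance matrix
#'
#' Exact LMG decomposition driven directly by a covariance (or population
#' covariance) matrix of `(response, regressors)`, with the response in the
#' first row/column. Used both internally and to derive the analytic
#' shares of a known generating model.
#'
#' @param C Covariance matrix, response first.
#' @return A list with `shares` (named raw shares), `share_fraction`,
#'   `r_squared`.
#' @export
lmg_from_covariance <- function(C) {
  C <- as.matrix(C)
  stopifnot(nrow(C) == ncol(C), nrow(C) >= 2L)
  shares <- lmg_shares_from_cov(C)
  names(shares) <- colnames(C)[-1L] %||% paste0("x", seq_len(nrow(C) - 1L))
  r2 <- r2_from_cov(C, seq_len(nrow(C) - 1L))
  list(shares = shares, share_fraction = shares / sum(shares), r_squared = r2)
}

#' @export
print.lmg_result <- function(x, ...) {
  cat(sprintf("LMG decomposition (%s): model R-squared %.4f\n", x$mode,
              x$r_squared))
  df <- x$shares
  df$share_pct <- sprintf("%.1f%%", 100 * df$share_fraction)
  print(df, digits = 4)
  invisible(x)
}

#' Cohort characteristics table
#'
#' Compares two named groups variable by variable: continuous variables by
#' the two-sample t test ([welch_t()], Welch by default) and dichotomous
#' 0/1 variables by [pearson_chi_square()] without continuity correction.
#' Variables listed but absent from the metadata, and dichotomous variables
#' with a zero margin, are skipped with a warning.
#'
#' @param metadata Data frame with a `class_label` column (see
#'   [read_metadata()]).
#' @param groups Length-2 character vector naming the two class labels to
#'   compare, reference group first.
#' @param continuous,dichotomous Column names to treat as continuous /
#'   dichotomous. By default, numeric columns with only values in `{0, 1}`
#'   are dichotomous and the remaining numeric columns continuous.
#' @param pooled Use the pooled t form for continuous variables.
#' @return A data.frame with one row per variable: group summaries,
#'   `statistic`, `df`, `p`.
#' @export
cohort_table <- function(metadata, groups = c("control", "AIS"),
                         continuous = NULL, dichotomous = NULL,
                         pooled = FALSE) {
  stopifnot(length(groups) == 2L, "class_label" %in% names(metadata))
  lab <- as.character(metadata$class_label)
  if (!all(groups %in% lab)) stop("both groups must be present in metadata")
  sub <- metadata[lab %in% groups, , drop = FALSE]
  lab <- as.character(sub$class_label)
  num_cols <- names(sub)[vapply(sub, is.numeric, logical(1L))]
  if (is.null(dichotomous))
    dichotomous <- num_cols[vapply(sub[num_cols], function(v)
      all(v %in% c(0, 1, NA)), logical(1L))]
  if (is.null(continuous)) continuous <- setdiff(num_cols, dichotomous)
  rows <- list()
  for (v in c(continuous, dichotomous)) {
    if (!v %in% names(sub)) {
      warning("variable '", v, "' absent from metadata; skipped")
      next
    }
    x1 <- sub[[v]][lab == groups[1L]]
    x2 <- sub[[v]][lab == groups[2L]]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2L || length(x2) < 2L) {
      warning("variable '", v, "' has fewer than 2 observations in a group; skipped")
      next
    }
    if (v %in% dichotomous) {
      tab <- counts_2x2(sum(x1), length(x1), sum(x2), length(x2))
      if (any(colSums(tab) == 0)) {
        warning("variable '", v, "' has a zero margin; skipped")
        next
      }
      tr <- pearson_chi_square(tab)
      rows[[v]] <- data.frame(
        variable = v, type = "dichotomous",
        group1 = sprintf("%d/%d (%.1f%%)", sum(x1), length(x1),
                         100 * mean(x1)),
        group2 = sprintf("%d/%d (%.1f%%)", sum(x2), length(x2),
                         100 * mean(x2)),
        statistic = unname(tr$statistic), df = tr$df, p = tr$p,
        test = tr$method, stringsAsFactors = FALSE)
    } else {
      tr <- welch_t(x1, x2, pooled = pooled)
      rows[[v]] <- data.frame(
        variable = v, type = "continuous",
        group1 = sprintf("%.1f+/-%.1f", mean(x1), sd(x1)),
        group2 = sprintf("%.1f+/-%.1f", mean(x2), sd(x2)),
        statistic = unname(tr$statistic), df = tr$df, p = tr$p,
        test = tr$method, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
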