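# Shared fixtures and independent oracles for the test suite. Everything
# here is deliberately naive (loops, closed forms) so it cannot share a
# bug with the implementation paths it checks.

# A two-class matrix in which the first `n_sep` genes separate the classes
# perfectly (disjoint value ranges) and the rest are noise.
make_separable <- function(n1 = 6, n2 = 6, n_genes = 8, n_sep = 2, sd = 0.1,
                           seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  x <- matrix(rnorm(n_genes * n, sd = 1), n_genes, n)
  for (g in seq_len(n_sep))
    x[g, ] <- c(rnorm(n1, 0, sd), rnorm(n2, 5, sd))
  dimnames(x) <- list(paste0("g", seq_len(n_genes)), paste0("s", seq_len(n)))
  list(x = x, labels = c(rep("control", n1), rep("AIS", n2)))
}

# Brute-force leave-one-out kNN: per-sample distance table, explicit stable
# (distance, index) ordering, explicit vote count.
oracle_loo_predict <- function(expr, labels, genes, k) {
  x <- expr[genes, , drop = FALSE]
  n <- ncol(x)
  labels <- as.character(labels)
  out <- character(n)
  for (i in seq_len(n)) {
    d2 <- numeric(n)
    for (j in seq_len(n)) d2[j] <- sum((x[, i] - x[, j])^2)
    cand <- setdiff(seq_len(n), i)
    cand <- cand[order(d2[cand], cand)]
    nn <- cand[seq_len(k)]
    tab <- table(labels[nn])
    out[i] <- names(tab)[which.max(tab)]
  }
  out
}

oracle_loo_fitness <- function(expr, labels, genes, k) {
  mean(oracle_loo_predict(expr, labels, genes, k) == as.character(labels))
}

# LMG by explicit average over all p! orderings of sequential R-squared
# increments, each R-squared from a fresh lm() fit.
oracle_lmg <- function(design, response) {
  X <- as.matrix(design)
  p <- ncol(X)
  perms <- permutations(p)
  shares <- numeric(p)
  for (r in seq_len(nrow(perms))) {
    prev <- 0
    S <- integer(0)
    for (j in perms[r, ]) {
      S <- c(S, j)
      r2 <- summary(lm(response ~ X[, S, drop = FALSE]))$r.squared
      shares[j] <- shares[j] + (r2 - prev)
      prev <- r2
    }
  }
  shares / nrow(perms)
}

permutations <- function(p) {
  if (p == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(p - 1L)
  out <- NULL
  for (j in seq_len(p)) {
    block <- cbind(j, sub + (sub >= j))
    out <- rbind(out, block)
  }
  out
}

# Stepwise Holm adjustment written out by hand.
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- min(1, (m - i + 1) * p[ord[i]])
    running <- max(running, val)
    adj[ord[i]] <- running
  }
  adj
}

# Construct a p x n data matrix whose sample correlation matrix is exactly
# `target` (whiten empirically, then colour by chol(target)).
data_with_exact_correlation <- function(target, n, seed = 1) {
  set.seed(seed)
  p <- nrow(target)
  y <- matrix(rnorm(p * n), p, n)
  y <- y - rowMeans(y)
  w <- solve(t(chol(tcrossprod(y) / (n - 1))))  # whitening
  z <- w %*% y
  x <- t(chol(target)) %*% z
  rownames(x) <- paste0("g", seq_len(p))
  colnames(x) <- paste0("s", seq_len(n))
  x
}

write_expr_fixture <- function(x) {
  f <- tempfile(fileext = ".tsv")
  write_expression_matrix(x, f)
  f
}
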