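# The core GA/kNN machinery: kNN prediction, leave-one-out chromosome
# fitness, the mutation operator, the hill-climbing search with random
# restarts, near-optimal-pool collection, frequency ranking, and an
# exhaustive enumeration oracle for small instances.
#
# A "chromosome" is a fixed-size set of distinct gene indices (stored
# sorted); its fitness is the fraction of cohort samples correctly
# classified by leave-one-out kNN (self excluded) in the chromosome's
# feature space. Chromosomes whose fitness reaches the termination cutoff
# are near-optimal solutions; genes are ranked by how often they appear in
# the pool of collected solutions.

#' GA search parameters
#'
#' Defaults follow the discovery configuration: chromosome length 5, five
#' nearest neighbours with majority rule, termination cutoff 0.97 and a
#' pool of 2,000 near-optimal solutions. The hill-climbing internals
#' (population size, per-gene mutation probability with a forced change,
#' random restarts after `max_mutation_cycles`) are exposed because they
#' are not dictated by the fitness definition.
#'
#' @param d Chromosome length (number of genes evaluated jointly).
#' @param k Number of nearest neighbours; must be odd.
#' @param cutoff Termination cutoff in (0, 1]: minimum leave-one-out
#'   fitness for a chromosome to be recorded as a near-optimal solution.
#' @param n_solutions Number of near-optimal solutions to collect.
#' @param max_mutation_cycles Mutation cycles per search before the search
#'   is abandoned and restarted from a fresh random population.
#' @param population_size Chromosomes evolved in parallel per search.
#' @param mutation_rate Per-position replacement probability (default
#'   `1/d`); if no position mutates, one is forced to change.
#' @param min_success_rate Abort pool collection if the fraction of
#'   searches reaching the cutoff falls below this floor.
#' @return A list of class `"ga_params"`.
#' @export
ga_params <- function(d = 5L, k = 5L, cutoff = 0.97, n_solutions = 2000L,
                      max_mutation_cycles = 10000L, population_size = 50L,
                      mutation_rate = 1 / d, min_success_rate = 0.001) {
  stopifnot(d >= 1, cutoff > 0, cutoff <= 1, n_solutions >= 1,
            population_size >= 1, mutation_rate >= 0, mutation_rate <= 1,
            max_mutation_cycles >= 1)
  if (k < 1 || k %% 2 == 0) stop("k must be odd and >= 1")
  structure(list(d = as.integer(d), k = as.integer(k), cutoff = cutoff,
                 n_solutions = as.integer(n_solutions),
                 max_mutation_cycles = as.integer(max_mutation_cycles),
                 population_size = as.integer(population_size),
                 mutation_rate = mutation_rate,
                 min_success_rate = min_success_rate),
            class = "ga_params")
}

# Map class labels onto 0/1 integers. Fitness only needs agreement, so the
# coding is irrelevant there; metrics use positive = "AIS".
binary_labels <- function(labels, positive = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("binary labels required, got classes: ",
         paste(classes, collapse = ", "))
  if (is.null(positive)) positive <- if ("AIS" %in% classes) "AIS" else classes[2L]
  if (!positive %in% classes) stop("positive class '", positive, "' not present")
  structure(as.integer(labels == positive), positive = positive,
            negative = setdiff(classes, positive))
}

#' Classify one sample by k-nearest neighbours
#'
#' Euclidean distance in the feature space of the supplied training matrix;
#' the `k` nearest training samples vote and the majority class is
#' returned. Distance ties straddling the k-th rank are resolved by stable
#' sort on (distance, training-sample index), so the result is
#' deterministic. With two classes and odd `k` the vote itself cannot tie.
#'
#' @param train Features x training-samples numeric matrix (e.g. a z-scored
#'   expression matrix restricted to a chromosome).
#' @param train_labels Class labels of the training samples.
#' @param query Numeric vector of length `nrow(train)`.
#' @param k Number of neighbours (odd, `<= ncol(train)`).
#' @return The predicted class label (same type of values as
#'   `train_labels`).
#' @export
knn_predict <- function(train, train_labels, query, k = 5L) {
  stopifnot(is.matrix(train), length(query) == nrow(train),
            length(train_labels) == ncol(train))
  if (k < 1 || k %% 2 == 0) stop("k must be odd and >= 1")
  if (ncol(train) < k) stop("need at least k training samples")
  d2 <- colSums((train - query)^2)
  nn <- order(d2, seq_along(d2))[seq_len(k)]  # stable (distance, index)
  votes <- table(as.character(train_labels)[nn])
  names(votes)[which.max(votes)]
}

#' Leave-one-out kNN fitness of a chromosome
#'
#' Each sample is classified from the remaining samples (self excluded)
#' using only the chromosome's genes; fitness is the fraction classified
#' correctly, in `[0, 1]`. This is the quantity the GA maximises and the
#' termination cutoff is applied to.
#'
#' @param expr Genes x samples numeric matrix (z-scored for the search).
#' @param labels Two-class label vector.
#' @param chromosome Integer vector of distinct gene indices (or gene ids
#'   matching `rownames(expr)`).
#' @param k Number of neighbours (odd); needs `ncol(expr) >= k + 1`.
#' @return Fitness in `[0, 1]`.
#' @export
chromosome_fitness <- function(expr, labels, chromosome, k = 5L) {
  chromosome <- resolve_genes(expr, chromosome)
  if (ncol(expr) < k + 1L) stop("need at least k + 1 samples")
  y <- binary_labels(labels)
  .loo_fitness_batch(expr, matrix(chromosome, ncol = 1L), as.integer(y), as.integer(k))[1L]
}

resolve_genes <- function(expr, genes) {
  if (is.character(genes)) {
    idx <- match(genes, rownames(expr))
    if (anyNA(idx))
      stop("gene id(s) not in matrix: ",
           paste(genes[is.na(idx)], collapse = ", "))
    genes <- idx
  }
  genes <- as.integer(genes)
  if (anyDuplicated(genes)) stop("chromosome has duplicate genes")
  if (any(genes < 1L | genes > nrow(expr))) stop("gene index out of range")
  genes
}

#' Mutate a chromosome
#'
#' Each position is independently replaced, with probability
#' `mutation_rate`, by a uniformly drawn pool gene not already in the
#' chromosome; if no position mutates, one randomly chosen position is
#' forced to change, so the output always differs from the input. The
#' result is returned in canonical sorted order.
#'
#' @param chromosome Integer vector of distinct gene indices.
#' @param gene_pool Integer vector of candidate gene indices
#'   (`length(gene_pool) > length(chromosome)`).
#' @param mutation_rate Per-position replacement probability.
#' @return A mutated chromosome (sorted integer vector).
#' @export
mutate_chromosome <- function(chromosome, gene_pool, mutation_rate = 1 / length(chromosome)) {
  d <- length(chromosome)
  stopifnot(d >= 1, length(gene_pool) > d)
  out <- chromosome
  hit <- runif(d) < mutation_rate
  if (!any(hit)) hit[sample.int(d, 1L)] <- TRUE
  for (j in which(hit)) {
    repeat {
      g <- gene_pool[sample.int(length(gene_pool), 1L)]
      if (!g %in% out) break
    }
    out[j] <- g
  }
  sort(out)
}

#' One GA search for a near-optimal chromosome
#'
#' Maintains a population of random chromosomes; every cycle each member
#' proposes a mutant and keeps the better of parent and mutant (hill
#' climbing). The first chromosome whose leave-one-out fitness reaches the
#' cutoff is returned; if no chromosome passes within
#' `max_mutation_cycles`, the search reports exhaustion (callers restart
#' with a fresh random population).
#'
#' @param expr Z-scored genes x samples matrix.
#' @param labels Two-class label vector.
#' @param params [ga_params()].
#' @param gene_pool Optional integer vector of gene indices to search
#'   within (default: all rows of `expr`).
#' @return A list with `success`, `genes` (sorted indices), `fitness`,
#'   `cycles`, `evals`.
#' @export
ga_search_one <- function(expr, labels, params = ga_params(),
                          gene_pool = seq_len(nrow(expr))) {
  y <- binary_labels(labels)
  gene_pool <- as.integer(gene_pool)
  if (length(gene_pool) <= params$d)
    stop("gene pool must be larger than the chromosome length")
  .ga_search_cpp(expr, as.integer(y), gene_pool, params$d, params$k,
                 params$cutoff, params$population_size,
                 as.double(params$max_mutation_cycles), params$mutation_rate)
}

#' Collect a pool of near-optimal solutions
#'
#' Runs independent GA searches (restarting exhausted ones) until
#' `params$n_solutions` chromosomes with fitness at or above the cutoff
#' have been recorded. Duplicate chromosomes may appear in the pool;
#' frequency ranking is the point of the pool, and `dedup = TRUE` switches
#' to unique-only pooling. Collection aborts with a diagnostic if the
#' search success rate falls below `params$min_success_rate`, which
#' normally means the cutoff is unreachable for the data.
#'
#' @inheritParams ga_search_one
#' @param dedup Keep only distinct chromosomes in the pool.
#' @return An object of class `"noso_pool"`: list with `chromosomes`
#'   (d x n_solutions integer matrix of gene indices), `fitness`,
#'   `gene_ids`, `params`, and search diagnostics `n_searches`,
#'   `n_exhausted`, `n_evals`.
#' @export
collect_near_optimal_pool <- function(expr, labels, params = ga_params(),
                                      gene_pool = seq_len(nrow(expr)),
                                      dedup = FALSE) {
  y <- binary_labels(labels)
  gene_pool <- as.integer(gene_pool)
  if (length(gene_pool) <= params$d)
    stop("gene pool must be larger than the chromosome length")
  res <- .ga_collect_pool_cpp(expr, as.integer(y), gene_pool, params$d,
                              params$k, params$cutoff, params$n_solutions,
                              params$population_size,
                              as.double(params$max_mutation_cycles),
                              params$mutation_rate, params$min_success_rate,
                              200L)
  chroms <- res$chromosomes
  fitness <- res$fitness
  if (dedup) {
    key <- apply(chroms, 2L, paste, collapse = ",")
    keep <- !duplicated(key)
    chroms <- chroms[, keep, drop = FALSE]
    fitness <- fitness[keep]
  }
  structure(list(chromosomes = chroms, fitness = fitness,
                 gene_ids = rownames(expr), params = params,
                 n_searches = res$n_searches, n_exhausted = res$n_exhausted,
                 n_evals = res$n_evals),
            class = "noso_pool")
}

#' @export
print.noso_pool <- function(x, ...) {
  cat(sprintf("Near-optimal solution pool: %d chromosomes of length %d\n",
              ncol(x$chromosomes), nrow(x$chromosomes)))
  cat(sprintf("  fitness: min %.3f, median %.3f (cutoff %.2f)\n",
              min(x$fitness), stats::median(x$fitness), x$params$cutoff))
  cat(sprintf("  %s searches run, %s exhausted, %.0f fitness evaluations\n",
              format(x$n_searches), format(x$n_exhausted), x$n_evals))
  invisible(x)
}

#' Rank genes by selection frequency in the pool
#'
#' A gene's score is the number of pool chromosomes containing it. Ties are
#' broken by the mean fitness of the chromosomes containing the gene
#' (higher first), then by gene id, so the ranking is deterministic.
#'
#' @param pool A `"noso_pool"` from [collect_near_optimal_pool()].
#' @return A data.frame of class `"gene_ranking"` with columns `rank`,
#'   `gene_id`, `gene_index`, `count`, `mean_fitness`, ordered best-first.
#' @export
rank_genes <- function(pool) {
  stopifnot(inherits(pool, "noso_pool"), ncol(pool$chromosomes) >= 1L)
  idx <- as.vector(pool$chromosomes)
  fit <- rep(pool$fitness, each = nrow(pool$chromosomes))
  count <- tapply(fit, idx, length)
  meanfit <- tapply(fit, idx, mean)
  gene_index <- as.integer(names(count))
  gene_id <- if (!is.null(pool$gene_ids)) pool$gene_ids[gene_index] else
    as.character(gene_index)
  ord <- order(-as.vector(count), -as.vector(meanfit), gene_id)
  out <- data.frame(rank = seq_along(ord), gene_id = gene_id[ord],
                    gene_index = gene_index[ord],
                    count = as.integer(count[ord]),
                    mean_fitness = as.vector(meanfit)[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Enumerate every chromosome passing the cutoff (test oracle)
#'
#' Exhaustively scores all `choose(n, d)` gene subsets with
#' [chromosome_fitness()] and returns those at or above the cutoff. Only
#' feasible on small instances; the enumeration budget guards against
#' accidental combinatorial blow-up.
#'
#' @inheritParams chromosome_fitness
#' @param d Chromosome length.
#' @param cutoff Fitness cutoff.
#' @param gene_pool Indices to enumerate within (default all genes).
#' @param budget Maximum number of subsets allowed (default 200,000).
#' @return A list with `chromosomes` (d x m matrix, sorted columns) and
#'   `fitness`.
#' @export
exhaustive_oracle <- function(expr, labels, d, k = 5L, cutoff = 0.97,
                              gene_pool = seq_len(nrow(expr)),
                              budget = 2e5) {
  n <- length(gene_pool)
  if (choose(n, d) > budget)
    stop("enumeration budget exceeded: choose(", n, ", ", d, ") subsets")
  y <- binary_labels(labels)
  subsets <- combn(as.integer(gene_pool), d)
  fitness <- .loo_fitness_batch(expr, subsets, as.integer(y), as.integer(k))
  keep <- fitness >= cutoff
  list(chromosomes = subsets[, keep, drop = FALSE], fitness = fitness[keep])
}
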