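test_that("knn_predict follows the majority of the nearest neighbours", {
  # 1-D: controls at 0, AIS at 1, query at 0.9 -> all five 1s are nearest
  train <- matrix(c(rep(0, 5), rep(1, 5)), nrow = 1)
  labs <- c(rep("control", 5), rep("AIS", 5))
  expect_equal(knn_predict(train, labs, 0.9, k = 5), "AIS")
  expect_equal(knn_predict(train, labs, 0.1, k = 5), "control")
  # k = 1, query on a training point
  expect_equal(knn_predict(train, labs, 1, k = 1), "AIS")
  expect_equal(knn_predict(train, labs, 0, k = 1), "control")
})

test_that("kNN prediction and fitness agree with a brute-force oracle", {
  set.seed(21)
  for (rep in 1:8) {
    n1 <- sample(4:7, 1); n2 <- sample(4:7, 1)
    x <- matrix(rnorm((n1 + n2) * 6), 6, n1 + n2,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:(n1 + n2))))
    labels <- c(rep("control", n1), rep("AIS", n2))
    genes <- sort(sample(6, 3))
    for (k in c(1, 3, 5)) {
      expect_equal(chromosome_fitness(x, labels, genes, k),
                   oracle_loo_fitness(x, labels, genes, k))
      # single-query prediction vs oracle, leave-one-out style
      i <- sample(n1 + n2, 1)
      pred <- knn_predict(x[genes, -i, drop = FALSE], labels[-i],
                          x[genes, i], k)
      expect_equal(pred, oracle_loo_predict(x, labels, genes, k)[i])
    }
  }
})

test_that("fitness is in [0,1], order-invariant, and perfect on separable data", {
  sim <- make_separable(n1 = 6, n2 = 6, n_genes = 8, n_sep = 2)
  expect_equal(chromosome_fitness(sim$x, sim$labels, c(1, 2), k = 3), 1.0)
  set.seed(9)
  for (rep in 1:5) {
    genes <- sample(8, 4)
    f1 <- chromosome_fitness(sim$x, sim$labels, genes, k = 3)
    f2 <- chromosome_fitness(sim$x, sim$labels, rev(genes), k = 3)
    expect_identical(f1, f2)
    expect_gte(f1, 0); expect_lte(f1, 1)
  }
  expect_error(chromosome_fitness(sim$x[, 1:4], sim$labels[1:4], 1:2, k = 5),
               "k \\+ 1")
})

test_that("compiled fitness kernel matches class::knn.cv on tie-free data", {
  skip_if_not_installed("class")
  set.seed(33)
  x <- matrix(rnorm(20 * 30), 20, 30)
  labels <- sample(c("control", "AIS"), 30, replace = TRUE, prob = c(.4, .6))
  for (k in c(1, 3, 5)) {
    genes <- sort(sample(20, 5))
    ours <- chromosome_fitness(x, labels, genes, k)
    ref <- mean(as.character(class::knn.cv(t(x[genes, ]), labels, k = k)) == labels)
    expect_equal(ours, ref)
  }
})

test_that("mutation replaces genes as specified", {
  set.seed(17)
  chrom <- c(2L, 5L, 9L)
  pool <- 1:20
  # rate 0: forced change in exactly one position
  for (rep in 1:20) {
    out <- mutate_chromosome(chrom, pool, mutation_rate = 0)
    expect_equal(length(setdiff(chrom, out)), 1L)
    expect_equal(length(out), 3L)
    expect_false(is.unsorted(out))
    expect_equal(anyDuplicated(out), 0L)
    expect_true(all(out %in% pool))
  }
  # pigeonhole: pool of size d + 1 leaves one possible replacement
  out <- mutate_chromosome(c(1L, 2L, 3L), 1:4, mutation_rate = 0)
  expect_true(4L %in% out)

  # empirical per-position change frequency ~ rate (positions not forced)
  rate <- 0.3
  n_draw <- 4000
  changed <- 0
  for (rep in seq_len(n_draw)) {
    out <- mutate_chromosome(chrom, pool, mutation_rate = rate)
    changed <- changed + length(setdiff(chrom, out))
  }
  # P(>=1 of 3 mutates) = 1 - 0.7^3; forced rule redistributes the
  # zero-change mass, so expected changes per draw:
  p0 <- (1 - rate)^3
  expected <- 3 * rate + p0 * 1
  se <- sqrt(3 * rate * (1 - rate) / n_draw)  # conservative
  expect_lt(abs(changed / n_draw - expected), 4 * se + 0.02)
})

test_that("GA search succeeds immediately on trivially separable data and exhausts on noise", {
  sim <- make_separable(n1 = 6, n2 = 6, n_genes = 6, n_sep = 6)
  p <- ga_params(d = 2, k = 3, cutoff = 1.0, n_solutions = 1,
                 population_size = 5)
  set.seed(2)
  res <- ga_search_one(z_transform(sim$x), sim$labels, p)
  expect_true(res$success)
  expect_equal(res$fitness, 1.0)
  expect_equal(res$cycles, 0)  # random initialisation already passes

  set.seed(4)
  noise <- matrix(rnorm(10 * 12), 10, 12,
                  dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  labs <- rep(c("control", "AIS"), 6)
  p2 <- ga_params(d = 2, k = 3, cutoff = 1.0, max_mutation_cycles = 5,
                  population_size = 5)
  res2 <- ga_search_one(noise, labs, p2)
  expect_false(res2$success)
})

test_that("GA output is always contained in the exhaustive oracle's passing set", {
  set.seed(55)
  n1 <- 7; n2 <- 7
  x <- matrix(rnorm(8 * (n1 + n2)), 8, n1 + n2,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:(n1 + n2))))
  x[1, ] <- c(rnorm(n1, 0, 0.6), rnorm(n2, 2, 0.6))
  x[2, ] <- c(rnorm(n1, 0, 0.6), rnorm(n2, -2, 0.6))
  labels <- c(rep("control", n1), rep("AIS", n2))
  z <- z_transform(x)
  oracle <- exhaustive_oracle(z, labels, d = 2, k = 3, cutoff = 0.9)
  expect_gt(ncol(oracle$chromosomes), 0)
  okey <- apply(oracle$chromosomes, 2, paste, collapse = "-")
  p <- ga_params(d = 2, k = 3, cutoff = 0.9, population_size = 10)
  for (s in 1:25) {
    set.seed(100 + s)
    res <- ga_search_one(z, labels, p)
    expect_true(res$success)
    expect_true(paste(res$genes, collapse = "-") %in% okey)
  }
})

test_that("pool collection is sound, deterministic, and respects dedup", {
  sim <- make_separable(n1 = 7, n2 = 7, n_genes = 10, n_sep = 3, seed = 8)
  z <- z_transform(sim$x)
  p <- ga_params(d = 2, k = 3, cutoff = 0.9, n_solutions = 40,
                 population_size = 10)
  set.seed(42)
  pool1 <- collect_near_optimal_pool(z, sim$labels, p)
  expect_equal(ncol(pool1$chromosomes), 40)
  expect_true(all(pool1$fitness >= p$cutoff))
  # independent re-scoring of every entry with the R oracle
  rescore <- apply(pool1$chromosomes, 2, function(g)
    oracle_loo_fitness(z, sim$labels, g, k = 3))
  expect_equal(rescore, pool1$fitness)

  set.seed(42)
  pool2 <- collect_near_optimal_pool(z, sim$labels, p)
  expect_identical(pool1$chromosomes, pool2$chromosomes)
  expect_identical(pool1$fitness, pool2$fitness)

  set.seed(42)
  pool3 <- collect_near_optimal_pool(z, sim$labels, p, dedup = TRUE)
  expect_equal(anyDuplicated(apply(pool3$chromosomes, 2, paste, collapse = "-")), 0L)

  # single-solution pool on separable data
  p1 <- ga_params(d = 2, k = 3, cutoff = 0.9, n_solutions = 1,
                  population_size = 10)
  set.seed(1)
  expect_equal(ncol(collect_near_optimal_pool(z, sim$labels, p1)$chromosomes), 1)
})

test_that("pool collection aborts with a diagnostic when the cutoff is hopeless", {
  set.seed(10)
  noise <- matrix(rnorm(12 * 12), 12, 12,
                  dimnames = list(paste0("g", 1:12), paste0("s", 1:12)))
  labs <- rep(c("control", "AIS"), 6)
  p <- ga_params(d = 2, k = 3, cutoff = 1.0, n_solutions = 5,
                 max_mutation_cycles = 3, population_size = 5,
                 min_success_rate = 0.5)
  expect_error(collect_near_optimal_pool(z_transform(noise), labs, p),
               "success rate")
})

test_that("gene ranking counts pool membership with deterministic ties", {
  mkpool <- function(chroms, fitness, ids) {
    structure(list(chromosomes = chroms, fitness = fitness, gene_ids = ids,
                   params = ga_params(d = nrow(chroms), k = 3, cutoff = 0.5),
                   n_searches = ncol(chroms), n_exhausted = 0,
                   n_evals = ncol(chroms)),
              class = "noso_pool")
  }
  ids <- paste0("g", 1:9)
  # one chromosome: all five genes count 1
  p1 <- mkpool(matrix(1:5, 5, 1), 1.0, ids)
  r1 <- rank_genes(p1)
  expect_equal(r1$count, rep(1L, 5))
  expect_equal(sort(r1$gene_index), 1:5)

  # {1,2}, {1,3}, {1,4}: gene 1 count 3, others 1
  p2 <- mkpool(cbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)), c(0.9, 0.8, 0.7), ids)
  r2 <- rank_genes(p2)
  expect_equal(r2$gene_index[1], 1L)
  expect_equal(r2$count, c(3L, 1L, 1L, 1L))
  # count ties broken by mean fitness (gene 2 from the 0.9 chromosome first)
  expect_equal(r2$gene_index[2:4], c(2L, 3L, 4L))
  # sum of counts = d * pool size
  expect_equal(sum(r2$count), 2L * 3L)
})

test_that("exhaustive oracle enumerates exactly the passing subsets", {
  x <- rbind(g1 = c(0, 0, 0, 5, 5, 5), g2 = rnorm(6), g3 = rnorm(6))
  colnames(x) <- paste0("s", 1:6)
  labels <- rep(c("control", "AIS"), each = 3)
  z <- z_transform(x)
  o <- exhaustive_oracle(z, labels, d = 1, k = 1, cutoff = 1.0)
  expect_identical(as.vector(o$chromosomes), 1L)

  set.seed(3)
  noise <- matrix(rnorm(4 * 8), 4, 8,
                  dimnames = list(paste0("g", 1:4), paste0("s", 1:8)))
  labs <- rep(c("control", "AIS"), 4)
  o2 <- exhaustive_oracle(z_transform(noise), labs, d = 2, k = 3, cutoff = 1.0)
  expect_equal(ncol(o2$chromosomes), 0)

  expect_error(exhaustive_oracle(z, labels, d = 1, k = 1, budget = 2),
               "budget")
})
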