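test_that("pascal_probability: enumeration, big-integer oracle, properties", {
  expect_equal(pascal_probability(100, 0), 1.0)
  # N=10, K=2: enumerate all position pairs
  n_pairs <- ncol(combn(10, 2))
  expect_equal(n_pairs, 45)
  expect_equal(pascal_probability(10, 2), 1 / 45)
  # log-space path vs exact big-integer binomial
  set.seed(19)
  for (i in 1:20) {
    N <- sample(20:5000, 1)
    K <- sample(0:10, 1)
    expect_equal(-log(pascal_probability(N, K)), oracle_log_choose(N, K),
                 tolerance = 1e-13)
  }
  # strictly decreasing in K for fixed N >= 2K
  p <- pascal_probability(rep(1500, 6), 0:5)
  expect_true(all(diff(p) < 0))
  expect_error(pascal_probability(5, 6), "exceed")
  # BH table carries raw and adjusted values
  tab <- pascal_gene_table(c(gA = 900, gB = 1200), c(gA = 3, gB = 0))
  expect_equal(tab$p_pascal[tab$gene_id == "gB"], 1)
  expect_true(all(tab$p_bh >= tab$p_pascal))
})

test_that("continuum_randomization handles trivial and analytic cases", {
  g <- tiny_genome()
  # all conditions empty
  expect_warning(
    r0 <- continuum_randomization(g, list(a = numeric(0), b = numeric(0)),
                                  iterations = 100, seed = 1),
    "zero observed")
  expect_equal(r0$observed, 0)
  expect_equal(r0$p_empirical, 1)
  expect_true(r0$p_empirical >= 1 / 101)

  # single gene covering half of a one-contig genome: hit prob ~ 0.5
  half <- annotated_genome(
    c(c1 = strrep("ACGT", 500)),  # 2000 bp
    data.frame(gene_id = "g", contig = "c1", start = 1L, end = 999L,
               strand = "+", kind = "CDS", product = ""))
  res <- continuum_randomization(half, list(a = 500), statistic = "shared_genes",
                                 iterations = 10000, seed = 42)
  p_hat <- res$null_mean  # E[S] = P(single draw lands in the gene)
  p_true <- 999 / 2000
  mc_sd <- sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(p_hat - p_true), 3 * mc_sd)
})

test_that("continuum_randomization is seed-reproducible and p is bounded", {
  sim <- simulate_dataset(small_config(seed = 41))
  gen <- sim$genome
  obs <- lapply(sim$replicates, function(reps) {
    m <- merge_replicates(reps)
    m$variants[, c("contig", "pos")]
  })
  r1 <- continuum_randomization(gen, obs, iterations = 2000, seed = 7)
  r2 <- continuum_randomization(gen, obs, iterations = 2000, seed = 7)
  expect_identical(r1$null, r2$null)
  expect_identical(r1$p_empirical, r2$p_empirical)
  expect_true(r1$p_empirical >= 1 / 2001)
  expect_true(r1$p_empirical <= 1)
  # p_combined is reported separately for the default statistic
  if (r1$observed > 0) expect_true(!is.null(r1$p_combined))
})

test_that("vectorized null statistics agree with the slow custom-function path", {
  sim <- simulate_dataset(small_config(seed = 43))
  gen <- sim$genome
  obs <- lapply(sim$replicates, function(reps) {
    merge_replicates(reps)$variants[, c("contig", "pos")]
  })
  slow_shared <- function(pos_by_cond, lookup) {
    sets <- lapply(pos_by_cond, function(p) {
      idx <- findInterval(p, lookup$gstart)
      ok <- idx > 0 & p <= lookup$gend[pmax(idx, 1)]
      unique(idx[ok])
    })
    length(Reduce(intersect, sets))
  }
  # chunk_size = 1 makes the vectorized path consume the RNG stream in the
  # same order as the per-iteration custom-function path
  fast <- continuum_randomization(gen, obs, iterations = 300, seed = 11,
                                  chunk_size = 1)
  slow <- continuum_randomization(gen, obs, statistic = slow_shared,
                                  iterations = 300, seed = 11)
  expect_equal(fast$observed, slow$observed)
  expect_equal(fast$null, slow$null)
})

test_that("friedman_test matches stats::friedman.test including ties", {
  # all conditions identical per block -> statistic 0, p 1
  m0 <- matrix(rep(c(1, 2, 3, 4), 3), ncol = 3)
  f0 <- friedman_test(m0)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p_value, 1)

  set.seed(101)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    k <- sample(2:5, 1)
    m <- matrix(sample(1:4, n * k, replace = TRUE), n, k)  # many ties
    if (all(apply(m, 1, function(r) length(unique(r)) == 1))) next
    f <- friedman_test(m)
    ref <- stats::friedman.test(m)
    expect_equal(f$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(f$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(f$df, unname(ref$parameter))
  }
})

test_that("friedman statistic is invariant under monotone block transforms", {
  set.seed(55)
  m <- matrix(rnorm(12), 4, 3)
  f1 <- friedman_test(m)$statistic
  m2 <- t(apply(m, 1, function(r) exp(r)))       # strictly monotone per block
  expect_equal(friedman_test(m2)$statistic, f1)
})

test_that("exact friedman p matches a brute-force permutation oracle", {
  set.seed(17)
  m <- matrix(rnorm(9), 3, 3)  # n=3 blocks, k=3: 216 permutations
  got <- friedman_test(m, exact = TRUE)
  # oracle: enumerate permutations of each block's values independently,
  # score with stats::friedman.test
  perms <- matrix(c(1,2,3, 1,3,2, 2,1,3, 2,3,1, 3,1,2, 3,2,1),
                  ncol = 3, byrow = TRUE)
  obs <- unname(stats::friedman.test(m)$statistic)
  stats_all <- c()
  for (i1 in 1:6) for (i2 in 1:6) for (i3 in 1:6) {
    mp <- rbind(m[1, perms[i1, ]], m[2, perms[i2, ]], m[3, perms[i3, ]])
    stats_all <- c(stats_all, unname(stats::friedman.test(mp)$statistic))
  }
  expect_equal(got$statistic, obs, tolerance = 1e-12)
  expect_equal(got$p_value, mean(stats_all >= obs - 1e-9), tolerance = 1e-12)
  expect_equal(got$n_permutations, 216)
})

test_that("nemenyi_posthoc flags pairs by critical difference", {
  expect_false(nemenyi_posthoc(matrix(1:8, ncol = 2))$applicable)

  # identical conditions are never flagged
  m <- matrix(rep(c(5, 1, 3, 2), 3), ncol = 3)
  nz <- nemenyi_posthoc(m)
  expect_true(all(!nz$pairs$significant))

  # strongly separated conditions: extreme pair flagged, agrees with a
  # brute-force comparison using the same quantile table
  set.seed(3)
  n <- 12
  m2 <- cbind(rnorm(n, 0), rnorm(n, 2), rnorm(n, 8))
  nm <- nemenyi_posthoc(m2)
  r <- t(apply(m2, 1, rank))
  mr <- colMeans(r)
  cd <- qtukey(0.95, 3, Inf) / sqrt(2) * sqrt(3 * 4 / (6 * n))
  for (j in seq_len(nrow(nm$pairs))) {
    i1 <- match(nm$pairs$a[j], colnames(m2) %||% paste0("cond", 1:3))
    i2 <- match(nm$pairs$b[j], colnames(m2) %||% paste0("cond", 1:3))
    expect_equal(nm$pairs$significant[j], abs(mr[i1] - mr[i2]) > cd)
  }
  expect_true(any(nm$pairs$significant))

  # boundary semantics on constructed ranks (1,2,3 in every block):
  # mean-rank gaps are 1, 2, 1 while CD ~ 1.048, so only the extreme pair
  # clears the threshold
  nmb <- nemenyi_posthoc(matrix(c(1, 2, 3), 10, 3, byrow = TRUE))
  gaps <- c(1, 2, 1)
  expect_lt(gaps[1], nmb$critical_difference)
  expect_gt(gaps[2], nmb$critical_difference)
  expect_equal(nmb$pairs$significant, gaps > nmb$critical_difference)
})

test_that("two_sample_t matches t.test and is antisymmetric", {
  a <- c(1, 1, 1)
  expect_equal(two_sample_t(a, a), list(t = 0, df = 4, p_value = 1))
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(sample(3:10, 1))
    y <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    for (ev in c(TRUE, FALSE)) {
      got <- two_sample_t(x, y, equal_variance = ev)
      ref <- t.test(x, y, var.equal = ev)
      expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
      swap <- two_sample_t(y, x, equal_variance = ev)
      expect_equal(swap$t, -got$t)
      expect_equal(swap$p_value, got$p_value)
    }
  }
  # hand-computed 3 vs 3 pooled example
  x <- c(1, 2, 3); y <- c(2, 4, 6)
  sp2 <- (var(x) * 2 + var(y) * 2) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  expect_equal(two_sample_t(x, y)$t, t_hand, tolerance = 1e-12)
})
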