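rand_nets <- function(n_sub, n_nodes, mean = 0, sd = 1) {
  lapply(seq_len(n_sub), function(i) {
    m <- matrix(rnorm(n_nodes^2, mean, sd), n_nodes, n_nodes)
    diag(m) <- 0
    m
  })
}

test_that("paired edge statistics behave like a paired t-test", {
  set.seed(1)
  std <- rand_nets(6, 4)
  expect_warning(es0 <- paired_edge_stats(std, std), "zero-variance")
  expect_true(all(es0$t == 0))

  dev <- lapply(std, function(m) m + matrix(rnorm(16, sd = 0.5), 4, 4))
  es <- paired_edge_stats(std, dev)
  expect_equal(es$f, es$t^2)
  # agree with stats::t.test on a specific edge
  d12 <- vapply(seq_along(std), function(i) dev[[i]][1, 2] - std[[i]][1, 2],
                numeric(1))
  expect_equal(es$t[1, 2], unname(t.test(d12)$statistic),
               tolerance = 1e-12)
  expect_error(paired_edge_stats(std[1:2], dev[1:2]), "3 subjects")
})

test_that("a planted mean shift is the top paired statistic almost always", {
  set.seed(2)
  hits <- replicate(100, {
    std <- rand_nets(13, 6)
    dev <- lapply(std, function(m) {
      m2 <- m + matrix(rnorm(36), 6, 6)
      m2[2, 5] <- m2[2, 5] + 1.5  # shift of 1.5 noise-SDs
      diag(m2) <- 0
      m2
    })
    es <- paired_edge_stats(std, dev)
    which.max(abs(es$t)) == (5 - 1) * 6 + 2
  })
  expect_gte(mean(hits), 0.95)
})

test_that("interaction statistics flip sign but not F when groups swap", {
  set.seed(3)
  a <- rand_nets(5, 4)
  b <- rand_nets(6, 4, mean = 0.3)
  ab <- interaction_edge_stats(a, b)
  ba <- interaction_edge_stats(b, a)
  expect_equal(ab$t, -ba$t, tolerance = 1e-12)
  expect_equal(ab$f, ba$f, tolerance = 1e-12)

  # identical groups: all statistics vanish (no degenerate variance)
  same <- rand_nets(4, 4)
  es0 <- interaction_edge_stats(same, same)
  expect_true(all(es0$t == 0))

  # fully constant data is degenerate and warned about
  const <- lapply(1:4, function(i) matrix(1 - diag(3), 3, 3))
  expect_warning(esc <- interaction_edge_stats(const, const),
                 "zero-variance")
  expect_true(all(esc$t == 0))

  # planted group-specific difference is the top |t|
  b2 <- lapply(b, function(m) {
    m[3, 1] <- m[3, 1] + 3
    m
  })
  es <- interaction_edge_stats(a, b2)
  expect_equal(which.max(abs(es$t)), (1 - 1) * 4 + 3)
})

test_that("permutation p-values agree with the exhaustive sign-flip oracle", {
  set.seed(4)
  D <- matrix(rnorm(5 * 9), 5, 9)
  D[, 1] <- D[, 1] + 2
  es <- edge_stats <- structure(
    list(t = matrix(ptenet:::col_t_onesample(D), 3, 3), data = D,
         n_nodes = 3, scheme = "one_sample"),
    class = "edge_stats")
  diag(es$t) <- 0
  design <- contrast_design("one_sample", n_permutations = 10000, seed = 5)
  p_mc <- permutation_pvalues(es, design)
  p_ex <- oracle_signflip_exhaustive(D)
  off <- row(p_mc) != col(p_mc)
  expect_lt(max(abs(p_mc[off] - p_ex[off])), 0.02)

  # determinism and subject-order invariance
  expect_identical(permutation_pvalues(es, design), p_mc)
  es_perm <- es
  es_perm$data <- D[c(3, 1, 5, 2, 4), ]
  expect_lt(max(abs(permutation_pvalues(es_perm, design)[off] - p_mc[off])),
            0.02)
})

test_that("an extreme observed statistic attains the add-one lower bound", {
  set.seed(6)
  D <- matrix(rnorm(10 * 4, sd = 0.01), 10, 4)
  D[, 2] <- D[, 2] + 10  # only the identity flip can tie this statistic
  es <- structure(
    list(t = matrix(ptenet:::col_t_onesample(D), 2, 2), data = D,
         n_nodes = 2, scheme = "one_sample"), class = "edge_stats")
  diag(es$t) <- 0
  design <- contrast_design("one_sample", n_permutations = 500, seed = 7)
  p <- permutation_pvalues(es, design)
  # identity flip reproduces |t_obs| so the count is at least 1/(P+1);
  # a constant column can never be beaten, only tied
  expect_gte(p[2, 1], 1 / 501)
  expect_lt(p[2, 1], 0.05)
})

test_that("BH mask matches the step-up definition", {
  expect_identical(fdr_bh(c(0.001, 0.02, 0.03, 0.04), 0.05),
                   rep(TRUE, 4))
  expect_identical(fdr_bh(rep(0.9, 6), 0.05), rep(FALSE, 6))
  set.seed(8)
  for (i in 1:100) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(fdr_bh(p, q), oracle_bh(p, q))
  }
  expect_error(fdr_bh(c(0.1, 0.2), 0), "q")
  expect_error(fdr_bh(c(0.1, 2), 0.05), "0, 1")
})

test_that("significant networks carry correct summaries", {
  n <- 360
  stats <- matrix(0, n, n)
  pvals <- matrix(1, n, n)
  mask <- matrix(FALSE, n, n)
  set.seed(9)
  idx <- cbind(sample.int(n, 67), sample.int(n, 67))
  idx <- idx[idx[, 1] != idx[, 2], ][1:60, ]
  # plus a handful of fixed edges to reach exactly 67
  extra <- cbind(1:7, 101:107)
  idx <- rbind(idx, extra)[1:67, ]
  mask[idx] <- TRUE
  stats[idx] <- rnorm(67)
  pvals[idx] <- 1e-5
  sn <- significant_network(stats, pvals, mask)
  expect_equal(nrow(sn$edges), 67)
  expect_equal(sn$density, 67 / (360 * 359))
  expect_equal(sum(sn$nodes$degree), 2 * 67)
  expect_equal(sum(sn$nodes$strength), 2 * sum(abs(stats[idx])))

  empty <- significant_network(stats, pvals, mask & FALSE)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(empty$density, 0)

  expect_s3_class(tidy(sn), "tbl_df")
  expect_equal(glance(sn)$n_edges, 67)
})

test_that("the full paired chain controls false positives and finds effects", {
  # power at a strong planted effect
  set.seed(10)
  # the add-one p floor 1/(P+1) must sit below the rank-one BH cut
  # q/m = 0.05/56, hence 2000 permutations
  design <- contrast_design("paired_condition", n_permutations = 2000,
                            q = 0.05, seed = 11)
  found <- replicate(10, {
    std <- rand_nets(13, 8)
    dev <- lapply(std, function(m) {
      m2 <- m + matrix(rnorm(64), 8, 8)
      m2[1, 2] <- m2[1, 2] + 2.5
      diag(m2) <- 0
      m2
    })
    sn <- network_contrast(std, dev, design)
    any(sn$edges$source == "node001" & sn$edges$target == "node002")
  })
  expect_gte(mean(found), 0.8)
})
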