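rand_trials <- function(n_trials, n_nodes, sd = 1) {
  arr <- array(rnorm(n_nodes^2 * n_trials, sd = sd),
               dim = c(n_nodes, n_nodes, n_trials))
  for (k in seq_len(n_trials)) diag(arr[, , k]) <- 0
  arr
}

test_that("identical conditions give unit edge correlations everywhere", {
  set.seed(1)
  a <- rand_trials(10, 4)
  ml <- edge_condition_correlation(a, a, alpha = 0.05)
  off <- row(ml$matrix) != col(ml$matrix)
  expect_true(all(abs(ml$matrix[off] - 1) < 1e-12))
  expect_identical(diag(ml$matrix), rep(0, 4))
  expect_equal(ml$n_pairs, 10)
  expect_error(edge_condition_correlation(a[, , 1:3], a[, , 1:3]),
               "4 paired trials")
})

test_that("the per-edge correlation threshold is calibrated under independence", {
  set.seed(2)
  fracs <- replicate(40, {
    a <- rand_trials(60, 6)
    b <- rand_trials(60, 6)
    ml <- edge_condition_correlation(a, b, alpha = 0.05)
    off <- row(ml$matrix) != col(ml$matrix)
    mean(ml$matrix[off] != 0)
  })
  # binomial CI around 0.05 over 40 x 30 edge tests
  se <- sqrt(0.05 * 0.95 / (40 * 30))
  expect_lt(abs(mean(fracs) - 0.05), 4 * se)
})

test_that("random pairing destroys chronological alignment reproducibly", {
  set.seed(3)
  a <- rand_trials(30, 4)
  m1 <- edge_condition_correlation(a, a, pairing = "random", seed = 5)
  m2 <- edge_condition_correlation(a, a, pairing = "random", seed = 5)
  expect_identical(m1$matrix, m2$matrix)
  off <- row(m1$matrix) != col(m1$matrix)
  expect_lt(mean(m1$matrix[off] == 1), 0.2)
  expect_error(edge_condition_correlation(a, a, pairing = "random"),
               "seed")
})

test_that("multilayer assembly mirrors off-diagonal blocks", {
  z <- function(seed) {
    set.seed(seed)
    m <- matrix(rnorm(9), 3, 3)
    diag(m) <- 0
    m
  }
  nets <- list(std = z(1), dev = z(2))
  ml <- z(3)
  g <- assemble_multilayer(nets, list("std|dev" = ml), subject = "s1")
  expect_equal(dim(g$matrix), c(6, 6))
  expect_equal(g$matrix[1:3, 1:3], nets$std, ignore_attr = TRUE)
  expect_equal(g$matrix[4:6, 4:6], nets$dev, ignore_attr = TRUE)
  expect_equal(g$matrix[1:3, 4:6], ml, ignore_attr = TRUE)
  expect_equal(g$matrix[4:6, 1:3], ml, ignore_attr = TRUE)

  expect_error(assemble_multilayer(nets, list()), "missing multilink")
  expect_error(
    assemble_multilayer(nets, list("std|dev" = matrix(0, 2, 2))),
    "shape")
})

test_that("multilayer graphs round-trip through disk bit-exactly", {
  set.seed(4)
  nets <- list(a = matrix(rnorm(16), 4, 4), b = matrix(rnorm(16), 4, 4))
  for (n in names(nets)) diag(nets[[n]]) <- 0
  g <- assemble_multilayer(nets,
                           list("a|b" = matrix(rnorm(16), 4, 4)),
                           subject = "s7")
  prefix <- file.path(withr::local_tempdir(), "graph")
  write_multilayer_graph(g, prefix)
  g2 <- read_multilayer_graph(prefix)
  expect_identical(g2$matrix, g$matrix)
  expect_identical(g2$states, g$states)
  expect_identical(g2$subject, "s7")
})

test_that("one-sample graph test finds planted entries and nothing in null graphs", {
  set.seed(5)
  make_graphs <- function(n_sub, planted = FALSE) {
    lapply(seq_len(n_sub), function(i) {
      nets <- list(a = matrix(rnorm(25), 5, 5), b = matrix(rnorm(25), 5, 5))
      for (n in names(nets)) diag(nets[[n]]) <- 0
      ml <- matrix(0, 5, 5)
      if (planted) ml[2, 3] <- 0.8 + rnorm(1, sd = 0.05)
      assemble_multilayer(nets, list("a|b" = ml),
                          subject = paste0("s", i))
    })
  }
  # the planted entry must beat the BH cut q/m, so the sign-flip p floor
  # (max(1/(P+1), 2/2^n)) has to sit below it: 15 subjects, 2000 flips
  design <- contrast_design("one_sample", n_permutations = 2000,
                            q = 0.05, seed = 6)

  null_graphs <- lapply(1:15, function(i) {
    g <- make_graphs(1)[[1]]
    g$matrix[] <- 0
    g
  })
  ms0 <- group_one_sample_graph_test(null_graphs, design)
  expect_equal(nrow(ms0$network$edges), 0)

  planted_graphs <- make_graphs(15, planted = TRUE)
  ms <- group_one_sample_graph_test(planted_graphs, design)
  blk <- ptenet:::multilayer_block(ms$mask, ms$states, ms$n_nodes, "a", "b")
  expect_true(blk[2, 3])
  expect_identical(group_one_sample_graph_test(planted_graphs, design), ms)
})

test_that("group differences split by sign into the two contrasts", {
  set.seed(7)
  mk <- function(n_sub, bump) {
    lapply(seq_len(n_sub), function(i) {
      nets <- list(a = matrix(rnorm(16), 4, 4), b = matrix(rnorm(16), 4, 4))
      for (n in names(nets)) diag(nets[[n]]) <- 0
      ml <- matrix(0, 4, 4)
      ml[1, 2] <- bump + rnorm(1, sd = 0.1)
      ml[3, 4] <- -bump + rnorm(1, sd = 0.1)
      assemble_multilayer(nets, list("a|b" = ml))
    })
  }
  design <- contrast_design("two_sample", n_permutations = 2000,
                            q = 0.01, seed = 8)
  res <- group_difference_graph_test(mk(7, 2), mk(7, -2), design)
  blk_ab <- ptenet:::multilayer_block(res$a_gt_b$mask, res$a_gt_b$states,
                                      4, "a", "b")
  blk_ba <- ptenet:::multilayer_block(res$b_gt_a$mask, res$b_gt_a$states,
                                      4, "a", "b")
  expect_true(blk_ab[1, 2])   # group A higher here
  expect_true(blk_ba[3, 4])   # group B higher here
  expect_false(any(blk_ab & blk_ba))

  # identical groups: both contrasts empty
  same <- mk(6, 1)
  res0 <- group_difference_graph_test(same, same, design)
  expect_equal(nrow(res0$a_gt_b$network$edges), 0)
  expect_equal(nrow(res0$b_gt_a$network$edges), 0)
})

test_that("between-block node degree counts incident significant entries", {
  mask <- matrix(FALSE, 8, 8)  # 2 states x 4 nodes
  mask[1, 6] <- TRUE  # state a node 1 -> state b node 2
  ms <- structure(list(mask = mask, states = c("a", "b"), n_nodes = 4),
                  class = "multilayer_stat")
  deg <- between_block_node_degree(ms, c("a", "b"))
  expect_equal(deg$degree, c(1L, 1L, 0L, 0L))
  expect_equal(sum(deg$degree), 2 * 1)

  empty <- structure(list(mask = mask & FALSE, states = c("a", "b"),
                          n_nodes = 4), class = "multilayer_stat")
  expect_true(all(between_block_node_degree(empty, c("a", "b"))$degree == 0))
  expect_error(between_block_node_degree(ms, c("a", "zz")), "unknown")
})

test_that("multilink components match a union-find oracle", {
  expect_equal(multilink_components(matrix(0, 4, 4))$n_components, 0)

  m <- matrix(0, 5, 5)
  m[1, 2] <- 1
  m[3, 4] <- -0.4
  expect_equal(multilink_components(m)$n_components, 2)

  set.seed(9)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    mask <- matrix(rbinom(n^2, 1, 0.15), n, n)
    diag(mask) <- 0
    res <- multilink_components(mask)
    orc <- oracle_components(mask)
    expect_equal(res$n_components, orc$n)
    # identical partitions up to component relabeling
    if (orc$n > 0) {
      a <- res$membership[order(as.integer(names(res$membership)))]
      b <- orc$membership[order(as.integer(names(orc$membership)))]
      expect_identical(names(a), names(b))
      expect_equal(length(unique(paste(a, b))), length(unique(a)))
    }
  }
})

test_that("common links are the elementwise intersection", {
  set.seed(10)
  masks <- lapply(1:3, function(i) matrix(rbinom(36, 1, 0.4), 6, 6))
  cl <- common_links(masks)
  expect_identical(cl, masks[[1]] != 0 & masks[[2]] != 0 & masks[[3]] != 0)
  expect_identical(common_links(list(masks[[1]], masks[[1]])),
                   masks[[1]] != 0)
  expect_false(any(common_links(list(diag(3), 1 - diag(3)))))
  expect_error(common_links(list(diag(3), diag(4))), "shape")
})

test_that("oscillator-simulated co-modulation yields the top edge correlations", {
  # full generator -> PTE -> edge-correlation path at sparse coupling
  # density, where the planted co-modulation stays edge-local; a planted
  # coupling co-modulates the PTE of both its directions, so planted
  # edges and their reversals are the expected top entries
  gt <- make_ground_truth(20, 12, n_multilink = 3, effect = 0, seed = 5,
                          conditions = c("standard", "audiovisual"))
  es <- simulate_subject_epochs(gt, 40, n_samples = 1441, fs = 900,
                                seed = 9)
  cfg <- pte_config()
  trials <- lapply(c("standard", "audiovisual"), function(cc) {
    idx <- which(es$condition == cc)
    simplify2array(lapply(idx, function(k)
      pte_matrix(es$data[k, , ], es$fs, cfg)))
  })
  mlm <- edge_condition_correlation(trials[[1]], trials[[2]],
                                    alpha = 0.05)
  r <- mlm$matrix
  top <- arrayInd(order(-abs(r))[1:3], dim(r))
  planted <- rbind(cbind(gt$multilink$source, gt$multilink$target),
                   cbind(gt$multilink$target, gt$multilink$source))
  expect_gte(sum(paste(top[, 1], top[, 2]) %in%
                   paste(planted[, 1], planted[, 2])), 2)
})
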