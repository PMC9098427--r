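test_that("ground truth respects its invariants and is deterministic", {
  gt <- make_ground_truth(30, 20, n_multilink = 5, effect = 0.5, seed = 7)
  expect_s3_class(gt, "ground_truth")
  expect_true(all(gt$coupling$source != gt$coupling$target))
  expect_true(all(is.finite(gt$coupling$strength)))
  expect_equal(nrow(gt$multilink), 5L)
  # multilinks lie within the paired conditions' edge sets
  for (cond in unique(c(gt$multilink$pair_a, gt$multilink$pair_b))) {
    ce <- gt$coupling[gt$coupling$condition == cond, ]
    expect_true(all(paste(gt$multilink$source, gt$multilink$target) %in%
                      paste(ce$source, ce$target)))
  }
  # same seed -> identical object
  expect_identical(gt, make_ground_truth(30, 20, 5, 0.5, seed = 7))

  # zero effect -> all conditions share identical strengths
  gt0 <- make_ground_truth(3, 1, 0, effect = 0, seed = 1)
  by_cond <- split(gt0$coupling$strength, gt0$coupling$condition)
  expect_true(all(vapply(by_cond, identical, TRUE, by_cond[[1]])))

  expect_error(make_ground_truth(2, 1, 0, 0, seed = 1), "n_nodes")
  expect_error(make_ground_truth(5, 0, 0, 0, seed = 1), "positive")
  expect_error(make_ground_truth(5, 3, 4, 0, seed = 1), "n_multilink")
  expect_error(make_ground_truth(5, 3, 0, effect = -5, seed = 1),
               "negative")
})

test_that("zero coupling, zero noise yields pure sinusoids at the natural frequency", {
  gt <- unidirectional_gt(seed = 3, strength = 0,
                          process_noise_sd = 0, measurement_noise_sd = 0)
  es <- simulate_subject_epochs(gt, 1, n_samples = 1200, fs = 600, seed = 11)
  set.seed(11)
  freqs <- runif(3, gt$oscillator_band[1], gt$oscillator_band[2])
  for (i in 1:3) {
    ph <- analytic_phase(es$data[1, i, ], 600, band = c(2, 60))
    mid <- 300:900
    inc <- diff(ph[mid])
    inc <- Arg(exp(1i * inc))  # unwrap
    expect_equal(mean(inc), 2 * pi * freqs[i] / 600, tolerance = 1e-3)
    expect_lt(sd(inc), 1e-2)
  }
})

test_that("simulation is bit-identical under a fixed seed and rejects bad input", {
  gt <- make_ground_truth(5, 4, 1, 0.2, seed = 2)
  a <- simulate_subject_epochs(gt, 3, n_samples = 100, fs = 300, seed = 4)
  b <- simulate_subject_epochs(gt, 3, n_samples = 100, fs = 300, seed = 4)
  expect_identical(a$data, b$data)
  expect_identical(attr(a, "trial_strengths"), attr(b, "trial_strengths"))
  expect_equal(dim(a$data), c(12, 5, 100))
  expect_true(all(table(a$condition) == 3))

  expect_error(simulate_subject_epochs(gt, 3, n_samples = 10, fs = 300,
                                       seed = 1), "sim_delay")
  expect_error(simulate_subject_epochs(gt, 3, n_samples = 100, fs = -1,
                                       seed = 1), "fs")
})

test_that("a strongly coupled edge is recovered directionally by PTE", {
  gt <- unidirectional_gt(seed = 5)
  es <- simulate_subject_epochs(gt, 1, n_samples = 1921, fs = 1200,
                                seed = 21)
  m <- pte_matrix(es$data[1, , ], 1200, pte_config())
  expect_gt(m[1, 2], m[2, 1])
})

edge_strength_cors <- function(gt, es) {
  ts <- attr(es, "trial_strengths")
  pair <- c(gt$multilink$pair_a[1], gt$multilink$pair_b[1])
  w <- ts |>
    dplyr::filter(condition %in% pair) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "kappa")
  cors <- w |>
    dplyr::group_by(source, target) |>
    dplyr::summarise(r = cor(.data[[pair[1]]], .data[[pair[2]]]),
                     .groups = "drop")
  cors$is_multilink <- paste(cors$source, cors$target) %in%
    paste(gt$multilink$source, gt$multilink$target)
  cors
}

test_that("multilink edges share their trial-strength draws across the pair", {
  gt2 <- make_ground_truth(6, 4, 2, 0, seed = 8, gamma = 2)
  es2 <- simulate_subject_epochs(gt2, 20, n_samples = 50, fs = 100, seed = 9)
  cors <- edge_strength_cors(gt2, es2)
  expect_true(all(abs(cors$r[cors$is_multilink] - 1) < 1e-12))
  expect_true(all(abs(cors$r[!cors$is_multilink]) < 0.9))

  # gamma = 0 removes the sharing: correlation collapses to noise level
  # (independent modulation kept on so strengths still vary)
  gt0 <- make_ground_truth(6, 4, 2, 0, seed = 8, gamma = 0,
                           trial_modulation_sd = 0.5)
  es0 <- simulate_subject_epochs(gt0, 40, n_samples = 50, fs = 100, seed = 9)
  cors0 <- edge_strength_cors(gt0, es0)
  expect_true(all(abs(cors0$r[cors0$is_multilink]) < 0.5))
})

test_that("multilink trial-strength correlation exceeds that of other edges", {
  # rank comparison over repeated simulations
  set.seed(99)
  diffs <- replicate(50, {
    seed <- sample.int(1e6, 1)
    gt <- make_ground_truth(6, 6, 2, 0, seed = seed, gamma = 2)
    es <- simulate_subject_epochs(gt, 15, n_samples = 40, fs = 100,
                                  seed = seed + 1)
    ts <- attr(es, "trial_strengths")
    pair <- c(gt$multilink$pair_a[1], gt$multilink$pair_b[1])
    cors <- edge_strength_cors(gt, es)
    mean(cors$r[cors$is_multilink]) - mean(cors$r[!cors$is_multilink])
  })
  expect_gt(mean(diffs > 0), 0.9)
  expect_lt(wilcox.test(diffs, alternative = "greater")$p.value, 0.01)
})

test_that("behavioral simulation draws binomial counts reproducibly", {
  acc <- tidyr::expand_grid(group = c("g1", "g2"),
                            modality = c("auditory", "visual",
                                         "audiovisual"))
  acc$accuracy <- 0.8
  tab <- simulate_behavior(acc, 12, c(g1 = 4, g2 = 3), seed = 2)
  expect_equal(nrow(tab), 7 * 3)
  expect_true(all(tab$n_correct >= 0 & tab$n_correct <= 12))
  expect_identical(tab, simulate_behavior(acc, 12, c(g1 = 4, g2 = 3),
                                          seed = 2))

  bad <- acc
  bad$accuracy[1] <- 1
  expect_error(simulate_behavior(bad, 12, c(g1 = 2, g2 = 2), seed = 1),
               "strictly inside")

  # law of large numbers at p = 0.5
  acc5 <- tibble::tibble(group = "g", modality = "auditory",
                         accuracy = 0.5)
  big <- simulate_behavior(acc5, 12, c(g = 10000), seed = 3)
  expect_equal(mean(big$n_correct / big$n_trials), 0.5,
               tolerance = 3 * sqrt(0.25 / 12 / 10000) / 0.5)

  hi <- tibble::tibble(group = "g", modality = "auditory",
                       accuracy = 0.999)
  htab <- simulate_behavior(hi, 12, c(g = 20), seed = 4)
  expect_true(mean(htab$n_correct == 12) > 0.8)
})
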