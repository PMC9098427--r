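#' Ground truth for the phase-oscillator generator
#'
#' Defines a multi-condition set of directed coupling edges among phase
#' oscillators, the deviant-condition effect edges, and the edges whose
#' trial-level strength modulation is shared across a condition pair
#' ("planted multilinks"). Every downstream stage of the pipeline can be
#' validated against this object.
#'
#' Edge topology is shared across conditions; each deviant condition adds
#' `effect` (in relative strength units, base 1) to its own designated
#' subset of edges, so condition contrasts have a known target. Multilink
#' edges carry a shared-modulation gain `gamma`: at simulation time the
#' per-trial strength of such an edge is `kappa * (1 + gamma * u)` with the
#' standard-normal draw `u` shared between trial k of the two paired
#' conditions; all other edges get an independent draw with gain
#' `trial_modulation_sd`.
#'
#' @param n_nodes Number of oscillators (>= 3).
#' @param edges_per_condition Number of directed coupling edges.
#' @param n_multilink Number of edges with shared cross-condition
#'   modulation (<= `edges_per_condition`).
#' @param effect Additive strength increment (relative units) applied on
#'   each deviant condition's designated edges; must not drive any
#'   strength negative.
#' @param seed Integer seed; the construction is deterministic given it.
#' @param conditions Ordered condition names; first is the standard.
#' @param gamma Shared-modulation gain of the multilink edges (>= 0).
#' @param multilink_pair Length-2 character, the condition pair whose
#'   trial draws are shared on multilink edges.
#' @param n_effect_edges Number of designated effect edges per deviant
#'   condition; default `ceiling(edges_per_condition / 5)`.
#' @param oscillator_band Range (Hz) for natural frequencies, default 8--12.
#' @param coupling_scale Conversion from relative strength units to rad/s
#'   applied at simulation time.
#' @param trial_modulation_sd Gain of the independent per-trial strength
#'   modulation on non-multilink edges; defaults to `gamma`, so every
#'   edge follows the same `kappa * (1 + gain * u)` law and only the
#'   sharing of `u` distinguishes multilinks.
#' @param process_noise_sd,measurement_noise_sd Nonnegative noise SDs
#'   (rad per step; observation units).
#' @param sim_delay Coupling delay in samples (positive integer).
#' @param edges Optional data frame (`source`, `target`, optionally
#'   `strength`) fixing the coupling topology instead of sampling it;
#'   `edges_per_condition` is then ignored.
#' @return A `ground_truth` object.
#' @examples
#' gt <- make_ground_truth(10, 6, n_multilink = 2, effect = 0.5, seed = 1)
#' gt$coupling
#' @export
make_ground_truth <- function(n_nodes, edges_per_condition, n_multilink,
                              effect, seed,
                              conditions = c("standard", "audiovisual",
                                             "auditory", "visual"),
                              gamma = 2,
                              multilink_pair = c("standard", "audiovisual"),
                              n_effect_edges = NULL,
                              oscillator_band = c(8, 12),
                              coupling_scale = 60,
                              trial_modulation_sd = NULL,
                              process_noise_sd = 0.15,
                              measurement_noise_sd = 0.05,
                              sim_delay = 10L, edges = NULL) {
  n_nodes <- as.integer(n_nodes)
  if (!is.null(edges)) edges_per_condition <- nrow(edges)
  edges_per_condition <- as.integer(edges_per_condition)
  n_multilink <- as.integer(n_multilink)
  if (n_nodes < 3L) stop("`n_nodes` must be >= 3", call. = FALSE)
  if (edges_per_condition < 1L)
    stop("`edges_per_condition` must be positive", call. = FALSE)
  if (n_multilink < 0L || n_multilink > edges_per_condition)
    stop("`n_multilink` must lie in [0, edges_per_condition]", call. = FALSE)
  if (gamma < 0) stop("`gamma` must be nonnegative", call. = FALSE)
  if (length(conditions) < 2L) stop("need >= 2 conditions", call. = FALSE)
  if (!all(multilink_pair %in% conditions))
    stop("`multilink_pair` must name two of `conditions`", call. = FALSE)
  if (process_noise_sd < 0 || measurement_noise_sd < 0)
    stop("noise SDs must be nonnegative", call. = FALSE)
  sim_delay <- as.integer(sim_delay)
  if (sim_delay < 1L) stop("`sim_delay` must be positive", call. = FALSE)
  if (is.null(trial_modulation_sd)) trial_modulation_sd <- gamma
  if (is.null(n_effect_edges))
    n_effect_edges <- ceiling(edges_per_condition / 5)
  n_effect_edges <- min(as.integer(n_effect_edges), edges_per_condition)

  max_edges <- n_nodes * (n_nodes - 1L)
  if (edges_per_condition > max_edges)
    stop("more edges requested than ordered node pairs exist", call. = FALSE)

  withr::local_seed(seed)
  if (is.null(edges)) {
    # sample directed edges without self-loops or duplicates
    pool <- sample.int(max_edges, edges_per_condition)
    src <- (pool - 1L) %% n_nodes + 1L
    tgt <- (pool - 1L) %/% n_nodes + 1L
    tgt <- tgt + (tgt >= src)  # skip the diagonal
    base <- runif(edges_per_condition, 0.8, 1.2)
  } else {
    src <- as.integer(edges$source)
    tgt <- as.integer(edges$target)
    if (any(src == tgt)) stop("self-edges are not allowed", call. = FALSE)
    if (any(src < 1L | src > n_nodes | tgt < 1L | tgt > n_nodes))
      stop("edge endpoints out of range", call. = FALSE)
    base <- if ("strength" %in% names(edges)) edges$strength
            else runif(edges_per_condition, 0.8, 1.2)
  }
  if (any(base + effect < 0))
    stop("`effect` drives a coupling strength negative", call. = FALSE)

  deviants <- setdiff(conditions, conditions[1])
  coupling <- dplyr::bind_rows(lapply(conditions, function(cond) {
    strength <- base
    designated <- integer(0)
    if (cond != conditions[1] && n_effect_edges > 0) {
      designated <- sample.int(edges_per_condition, n_effect_edges)
      strength[designated] <- strength[designated] + effect
    }
    tibble::tibble(condition = cond, source = src, target = tgt,
                   strength = strength,
                   effect_edge = seq_along(src) %in% designated)
  }))

  ml_idx <- if (n_multilink > 0) sample.int(edges_per_condition, n_multilink)
            else integer(0)
  multilink <- tibble::tibble(
    source = src[ml_idx], target = tgt[ml_idx],
    pair_a = multilink_pair[1], pair_b = multilink_pair[2],
    gamma = rep(gamma, length(ml_idx))
  )

  structure(
    list(n_nodes = n_nodes, conditions = conditions, coupling = coupling,
         multilink = multilink, oscillator_band = as.numeric(oscillator_band),
         coupling_scale = coupling_scale,
         trial_modulation_sd = trial_modulation_sd,
         process_noise_sd = process_noise_sd,
         measurement_noise_sd = measurement_noise_sd,
         sim_delay = sim_delay, effect = effect, seed = seed),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", x$n_nodes, " nodes, ",
      nrow(x$coupling) / length(x$conditions), " edges/condition, ",
      nrow(x$multilink), " multilink edge(s), conditions: ",
      paste(x$conditions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate one subject's epoch set from a ground truth
#'
#' Evolves delayed-coupling phase oscillators (Euler step) for every trial
#' of every condition and observes `sin(theta)` plus measurement noise.
#' Natural frequencies are drawn once per subject from the ground truth's
#' oscillator band. Per-trial coupling strengths are
#' `kappa * (1 + g * u)`: for multilink edges `g` is the edge's `gamma`
#' and `u` is shared between trial k of the two paired conditions; for all
#' other edges `g = trial_modulation_sd` and `u` is independent.
#'
#' @param gt A [make_ground_truth()] object.
#' @param n_trials_per_condition Trials per condition.
#' @param n_samples Samples per epoch (default 1921).
#' @param fs Sampling rate in Hz (default 1200).
#' @param seed Integer seed; the simulation is deterministic given it.
#' @param subject Subject identifier stored with the result.
#' @return An `epoch_set`: list with `data` (trials x nodes x samples
#'   array), `fs`, `condition` (label per trial), `subject`, `node_labels`,
#'   and attribute `trial_strengths` (tibble of per-trial edge strengths,
#'   relative units).
#' @examples
#' gt <- make_ground_truth(4, 2, 0, 0, seed = 1)
#' es <- simulate_subject_epochs(gt, 2, n_samples = 200, fs = 300, seed = 1)
#' dim(es$data)
#' @export
simulate_subject_epochs <- function(gt, n_trials_per_condition,
                                    n_samples = 1921L, fs = 1200,
                                    seed, subject = "S01") {
  stopifnot(inherits(gt, "ground_truth"))
  n_samples <- as.integer(n_samples)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (n_samples <= gt$sim_delay + 2L)
    stop("`n_samples` must exceed sim_delay + 2", call. = FALSE)
  n_tr <- as.integer(n_trials_per_condition)
  if (n_tr < 1L) stop("need at least one trial per condition", call. = FALSE)

  conditions <- gt$conditions
  n_nodes <- gt$n_nodes
  withr::local_seed(seed)
  freqs <- runif(n_nodes, gt$oscillator_band[1], gt$oscillator_band[2])

  # per-condition edge tables in a fixed edge order
  cond_edges <- lapply(conditions, function(cond)
    dplyr::filter(gt$coupling, .data$condition == cond))
  names(cond_edges) <- conditions
  edge_key <- paste(cond_edges[[1]]$source, cond_edges[[1]]$target)
  ml_key <- paste(gt$multilink$source, gt$multilink$target)
  is_ml <- edge_key %in% ml_key

  # draw modulation factors: shared u for multilink edges across the pair,
  # independent u elsewhere; a zero-gamma multilink edge degrades to an
  # ordinary independently modulated edge
  is_shared <- edge_key %in% ml_key[gt$multilink$gamma > 0]
  shared_u <- matrix(rnorm(n_tr * sum(is_shared)), n_tr, sum(is_shared))
  n_edges <- length(edge_key)
  gains <- rep(gt$trial_modulation_sd, n_edges)
  if (nrow(gt$multilink)) {
    pos <- match(ml_key, edge_key)
    keep <- gt$multilink$gamma > 0
    gains[pos[keep]] <- gt$multilink$gamma[keep]
  }
  strength_rows <- vector("list", length(conditions))
  total_trials <- n_tr * length(conditions)
  data <- array(NA_real_, dim = c(total_trials, n_nodes, n_samples))
  condition_labels <- character(total_trials)

  trial_counter <- 0L
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    edges <- cond_edges[[cond]]
    in_pair <- cond %in% c(gt$multilink$pair_a, gt$multilink$pair_b)
    u <- matrix(rnorm(n_tr * n_edges), n_tr, n_edges)
    if (in_pair && any(is_shared)) u[, is_shared] <- shared_u
    kap_trial <- sweep(u, 2, gains, `*`) + 1  # (1 + g*u)
    kap_trial <- sweep(kap_trial, 2, edges$strength, `*`)
    strength_rows[[ci]] <- tibble::tibble(
      condition = cond,
      trial = rep(seq_len(n_tr), times = n_edges),
      source = rep(edges$source, each = n_tr),
      target = rep(edges$target, each = n_tr),
      kappa = as.numeric(kap_trial)
    )
    for (k in seq_len(n_tr)) {
      trial_counter <- trial_counter + 1L
      x <- cpp_simulate_trial(
        freqs, edges$source - 1L, edges$target - 1L,
        kap_trial[k, ] * gt$coupling_scale,
        n_samples, fs, gt$sim_delay,
        gt$process_noise_sd, gt$measurement_noise_sd
      )
      if (!all(is.finite(x)))
        stop("simulation diverged (non-finite output); reduce coupling",
             call. = FALSE)
      data[trial_counter, , ] <- x
      condition_labels[trial_counter] <- cond
    }
  }

  es <- structure(
    list(data = data, fs = fs, condition = condition_labels,
         subject = subject,
         node_labels = sprintf("node%03d", seq_len(n_nodes)),
         seed = seed),
    class = "epoch_set"
  )
  attr(es, "trial_strengths") <- dplyr::bind_rows(strength_rows)
  attr(es, "ground_truth") <- gt
  es
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> subject ", x$subject, ": ", dim(x$data)[1], " trials x ",
      dim(x$data)[2], " nodes x ", dim(x$data)[3], " samples @ ", x$fs,
      " Hz\n", sep = "")
  cat("conditions: ", paste(sprintf("%s (%d)", names(table(x$condition)),
                                    table(x$condition)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Simulate per-subject 2AFC correct-response counts
#'
#' Binomial draws of correct responses per subject and modality, given a
#' table of true accuracies by group and modality.
#'
#' @param accuracy_by_group_modality Data frame with columns `group`,
#'   `modality`, `accuracy`; accuracies must lie strictly inside (0, 1).
#' @param n_trials Trials per modality (default 12).
#' @param n_subjects_per_group Named integer vector of subjects per group.
#' @param seed Integer seed.
#' @return Tibble (subject, group, modality, n_correct, n_trials).
#' @examples
#' acc <- tidyr::expand_grid(group = c("a", "b"),
#'                           modality = c("auditory", "visual"))
#' acc$accuracy <- 0.8
#' simulate_behavior(acc, 12, c(a = 3, b = 3), seed = 1)
#' @export
simulate_behavior <- function(accuracy_by_group_modality, n_trials = 12L,
                              n_subjects_per_group, seed) {
  acc <- tibble::as_tibble(accuracy_by_group_modality)
  stopifnot(all(c("group", "modality", "accuracy") %in% names(acc)))
  if (any(acc$accuracy <= 0 | acc$accuracy >= 1))
    stop("accuracies must lie strictly inside (0, 1)", call. = FALSE)
  if (is.null(names(n_subjects_per_group)))
    stop("`n_subjects_per_group` must be a named vector", call. = FALSE)
  withr::local_seed(seed)
  rows <- lapply(names(n_subjects_per_group), function(g) {
    n_sub <- n_subjects_per_group[[g]]
    sub_ids <- sprintf("%s_%02d", g, seq_len(n_sub))
    ga <- dplyr::filter(acc, .data$group == g)
    if (nrow(ga) == 0) stop("no accuracies given for group ", g,
                            call. = FALSE)
    dplyr::bind_rows(lapply(seq_len(nrow(ga)), function(i)
      tibble::tibble(
        subject = sub_ids, group = g, modality = ga$modality[i],
        n_correct = rbinom(n_sub, n_trials, ga$accuracy[i]),
        n_trials = as.integer(n_trials)
      )))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$group, .data$subject,
                 .data$modality)
}
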