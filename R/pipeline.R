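#' Configuration of the scaled experiment pipeline
#'
#' Collects every knob of the end-to-end reproduction -- simulation
#' geometry, PTE settings, contrast design, multilink threshold -- with a
#' mandatory seed, and validates them once. Defaults run a desk-scale
#' version of a two-group, four-condition experiment.
#'
#' @param out_dir Output directory for all stages.
#' @param seed Integer seed (mandatory; every stochastic stage derives
#'   its stream from it).
#' @param n_nodes Nodes in the simulated source space.
#' @param n_subjects Named integer vector, subjects per group.
#' @param n_trials Trials per condition per subject.
#' @param n_samples,fs Epoch geometry (defaults 1921 samples at 1200 Hz).
#' @param edges_per_condition,n_multilink,effect,gamma Generator settings
#'   (see [make_ground_truth()]).
#' @param pte A [pte_config()].
#' @param n_permutations,q Contrast design settings.
#' @param alpha Per-edge multilink correlation threshold.
#' @param pairing Trial pairing scheme for the multilink correlation.
#' @param accuracies Behavioral accuracy table (group, modality,
#'   accuracy); defaults emulate above-chance performance in both groups.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed,
                            n_nodes = 30L,
                            n_subjects = c(groupA = 10L, groupB = 10L),
                            n_trials = 60L,
                            n_samples = 1921L, fs = 1200,
                            edges_per_condition = 20L,
                            n_multilink = 5L,
                            effect = 0.5, gamma = 2,
                            pte = pte_config(),
                            n_permutations = 1000L, q = 0.001,
                            alpha = 0.05,
                            pairing = "chronological",
                            accuracies = NULL) {
  if (missing(seed) || is.null(seed))
    stop("`seed` is mandatory", call. = FALSE)
  if (is.null(names(n_subjects)) || length(n_subjects) != 2L)
    stop("`n_subjects` must name exactly two groups", call. = FALSE)
  if (is.null(accuracies)) {
    accuracies <- tidyr::expand_grid(
      group = names(n_subjects),
      modality = c("audiovisual", "auditory", "visual")
    )
    accuracies$accuracy <- ifelse(accuracies$group == names(n_subjects)[1],
                                  0.70, 0.85)
  }
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_nodes = as.integer(n_nodes), n_subjects = n_subjects,
              n_trials = as.integer(n_trials),
              n_samples = as.integer(n_samples), fs = fs,
              edges_per_condition = as.integer(edges_per_condition),
              n_multilink = as.integer(n_multilink),
              effect = effect, gamma = gamma, pte = pte,
              n_permutations = as.integer(n_permutations), q = q,
              alpha = alpha, pairing = pairing, accuracies = accuracies)
  structure(cfg, class = "pipeline_config")
}

subject_ids <- function(cfg) {
  unlist(lapply(names(cfg$n_subjects), function(g)
    sprintf("%s_%02d", g, seq_len(cfg$n_subjects[[g]]))), use.names = FALSE)
}

subject_seed <- function(cfg, i, stage) {
  (cfg$seed * 1009L + i * 9973L + stage * 101L) %% 2147483647L
}

write_manifest <- function(cfg, stage, extra = list()) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(list(stage = stage, seed = cfg$seed,
                     version = as.character(utils::packageVersion("ptenet")),
                     config = cfg[setdiff(names(cfg), c("pte", "accuracies"))],
                     pte = unclass(cfg$pte)),
                extra)
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir,
                                 sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}

#' Simulate all subjects of a configured experiment
#'
#' Writes one epoch-set directory per subject under
#' `<out_dir>/epochs/<subject>/` plus a ground-truth manifest.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the list of ground truths per group.
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  gt <- make_ground_truth(cfg$n_nodes, cfg$edges_per_condition,
                          cfg$n_multilink, cfg$effect, seed = cfg$seed,
                          gamma = cfg$gamma)
  ids <- subject_ids(cfg)
  for (i in seq_along(ids)) {
    es <- simulate_subject_epochs(gt, cfg$n_trials,
                                  n_samples = cfg$n_samples, fs = cfg$fs,
                                  seed = subject_seed(cfg, i, 1L),
                                  subject = ids[i])
    write_epoch_set(es, file.path(cfg$out_dir, "epochs", ids[i]))
  }
  write_manifest(cfg, "simulate",
                 list(subjects = ids,
                      multilink_edges = gt$multilink))
  invisible(gt)
}

#' Estimate PTE networks for all simulated subjects
#'
#' Reads each subject's epoch directory, computes single-trial PTE
#' matrices, and writes (a) the trial-averaged z-scored condition network
#' as labelled TSV under `<out_dir>/networks/` and (b) the per-trial
#' arrays (needed by the multilayer stage) as RDS under
#' `<out_dir>/trials/`.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, `NULL`.
#' @export
run_pte <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  ids <- subject_ids(cfg)
  dir.create(file.path(cfg$out_dir, "networks"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "trials"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in ids) {
    es <- read_epoch_set(file.path(cfg$out_dir, "epochs", id))
    for (cond in unique(es$condition)) {
      tr_idx <- which(es$condition == cond)
      mats <- lapply(tr_idx, function(k) {
        m <- pte_matrix(es$data[k, , ], es$fs, cfg$pte)
        attr(m, "bins") <- NULL
        m
      })
      arr <- simplify2array(mats)
      saveRDS(arr, file.path(cfg$out_dir, "trials",
                             sprintf("%s_%s.rds", id, cond)))
      cn <- condition_mean_z(mats, subject = id, condition = cond)
      rownames(cn$matrix) <- colnames(cn$matrix) <- es$node_labels
      write_matrix_tsv(cn$matrix,
                       file.path(cfg$out_dir, "networks",
                                 sprintf("%s_%s.tsv", id, cond)))
    }
  }
  write_manifest(cfg, "pte")
  invisible(NULL)
}

read_condition_networks <- function(cfg, ids, cond) {
  lapply(ids, function(id)
    read_matrix_tsv(file.path(cfg$out_dir, "networks",
                              sprintf("%s_%s.tsv", id, cond))))
}

#' Condition contrasts and group interaction on the PTE networks
#'
#' For each deviant condition: the paired standard-vs-deviant permutation
#' contrast within each group, and the group x condition interaction.
#' Writes each significant network's edge/node TSVs and a summary table
#' (contrast, condition, edges, nodes, density) mirroring the usual
#' network reporting.
#'
#' @param cfg A [pipeline_config()].
#' @return Tibble summarizing every contrast.
#' @export
run_contrasts <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  groups <- names(cfg$n_subjects)
  conds <- c("standard", "audiovisual", "auditory", "visual")
  deviants <- conds[-1]
  dir.create(file.path(cfg$out_dir, "contrasts"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- list()
  for (dev in deviants) {
    diffs_by_group <- list()
    for (g in groups) {
      ids <- grep(paste0("^", g), subject_ids(cfg), value = TRUE)
      std <- read_condition_networks(cfg, ids, "standard")
      dv <- read_condition_networks(cfg, ids, dev)
      design <- contrast_design("paired_condition",
                                n_permutations = cfg$n_permutations,
                                q = cfg$q, seed = cfg$seed)
      sn <- network_contrast(std, dv, design,
                             labels = rownames(std[[1]]))
      write_stat_network(sn, file.path(cfg$out_dir, "contrasts",
                                       sprintf("%s_%s", g, dev)))
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        glance(sn), contrast = paste0(g, ": standard vs ", dev),
        .before = 1)
      diffs_by_group[[g]] <- mapply(function(s, d) d - s, std, dv,
                                    SIMPLIFY = FALSE)
    }
    design_i <- contrast_design("group_interaction",
                                n_permutations = cfg$n_permutations,
                                q = cfg$q, seed = cfg$seed)
    sn_i <- interaction_contrast(diffs_by_group[[1]], diffs_by_group[[2]],
                                 design_i,
                                 labels = rownames(diffs_by_group[[1]][[1]]))
    write_stat_network(sn_i, file.path(cfg$out_dir, "contrasts",
                                       sprintf("interaction_%s", dev)))
    rows[[length(rows) + 1L]] <- dplyr::mutate(
      glance(sn_i), contrast = paste0("interaction: ", dev), .before = 1)
  }
  out <- dplyr::bind_rows(rows)
  utils::write.table(out, file.path(cfg$out_dir, "contrasts",
                                    "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Multilayer graphs, group tests and multilink summaries
#'
#' Builds each subject's multilayer graph (z-scored condition networks on
#' the diagonal, thresholded cross-condition edge correlations off it),
#' runs the one-sample group tests and the between-group contrast, and
#' writes the graphs and significant networks.
#'
#' @param cfg A [pipeline_config()].
#' @return List with the per-group `multilayer_stat`s, the two group
#'   difference contrasts, and a block-level edge-count summary tibble.
#' @export
run_multilayer_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  conds <- c("standard", "audiovisual", "auditory", "visual")
  groups <- names(cfg$n_subjects)
  dir.create(file.path(cfg$out_dir, "multilayer"), recursive = TRUE,
             showWarnings = FALSE)
  graphs <- list()
  for (id in subject_ids(cfg)) {
    trials <- lapply(conds, function(cond)
      readRDS(file.path(cfg$out_dir, "trials",
                        sprintf("%s_%s.rds", id, cond))))
    names(trials) <- conds
    nets <- lapply(conds, function(cond)
      condition_mean_z(trials[[cond]], subject = id, condition = cond))
    names(nets) <- conds
    pairs <- list()
    for (a in seq_len(length(conds) - 1L)) for (b in (a + 1L):length(conds)) {
      key <- paste(conds[a], conds[b], sep = "|")
      pairs[[key]] <- edge_condition_correlation(
        trials[[conds[a]]], trials[[conds[b]]], alpha = cfg$alpha,
        pairing = cfg$pairing, seed = cfg$seed,
        pair = c(conds[a], conds[b]))
    }
    g <- assemble_multilayer(nets, pairs, subject = id)
    graphs[[id]] <- g
    write_multilayer_graph(g, file.path(cfg$out_dir, "multilayer", id))
  }
  design1 <- contrast_design("one_sample",
                             n_permutations = cfg$n_permutations,
                             q = cfg$q, seed = cfg$seed)
  by_group <- lapply(groups, function(g)
    group_one_sample_graph_test(
      graphs[grep(paste0("^", g), names(graphs))], design1))
  names(by_group) <- groups
  design2 <- contrast_design("two_sample",
                             n_permutations = cfg$n_permutations,
                             q = cfg$q, seed = cfg$seed)
  diff <- group_difference_graph_test(
    graphs[grep(paste0("^", groups[1]), names(graphs))],
    graphs[grep(paste0("^", groups[2]), names(graphs))], design2)

  summary <- dplyr::bind_rows(lapply(groups, function(g) {
    ms <- by_group[[g]]
    dplyr::bind_rows(lapply(pair_keys(conds), function(key) {
      ab <- strsplit(key, "|", fixed = TRUE)[[1]]
      blk <- multilayer_block(ms$mask, ms$states, ms$n_nodes,
                              ab[1], ab[2])
      tibble::tibble(group = g, block = key,
                     edges = sum(blk),
                     nodes = sum(rowSums(blk) + colSums(blk) > 0),
                     density = mean(blk))
    }))
  }))
  utils::write.table(summary,
                     file.path(cfg$out_dir, "multilayer", "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in groups)
    write_stat_network(by_group[[g]]$network,
                       file.path(cfg$out_dir, "multilayer",
                                 paste0("onesample_", g)))
  write_manifest(cfg, "multilayer")
  list(by_group = by_group, difference = diff, summary = summary)
}

#' Behavioral stage of the pipeline
#'
#' Simulates per-subject 2AFC counts from the configured accuracies and
#' runs the full behavioral analysis, writing the results tables.
#'
#' @param cfg A [pipeline_config()].
#' @return The [analyze_behavior()] result list.
#' @export
run_behavioral_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  tab <- simulate_behavior(cfg$accuracies, n_trials = 12L,
                           n_subjects_per_group = cfg$n_subjects,
                           seed = cfg$seed + 7L)
  res <- analyze_behavior(tab)
  dir.create(file.path(cfg$out_dir, "behavior"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.table(tab, file.path(cfg$out_dir, "behavior", "table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$chance_tests,
                     file.path(cfg$out_dir, "behavior", "chance_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$anova,
                     file.path(cfg$out_dir, "behavior", "anova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "behavior")
  res
}
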