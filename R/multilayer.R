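#' Cross-condition edge-to-edge correlation (multilink) matrix
#'
#' For every directed edge (i, j), the Pearson correlation over paired
#' trials between the edge's single-trial PTE values in condition A and in
#' condition B, thresholded by the two-sided t test
#' `t = r * sqrt((n - 2) / (1 - r^2))` at `alpha`. Positive and negative
#' significant correlations are both retained; everything else is 0.
#'
#' Trials are paired by chronological index after truncating both
#' conditions to the common trial count; `pairing = "random"` instead
#' pairs a seeded random permutation (for sensitivity analysis).
#'
#' @param trialsA,trialsB Single-trial edge matrices per condition:
#'   N x N x trials arrays (or lists of N x N matrices).
#' @param alpha Per-edge two-sided significance level (default 0.05).
#' @param pairing `"chronological"` (default) or `"random"`.
#' @param seed Seed for random pairing (required when
#'   `pairing = "random"`).
#' @param pair Optional length-2 character naming the two conditions.
#' @return A `multilink_matrix`: `matrix` (thresholded r), `pair`,
#'   `alpha`, `n_pairs`.
#' @export
edge_condition_correlation <- function(trialsA, trialsB, alpha = 0.05,
                                       pairing = c("chronological",
                                                   "random"),
                                       seed = NULL, pair = c("A", "B")) {
  pairing <- match.arg(pairing)
  a <- as_trial_matrix(trialsA)
  b <- as_trial_matrix(trialsB)
  if (a$n_nodes != b$n_nodes)
    stop("conditions must share the node set", call. = FALSE)
  n <- min(nrow(a$data), nrow(b$data))
  if (n < 4L) stop("need at least 4 paired trials", call. = FALSE)
  A <- a$data[seq_len(n), , drop = FALSE]
  B <- b$data[seq_len(n), , drop = FALSE]
  if (pairing == "random") {
    if (is.null(seed)) stop("random pairing needs a `seed`", call. = FALSE)
    withr::local_seed(seed)
    B <- B[sample.int(n), , drop = FALSE]
  }
  ca <- sweep(A, 2, colMeans(A))
  cb <- sweep(B, 2, colMeans(B))
  sa <- sqrt(colSums(ca^2))
  sb <- sqrt(colSums(cb^2))
  denom <- sa * sb
  r <- colSums(ca * cb) / ifelse(denom > 0, denom, Inf)
  if (any(denom[offdiag_vec(a$n_nodes)] == 0))
    warning("constant edge series; correlation set to 0", call. = FALSE)
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  r[p > alpha] <- 0
  m <- matrix(r, a$n_nodes, a$n_nodes)
  diag(m) <- 0
  structure(list(matrix = m, pair = pair, alpha = alpha, n_pairs = n),
            class = "multilink_matrix")
}

as_trial_matrix <- function(x) {
  if (is.list(x) && !is.array(x))
    x <- simplify2array(x)
  if (!(is.array(x) && length(dim(x)) == 3L))
    stop("expected an N x N x trials array or list of matrices",
         call. = FALSE)
  n <- dim(x)[1]
  list(data = t(apply(x, 3, as.numeric)), n_nodes = n)
}

offdiag_vec <- function(n) as.vector(row(diag(n)) != col(diag(n)))

#' @export
print.multilink_matrix <- function(x, ...) {
  cat("<multilink_matrix> ", paste(x$pair, collapse = " ~ "), ": ",
      sum(x$matrix != 0), " significant edge correlations (alpha ",
      x$alpha, ", ", x$n_pairs, " trial pairs)\n", sep = "")
  invisible(x)
}

#' Assemble a multilayer task-state graph
#'
#' Places the K z-scored condition networks on the block diagonal and the
#' K(K-1)/2 multilink matrices on the off-diagonal blocks; block (b, a)
#' mirrors block (a, b) entrywise, since the edge-wise correlation is a
#' single number per directed edge, symmetric in condition order.
#'
#' @param condition_nets Named list of K `condition_network`s (or plain
#'   z-scored matrices), in state order.
#' @param pair_mats Named list of `multilink_matrix` objects (or plain
#'   matrices), one per unordered state pair, named `"a|b"` with `a`
#'   before `b` in state order.
#' @param subject Optional subject identifier.
#' @return A `multilayer_graph`: `matrix` ((K N) x (K N)), `states`,
#'   `n_nodes`, `subject`.
#' @export
assemble_multilayer <- function(condition_nets, pair_mats,
                                subject = NA_character_) {
  states <- names(condition_nets)
  if (is.null(states)) stop("`condition_nets` must be named", call. = FALSE)
  mats <- lapply(condition_nets, function(x)
    if (inherits(x, "condition_network")) x$matrix else x)
  n <- unique(vapply(mats, nrow, 1L))
  if (length(n) != 1L) stop("inconsistent node counts", call. = FALSE)
  K <- length(states)
  pm <- lapply(pair_mats, function(x)
    if (inherits(x, "multilink_matrix")) x$matrix else x)
  need <- pair_keys(states)
  missing <- setdiff(need, names(pm))
  if (length(missing))
    stop("missing multilink block(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(vapply(pm[need], function(m) all(dim(m) == c(n, n)), TRUE)))
    stop("multilink block shape mismatch", call. = FALSE)

  big <- matrix(0, K * n, K * n)
  blk <- function(k) ((k - 1L) * n + 1L):(k * n)
  for (k in seq_len(K)) big[blk(k), blk(k)] <- mats[[k]]
  for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
    m <- pm[[paste(states[a], states[b], sep = "|")]]
    big[blk(a), blk(b)] <- m
    big[blk(b), blk(a)] <- m
  }
  labels <- as.character(outer(sprintf("node%03d", seq_len(n)), states,
                               function(nd, st) paste(st, nd, sep = ".")))
  dimnames(big) <- list(labels, labels)
  structure(list(matrix = big, states = states, n_nodes = n,
                 subject = subject),
            class = "multilayer_graph")
}

pair_keys <- function(states) {
  K <- length(states)
  unlist(lapply(seq_len(K - 1L), function(a)
    paste(states[a], states[(a + 1L):K], sep = "|")))
}

#' @export
print.multilayer_graph <- function(x, ...) {
  cat("<multilayer_graph> ", length(x$states), " states x ", x$n_nodes,
      " nodes = ", nrow(x$matrix), " x ", ncol(x$matrix), " (subject ",
      x$subject, ")\n", sep = "")
  invisible(x)
}

#' One-sample permutation test on a group of multilayer graphs
#'
#' Entrywise one-sample t across subjects against 0, sign-flip permutation
#' p-values, BH-FDR at `design$q`. Returns the significant graph as a
#' `multilayer_stat` (a `stat_network` over the K N multilayer nodes plus
#' the state layout).
#'
#' @param graphs List of per-subject `multilayer_graph`s sharing layout.
#' @param design A [contrast_design()] with scheme `"one_sample"`.
#' @return A `multilayer_stat` object.
#' @export
group_one_sample_graph_test <- function(graphs, design) {
  stopifnot(length(graphs) >= 3L)
  lay <- graph_layout(graphs)
  D <- do.call(rbind, lapply(graphs, function(g) as.numeric(g$matrix)))
  # all-zero entries (thresholded multilinks) are routine here: no warning
  es <- edge_stats_from_diffs(D, lay$side, "one_sample",
                              warn_zero_var = FALSE)
  p <- permutation_pvalues(es, design)
  mask <- fdr_bh(p, design$q)
  sn <- significant_network(es$t, p, mask, labels = lay$labels,
                            meta = list(q = design$q,
                                        n_permutations = design$n_permutations,
                                        seed = design$seed,
                                        correction = "BH"))
  structure(list(network = sn, states = lay$states, n_nodes = lay$n,
                 mask = mask, t = es$t),
            class = "multilayer_stat")
}

graph_layout <- function(graphs) {
  states <- unique(lapply(graphs, function(g) g$states))
  n <- unique(vapply(graphs, function(g) g$n_nodes, 1L))
  if (length(states) != 1L || length(n) != 1L)
    stop("graphs must share states and node count", call. = FALSE)
  list(states = states[[1]], n = n,
       side = length(states[[1]]) * n,
       labels = rownames(graphs[[1]]$matrix))
}

#' Between-group permutation test on multilayer graphs
#'
#' Entrywise two-sample t between groups with group-label permutations and
#' BH-FDR; significant entries are split by sign into the two one-sided
#' contrasts (A greater, B greater).
#'
#' @param graphsA,graphsB Lists of per-subject `multilayer_graph`s.
#' @param design A [contrast_design()] with scheme `"two_sample"`.
#' @return List with `a_gt_b` and `b_gt_a` `multilayer_stat` objects.
#' @export
group_difference_graph_test <- function(graphsA, graphsB, design) {
  stopifnot(length(graphsA) >= 3L, length(graphsB) >= 3L)
  lay <- graph_layout(c(graphsA, graphsB))
  A <- do.call(rbind, lapply(graphsA, function(g) as.numeric(g$matrix)))
  B <- do.call(rbind, lapply(graphsB, function(g) as.numeric(g$matrix)))
  tvec <- col_t_twosample(A, B)
  tm <- matrix(tvec, lay$side, lay$side)
  diag(tm) <- 0
  es <- structure(list(t = tm, f = tm^2, data = list(A = A, B = B),
                       n_nodes = lay$side, scheme = "two_sample"),
                  class = "edge_stats")
  p <- permutation_pvalues(es, design)
  mask <- fdr_bh(p, design$q)
  meta <- list(q = design$q, n_permutations = design$n_permutations,
               seed = design$seed, correction = "BH")
  side <- function(keep) {
    m <- mask & keep
    sn <- significant_network(es$t, p, m, labels = lay$labels, meta = meta)
    structure(list(network = sn, states = lay$states, n_nodes = lay$n,
                   mask = m, t = es$t),
              class = "multilayer_stat")
  }
  list(a_gt_b = side(es$t > 0), b_gt_a = side(es$t < 0))
}

#' @export
print.multilayer_stat <- function(x, ...) {
  cat("<multilayer_stat> ", nrow(x$network$edges),
      " significant entries over ", length(x$states), " states x ",
      x$n_nodes, " nodes\n", sep = "")
  invisible(x)
}

# Extract one N x N block of a multilayer matrix/mask.
multilayer_block <- function(mat, states, n, a, b) {
  ia <- match(a, states); ib <- match(b, states)
  if (is.na(ia) || is.na(ib)) stop("unknown state pair", call. = FALSE)
  blk <- function(k) ((k - 1L) * n + 1L):(k * n)
  mat[blk(ia), blk(ib)]
}

#' Node degree within one between-state block
#'
#' Counts, for each region, the significant entries of the chosen
#' between-state block whose row or column is that region -- the number of
#' multilinks the region participates in for that state pair.
#'
#' @param ms A `multilayer_stat` (or a logical/numeric (K N) x (K N)
#'   matrix with `states` and `n_nodes` supplied).
#' @param pair Length-2 character: the state pair.
#' @param states,n_nodes Layout, only needed when `ms` is a plain matrix.
#' @return Tibble (node, degree).
#' @export
between_block_node_degree <- function(ms, pair, states = NULL,
                                      n_nodes = NULL) {
  if (inherits(ms, "multilayer_stat")) {
    mask <- ms$mask; states <- ms$states; n_nodes <- ms$n_nodes
  } else mask <- ms != 0
  blk <- multilayer_block(mask, states, n_nodes, pair[1], pair[2]) != 0
  deg <- rowSums(blk) + colSums(blk)
  tibble::tibble(node = sprintf("node%03d", seq_len(n_nodes)),
                 degree = as.integer(deg))
}

#' Connected components of a multilink block
#'
#' Components of the undirected graph induced by the nonzero entries of a
#' thresholded edge-to-edge correlation block; each component is one
#' multilink.
#'
#' @param block_mask N x N matrix (nonzero entries are links).
#' @return List with `n_components`, `membership` (per node involved),
#'   and `components` (list of tibbles with the member nodes and the
#'   entries joining them).
#' @export
multilink_components <- function(block_mask) {
  idx <- which(block_mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(list(n_components = 0L, membership = integer(0),
                components = list()))
  g <- igraph::graph_from_edgelist(
    cbind(as.character(idx[, 1]), as.character(idx[, 2])),
    directed = FALSE
  )
  comp <- igraph::components(g)
  nodes <- as.integer(igraph::V(g)$name)
  comps <- lapply(seq_len(comp$no), function(k) {
    members <- nodes[comp$membership == k]
    keep <- idx[, 1] %in% members | idx[, 2] %in% members
    tibble::tibble(nodes = list(sort(members)),
                   entries = list(idx[keep, , drop = FALSE]))
  })
  list(n_components = comp$no,
       membership = stats::setNames(comp$membership, nodes),
       components = comps)
}

#' Links common to every block
#'
#' @param blocks List of equally shaped matrices or masks.
#' @return Logical matrix: entries nonzero in every input.
#' @export
common_links <- function(blocks) {
  shapes <- unique(lapply(blocks, dim))
  if (length(shapes) != 1L) stop("shape mismatch", call. = FALSE)
  Reduce(`&`, lapply(blocks, function(b) b != 0))
}
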