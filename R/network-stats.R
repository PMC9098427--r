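#' Design of a permutation contrast
#'
#' @param scheme One of `"paired_condition"`, `"group_interaction"`,
#'   `"one_sample"`, `"two_sample"`.
#' @param n_permutations Number of random permutations (>= 100;
#'   default 10000).
#' @param q FDR level for the Benjamini--Hochberg correction
#'   (default 0.001).
#' @param seed Integer seed driving the permutation draws.
#' @return A `contrast_design` list.
#' @examples
#' contrast_design("paired_condition", n_permutations = 1000, seed = 1)
#' @export
contrast_design <- function(scheme = c("paired_condition",
                                       "group_interaction",
                                       "one_sample", "two_sample"),
                            n_permutations = 10000L, q = 0.001, seed = 1L) {
  scheme <- match.arg(scheme)
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 100L)
    stop("`n_permutations` must be >= 100", call. = FALSE)
  if (q <= 0 || q >= 1) stop("`q` must lie in (0, 1)", call. = FALSE)
  structure(list(scheme = scheme, n_permutations = n_permutations,
                 q = q, seed = as.integer(seed)),
            class = "contrast_design")
}

# Coerce a per-subject collection of networks into a subjects x entries
# matrix (full vectorized N x N layout, column-major).
as_subject_matrix <- function(x) {
  if (is.list(x) && !is.array(x))
    x <- lapply(x, function(m)
      if (inherits(m, c("condition_network", "multilink_matrix")))
        m$matrix else m)
  if (is.array(x) && length(dim(x)) == 3L)
    x <- lapply(seq_len(dim(x)[3]), function(k) x[, , k])
  n <- unique(vapply(x, nrow, 1L))
  if (length(n) != 1L) stop("inconsistent matrix sizes", call. = FALSE)
  list(data = do.call(rbind, lapply(x, as.numeric)), n_nodes = n)
}

col_t_onesample <- function(D, mu0 = 0) {
  s <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - s * m^2) / (s - 1)
  v[v < 0] <- 0
  t <- (m - mu0) / sqrt(v / s)
  t[!is.finite(t)] <- 0
  t
}

col_t_twosample <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  sp2 <- (colSums(A^2) - na * ma^2 + colSums(B^2) - nb * mb^2) /
    (na + nb - 2)
  sp2[sp2 < 0] <- 0
  t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  t[!is.finite(t)] <- 0
  t
}

#' Paired edge statistics between two conditions
#'
#' For each directed edge, a paired t statistic across subjects on
#' (deviant - standard), plus its squared (F) form. Zero-variance edges
#' yield statistic 0 with one warning.
#'
#' @param standard,deviant Per-subject networks in matching subject order:
#'   lists of N x N matrices (or `condition_network`s) or N x N x S arrays.
#' @return An `edge_stats` object: `t` and `f` matrices, the per-subject
#'   difference data, and `scheme = "paired_condition"`.
#' @export
paired_edge_stats <- function(standard, deviant) {
  s <- as_subject_matrix(standard)
  d <- as_subject_matrix(deviant)
  if (s$n_nodes != d$n_nodes || nrow(s$data) != nrow(d$data))
    stop("standard and deviant must cover the same subjects and nodes",
         call. = FALSE)
  if (nrow(s$data) < 3L) stop("need at least 3 subjects", call. = FALSE)
  diffs <- d$data - s$data
  edge_stats_from_diffs(diffs, s$n_nodes, "paired_condition")
}

edge_stats_from_diffs <- function(diffs, n_nodes, scheme,
                                  warn_zero_var = TRUE) {
  tvec <- col_t_onesample(diffs)
  if (warn_zero_var) {
    v <- colSums(sweep(diffs, 2, colMeans(diffs))^2)
    if (any(v[offdiag_vec(n_nodes)] == 0))
      warning("zero-variance edge(s); statistic set to 0", call. = FALSE)
  }
  tm <- matrix(tvec, n_nodes, n_nodes)
  diag(tm) <- 0
  structure(list(t = tm, f = tm^2, data = diffs, n_nodes = n_nodes,
                 scheme = scheme),
            class = "edge_stats")
}

#' Group-by-condition interaction statistics per edge
#'
#' Two-sample t statistic between groups on per-subject condition
#' difference matrices (deviant - standard); its square is the interaction
#' F of the 2 x 2 mixed design.
#'
#' @param groupA_diffs,groupB_diffs Per-subject difference networks
#'   (lists of N x N matrices or N x N x S arrays), one entry per subject.
#' @return An `edge_stats` object with `scheme = "group_interaction"`.
#' @export
interaction_edge_stats <- function(groupA_diffs, groupB_diffs) {
  a <- as_subject_matrix(groupA_diffs)
  b <- as_subject_matrix(groupB_diffs)
  if (a$n_nodes != b$n_nodes)
    stop("groups must share the node set", call. = FALSE)
  if (nrow(a$data) < 3L || nrow(b$data) < 3L)
    stop("need at least 3 subjects per group", call. = FALSE)
  tvec <- col_t_twosample(a$data, b$data)
  pooled <- rbind(sweep(a$data, 2, colMeans(a$data)),
                  sweep(b$data, 2, colMeans(b$data)))
  if (any(colSums(pooled^2)[offdiag_vec(a$n_nodes)] == 0))
    warning("zero-variance edge(s); statistic set to 0", call. = FALSE)
  tm <- matrix(tvec, a$n_nodes, a$n_nodes)
  diag(tm) <- 0
  structure(list(t = tm, f = tm^2, data = list(A = a$data, B = b$data),
                 n_nodes = a$n_nodes, scheme = "group_interaction"),
            class = "edge_stats")
}

#' Permutation p-values for edge statistics
#'
#' Sign-flip permutations (paired / one-sample schemes) or group-label
#' permutations (two-sample / interaction schemes) of the subject data,
#' recomputing the t statistic for every permutation. The p-value uses the
#' add-one estimator `(1 + #{|t_perm| >= |t_obs|}) / (1 + n_permutations)`
#' and is therefore never zero. Deterministic given `design$seed`.
#'
#' @param es An `edge_stats` object (from [paired_edge_stats()],
#'   [interaction_edge_stats()], or the multilayer tests).
#' @param design A [contrast_design()]; its scheme class (sign-flip vs
#'   label permutation) must match the statistic's.
#' @return Matrix of p-values shaped like `es$t` (diagonal 1).
#' @export
permutation_pvalues <- function(es, design) {
  stopifnot(inherits(es, "edge_stats"), inherits(design, "contrast_design"))
  signflip <- design$scheme %in% c("paired_condition", "one_sample")
  labelperm <- design$scheme %in% c("group_interaction", "two_sample")
  if (signflip && !is.matrix(es$data))
    stop("sign-flip scheme requires per-subject difference data",
         call. = FALSE)
  if (labelperm && !is.list(es$data))
    stop("label-permutation scheme requires two groups of data",
         call. = FALSE)
  withr::local_seed(design$seed)
  P <- design$n_permutations
  obs <- abs(as.numeric(es$t))
  # tie threshold: permuted statistics equal to the observed one (e.g. the
  # identity sign flip) must count as exceedances despite floating noise
  thr <- obs * (1 - 1e-9) - 1e-12
  exceed <- numeric(length(obs))
  chunk <- max(1L, min(P, as.integer(2e7 / length(obs))))

  if (signflip) {
    D <- es$data
    s <- nrow(D)
    ss <- colSums(D^2)
    done <- 0L
    while (done < P) {
      k <- min(chunk, P - done)
      signs <- matrix(sample(c(-1, 1), k * s, replace = TRUE), k, s)
      m <- signs %*% D / s
      v <- sweep(-s * m^2, 2, ss, `+`) / (s - 1)
      v[v < 0] <- 0
      tp <- abs(m / sqrt(v / s))
      tp[!is.finite(tp)] <- 0
      exceed <- exceed + colSums(sweep(tp, 2, thr, `>=`))
      done <- done + k
    }
  } else {
    X <- rbind(es$data$A, es$data$B)
    na <- nrow(es$data$A); nb <- nrow(es$data$B)
    s <- na + nb
    tot <- colSums(X); totsq <- colSums(X^2)
    done <- 0L
    while (done < P) {
      k <- min(chunk, P - done)
      ind <- matrix(0, k, s)
      for (r in seq_len(k)) ind[r, sample.int(s, na)] <- 1
      sa <- ind %*% X
      sqa <- ind %*% X^2
      ma <- sa / na
      mb <- sweep(-sa, 2, tot, `+`) / nb
      sp2 <- (sqa - na * ma^2 +
                sweep(-sqa, 2, totsq, `+`) - nb * mb^2) / (s - 2)
      sp2[sp2 < 0] <- 0
      tp <- abs((ma - mb) / sqrt(sp2 * (1 / na + 1 / nb)))
      tp[!is.finite(tp)] <- 0
      exceed <- exceed + colSums(sweep(tp, 2, thr, `>=`))
      done <- done + k
    }
  }
  p <- matrix((1 + exceed) / (1 + P), es$n_nodes, es$n_nodes)
  diag(p) <- 1
  p
}

#' Benjamini--Hochberg significance mask
#'
#' Step-up FDR control: sort p ascending, find the largest i with
#' `p_(i) <= i * q / m`, reject all ranked at or below it. For a square
#' matrix the family is the off-diagonal entries (the diagonal is
#' structural and never tested).
#'
#' @param pvals Numeric vector or square matrix of p-values in [0, 1].
#' @param q FDR level in (0, 1).
#' @return Logical mask of the same shape (`FALSE` on a matrix diagonal).
#' @examples
#' fdr_bh(c(0.001, 0.02, 0.03, 0.04), q = 0.05)
#' @export
fdr_bh <- function(pvals, q) {
  if (q <= 0 || q >= 1) stop("`q` must lie in (0, 1)", call. = FALSE)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (is.matrix(pvals)) {
    off <- row(pvals) != col(pvals)
    mask <- matrix(FALSE, nrow(pvals), ncol(pvals))
    mask[off] <- p.adjust(pvals[off], method = "BH") <= q
    return(mask)
  }
  p.adjust(pvals, method = "BH") <= q
}

#' Assemble a significant network with node summaries
#'
#' Retains masked edges with their statistics and p-values and computes
#' the standard graph summaries: node strength (sum of |statistic| over
#' incident significant edges), node degree (incident edge count, in plus
#' out), and density (edges over N(N-1) ordered pairs).
#'
#' @param stats Matrix of edge statistics (e.g. t values).
#' @param pvals Matrix of p-values.
#' @param mask Logical significance mask.
#' @param labels Optional node labels (default `node001`, ...).
#' @param meta Optional named list recorded as `threshold_meta`.
#' @return A `stat_network`: edges and nodes tibbles, density, n_nodes.
#' @export
significant_network <- function(stats, pvals, mask, labels = NULL,
                                meta = list()) {
  stopifnot(all(dim(stats) == dim(pvals)), all(dim(stats) == dim(mask)))
  n <- nrow(stats)
  if (is.null(labels)) labels <- sprintf("node%03d", seq_len(n))
  idx <- which(mask, arr.ind = TRUE)
  edges <- tibble::tibble(
    source = labels[idx[, 1]], target = labels[idx[, 2]],
    statistic = stats[idx], p_value = pvals[idx]
  )
  strength <- degree <- stats::setNames(numeric(n), labels)
  if (nrow(idx)) {
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      a <- abs(stats[i, j])
      strength[i] <- strength[i] + a
      strength[j] <- strength[j] + a
      degree[i] <- degree[i] + 1
      degree[j] <- degree[j] + 1
    }
  }
  structure(
    list(
      edges = edges,
      nodes = tibble::tibble(node = labels, strength = unname(strength),
                             degree = as.integer(unname(degree))),
      density = nrow(edges) / (n * (n - 1)),
      n_nodes = n,
      threshold_meta = meta
    ),
    class = "stat_network"
  )
}

#' @export
print.stat_network <- function(x, ...) {
  cat("<stat_network> ", nrow(x$edges), " significant edges among ",
      x$n_nodes, " nodes (density ",
      formatC(x$density, format = "g", digits = 3), ")\n", sep = "")
  invisible(x)
}

#' One-sample permutation test on a stack of per-subject networks
#'
#' Entrywise one-sample t across subjects against zero, sign-flip
#' permutation p-values, and BH-FDR at `design$q`. This is the building
#' block of the multilayer group tests and can be applied directly to any
#' per-subject matrix collection -- e.g. the multilink matrices of one
#' condition pair (a single between-state block).
#'
#' @param networks Per-subject matrices (list of N x N or N x N x S
#'   array).
#' @param design A [contrast_design()] with scheme `"one_sample"`.
#' @param labels Optional node labels.
#' @return A `stat_network`.
#' @export
one_sample_network_test <- function(networks, design, labels = NULL) {
  x <- as_subject_matrix(networks)
  if (nrow(x$data) < 3L) stop("need at least 3 subjects", call. = FALSE)
  es <- edge_stats_from_diffs(x$data, x$n_nodes, "one_sample",
                              warn_zero_var = FALSE)
  p <- permutation_pvalues(es, design)
  mask <- fdr_bh(p, design$q)
  significant_network(es$t, p, mask, labels = labels,
                      meta = list(q = design$q,
                                  n_permutations = design$n_permutations,
                                  seed = design$seed, correction = "BH"))
}

#' Paired condition contrast with permutation FDR control
#'
#' Convenience chain: [paired_edge_stats()] on standard vs deviant
#' networks, [permutation_pvalues()] under subject sign flips,
#' [fdr_bh()] at `design$q`, and [significant_network()].
#'
#' @inheritParams paired_edge_stats
#' @param design A [contrast_design()] with a sign-flip scheme.
#' @param labels Optional node labels.
#' @return A `stat_network`.
#' @export
network_contrast <- function(standard, deviant, design, labels = NULL) {
  es <- paired_edge_stats(standard, deviant)
  p <- permutation_pvalues(es, design)
  mask <- fdr_bh(p, design$q)
  significant_network(es$t, p, mask, labels = labels,
                      meta = list(q = design$q,
                                  n_permutations = design$n_permutations,
                                  seed = design$seed, correction = "BH"))
}

#' Group-by-condition interaction contrast
#'
#' @param groupA_diffs,groupB_diffs Per-subject (deviant - standard)
#'   difference networks for the two groups.
#' @param design A [contrast_design()] with a label-permutation scheme.
#' @param labels Optional node labels.
#' @return A `stat_network`.
#' @export
interaction_contrast <- function(groupA_diffs, groupB_diffs, design,
                                 labels = NULL) {
  es <- interaction_edge_stats(groupA_diffs, groupB_diffs)
  p <- permutation_pvalues(es, design)
  mask <- fdr_bh(p, design$q)
  significant_network(es$t, p, mask, labels = labels,
                      meta = list(q = design$q,
                                  n_permutations = design$n_permutations,
                                  seed = design$seed, correction = "BH"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname significant_network
#' @param x A `stat_network`.
#' @param ... Unused.
tidy.stat_network <- function(x, ...) x$edges

#' @export
#' @rdname significant_network
glance.stat_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = x$n_nodes,
    n_edges = nrow(x$edges),
    n_active_nodes = sum(x$nodes$degree > 0),
    density = x$density,
    q = x$threshold_meta$q %||% NA_real_,
    n_permutations = x$threshold_meta$n_permutations %||% NA_integer_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
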