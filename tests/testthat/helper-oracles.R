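# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive every quantity from first principles and
# never call the code paths they check.

# Transfer entropy from explicit joint-probability tables: bins phases,
# accumulates the full 3-way histogram, and sums entropies with a triple
# loop over cells.
oracle_pte <- function(phase_x, phase_y, delay, bins) {
  m <- length(phase_y) - delay
  to_bin <- function(ph) {
    b <- floor((ph + pi) / (2 * pi) * bins)
    pmin(pmax(b, 0), bins - 1) + 1
  }
  yf <- to_bin(phase_y[(1 + delay):(m + delay)])
  yp <- to_bin(phase_y[1:m])
  xp <- to_bin(phase_x[1:m])
  p3 <- array(0, c(bins, bins, bins))
  for (t in 1:m) p3[yf[t], yp[t], xp[t]] <- p3[yf[t], yp[t], xp[t]] + 1
  p3 <- p3 / m

  ent <- function(p) {
    h <- 0
    for (v in p) if (v > 0) h <- h - v * log(v)
    h
  }
  p_yfyp <- apply(p3, c(1, 2), sum)
  p_ypxp <- apply(p3, c(2, 3), sum)
  p_yp <- apply(p3, 2, sum)
  ent(p_yfyp) - ent(p_yp) - ent(p3) + ent(p_ypxp)
}

# Benjamini-Hochberg step-up straight from its definition.
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  thresh <- (1:m) * q / m
  k <- suppressWarnings(max(which(ps <= thresh)))
  mask <- logical(m)
  if (is.finite(k)) mask[ord[1:k]] <- TRUE
  mask
}

# Exhaustive sign-flip permutation p-values for a one-sample t on a
# subjects x entries matrix (all 2^n sign assignments).
oracle_signflip_exhaustive <- function(D) {
  s <- nrow(D)
  tstat <- function(M) {
    m <- colMeans(M)
    v <- apply(M, 2, var)
    t <- m / sqrt(v / s)
    t[!is.finite(t)] <- 0
    t
  }
  obs <- abs(tstat(D))
  total <- 2^s
  exceed <- numeric(ncol(D))
  for (code in 0:(total - 1)) {
    signs <- ifelse(bitwAnd(code, 2^(0:(s - 1))) > 0, 1, -1)
    exceed <- exceed + (abs(tstat(D * signs)) >= obs)
  }
  exceed / total
}

# Connected components by union-find over the nodes touched by nonzero
# entries of a mask.
oracle_components <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(n = 0, membership = integer(0)))
  nodes <- sort(unique(c(idx[, 1], idx[, 2])))
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (r in seq_len(nrow(idx))) {
    a <- find(match(idx[r, 1], nodes))
    b <- find(match(idx[r, 2], nodes))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(nodes), find, 1L)
  list(n = length(unique(roots)),
       membership = stats::setNames(match(roots, unique(roots)), nodes))
}

# Classical mixed-design (one between, one within factor) sums of squares
# computed by explicit cell-mean formulas; requires equal group sizes.
oracle_mixed_anova <- function(values, subject, group, modality) {
  G <- mean(values)
  K <- length(unique(modality))
  subj_means <- tapply(values, subject, mean)
  subj_group <- tapply(as.character(group), subject, unique)
  grp_means <- tapply(values, group, mean)
  mod_means <- tapply(values, modality, mean)
  n_per_group <- table(subj_group)

  ss_between_subj <- K * sum((subj_means - G)^2)
  ss_group <- K * sum(n_per_group * (grp_means[names(n_per_group)] - G)^2)
  ss_subj_within <- ss_between_subj - ss_group

  ss_within_total <- sum((values - subj_means[as.character(subject)])^2)
  n_subj <- length(unique(subject))
  ss_modality <- n_subj * sum((mod_means - G)^2)
  cell_means <- tapply(values, list(group, modality), mean)
  ss_cells <- 0
  for (g in rownames(cell_means)) for (m in colnames(cell_means)) {
    ss_cells <- ss_cells + n_per_group[[g]] *
      (cell_means[g, m] - grp_means[[g]] - mod_means[[m]] + G)^2
  }
  ss_resid <- ss_within_total - ss_modality - ss_cells

  n_groups <- length(unique(group))
  df_int <- (K - 1) * (n_groups - 1)
  df_resid <- (K - 1) * (n_subj - n_groups)
  list(
    F_group = (ss_group / (n_groups - 1)) /
      (ss_subj_within / (n_subj - n_groups)),
    F_modality = (ss_modality / (K - 1)) / (ss_resid / df_resid),
    F_interaction = (ss_cells / df_int) / (ss_resid / df_resid),
    df_int = c(df_int, df_resid),
    eta_interaction = ss_cells / (ss_cells + ss_resid)
  )
}

# Small ground truth with one fixed directed edge 1 -> 2 (three nodes so
# the constructor's minimum holds; node 3 stays uncoupled).
unidirectional_gt <- function(seed, strength = 1, ...) {
  make_ground_truth(
    3, 1, 0, 0, seed = seed,
    edges = data.frame(source = 1L, target = 2L, strength = strength),
    trial_modulation_sd = 0,  # a fixed, constant coupling
    ...
  )
}
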