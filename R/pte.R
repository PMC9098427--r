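#' Configuration for phase-transfer-entropy estimation
#'
#' Bundles the estimator settings used throughout the connectivity stage:
#' the prediction delay (in samples), the embedding length of the target's
#' past, the analysis band for phase extraction, and the histogram bin rule.
#'
#' @param delay Positive integer; how many samples ahead the target's future
#'   phase lies, and how far back the source's past is taken. Default 10.
#' @param embedding_k Length of the target's past history. Only `1` is
#'   supported (single past sample), which is also the default.
#' @param band Numeric length-2, Hz: the passband applied during analytic
#'   phase extraction. Default `c(2, 60)`.
#' @param bin_rule Name of the bin-count rule; only `"scott"` (the
#'   Nason--Scott normal-reference width) is available.
#' @param bins_override Optional integer; if given, used verbatim as the
#'   number of phase bins instead of the rule.
#' @return An object of class `pte_config`.
#' @examples
#' pte_config()
#' pte_config(delay = 5, band = c(4, 30))
#' @export
pte_config <- function(delay = 10L, embedding_k = 1L, band = c(2, 60),
                       bin_rule = "scott", bins_override = NULL) {
  delay <- as.integer(delay)
  if (length(delay) != 1L || is.na(delay) || delay < 1L)
    stop("`delay` must be a positive integer", call. = FALSE)
  if (!identical(as.integer(embedding_k), 1L))
    stop("only embedding length k = 1 is supported", call. = FALSE)
  if (length(band) != 2L || !all(is.finite(band)) || band[1] <= 0 ||
      band[2] <= band[1])
    stop("`band` must be an increasing positive (low, high) pair in Hz",
         call. = FALSE)
  bin_rule <- match.arg(bin_rule, "scott")
  if (!is.null(bins_override)) {
    bins_override <- as.integer(bins_override)
    if (bins_override < 2L) stop("`bins_override` must be >= 2", call. = FALSE)
  }
  structure(
    list(delay = delay, embedding_k = 1L, band = as.numeric(band),
         bin_rule = bin_rule, bins_override = bins_override),
    class = "pte_config"
  )
}

#' Instantaneous phase of a band-limited analytic signal
#'
#' Computes the analytic signal in the frequency domain -- zeroing all
#' negative-frequency and out-of-band coefficients and doubling the retained
#' positive-frequency coefficients -- and returns its argument. Band
#' restriction and phase extraction are fused into one step so no separate
#' time-domain filter smears the phase.
#'
#' @param signal Real numeric vector, length >= 64.
#' @param fs Sampling rate in Hz.
#' @param band Numeric length-2 passband in Hz; must lie inside (0, fs/2).
#' @return Numeric vector of phases in (-pi, pi], same length as `signal`.
#' @examples
#' ph <- analytic_phase(cos(2 * pi * 10 * (0:1199) / 1200), fs = 1200)
#' mean(diff(ph[100:200]))  # ~ 2*pi*10/1200
#' @export
analytic_phase <- function(signal, fs, band = c(2, 60)) {
  n <- length(signal)
  if (n < 64L) stop("`signal` must have at least 64 samples", call. = FALSE)
  if (!all(is.finite(signal))) stop("`signal` contains non-finite values",
                                    call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (band[1] <= 0 || band[2] >= fs / 2 || band[2] <= band[1])
    stop("`band` must lie inside (0, fs/2)", call. = FALSE)
  if (sd(signal) == 0)
    stop("constant (zero-power) signal has no phase", call. = FALSE)
  xf <- fft(signal)
  freq <- (seq_len(n) - 1L) * fs / n
  # strictly positive frequencies, excluding the Nyquist bin for even n
  pos <- seq(2L, floor((n - 1) / 2) + 1L)
  keep <- pos[freq[pos] >= band[1] & freq[pos] <= band[2]]
  if (length(keep) == 0L)
    stop("no Fourier coefficients fall inside `band`", call. = FALSE)
  yf <- complex(n)
  yf[keep] <- 2 * xf[keep]
  z <- fft(yf, inverse = TRUE) / n
  Arg(z)
}

#' Histogram bin count from the Nason--Scott rule
#'
#' Normal-reference bin width `h = 3.49 * sd * m^(-1/3)` evaluated on a
#' pooled phase sample, converted to a count of equal bins partitioning
#' `[-pi, pi]`: `ceiling(2*pi / h)`, with a floor of 2.
#'
#' @param phases Numeric sample of phases used to estimate the spread.
#' @param m Sample size entering the rule (defaults to `length(phases)`);
#'   passed separately because the spread may be pooled over more values
#'   than one axis contributes.
#' @return Integer bin count >= 2.
#' @examples
#' scott_bins(runif(1911, -pi, pi))
#' @export
scott_bins <- function(phases, m = length(phases)) {
  if (m < 2) stop("`m` must be at least 2", call. = FALSE)
  s <- sd(phases)
  if (!is.finite(s) || s == 0)
    stop("degenerate phase sample: zero spread", call. = FALSE)
  h <- 3.49 * s * m^(-1 / 3)
  max(2L, as.integer(ceiling(2 * pi / h)))
}

# Map phases in (-pi, pi] to bin indices 1..bins (uniform partition).
bin_phases <- function(ph, bins) {
  b <- floor((ph + pi) / (2 * pi) * bins)
  as.integer(pmin(pmax(b, 0), bins - 1)) + 1L
}

# Plug-in entropy (nats) of a vector of integer codes with `levels` cells.
plugin_entropy <- function(codes, levels) {
  cnt <- tabulate(codes, nbins = levels)
  p <- cnt[cnt > 0] / length(codes)
  -sum(p * log(p))
}

#' Phase transfer entropy between two phase series
#'
#' Plug-in estimate of the transfer entropy from the phase of a source
#' signal to the phase of a target, with a single-sample target history:
#' `PTE = H(yf, yp) - H(yp) - H(yf, yp, xp) + H(yp, xp)` where
#' `yf = phase_y[t + delay]`, `yp = phase_y[t]`, `xp = phase_x[t]`, and all
#' entropies are natural-log histogram entropies over binned phases.
#'
#' This is the reference (pure R) estimator; [pte_matrix()] uses an
#' identical compiled kernel for all node pairs of a trial.
#'
#' @param phase_x,phase_y Phase series of equal length (source, target).
#' @param cfg A [pte_config()].
#' @param bins Optional bin count; if `NULL`, the Nason--Scott rule is
#'   evaluated on the pooled pair of series with `m = T - delay`
#'   (or `cfg$bins_override` wins if set).
#' @return Nonnegative scalar, nats (up to floating tolerance).
#' @examples
#' set.seed(1)
#' x <- cumsum(rnorm(500, sd = 0.3))
#' y <- c(rep(0, 10), x[1:490]) + rnorm(500, sd = 0.05)
#' wx <- Arg(exp(1i * x)); wy <- Arg(exp(1i * y))
#' pte_pair(wx, wy, pte_config()) > pte_pair(wy, wx, pte_config())
#' @export
pte_pair <- function(phase_x, phase_y, cfg = pte_config(), bins = NULL) {
  if (length(phase_x) != length(phase_y))
    stop("phase series must have equal length", call. = FALSE)
  T_len <- length(phase_y)
  d <- cfg$delay
  m <- T_len - d
  if (m < 2) stop("series too short for the configured delay", call. = FALSE)
  if (is.null(bins)) {
    bins <- if (!is.null(cfg$bins_override)) cfg$bins_override
            else scott_bins(c(phase_x, phase_y), m = m)
  }
  bins <- as.integer(bins)
  if (bins < 2L) stop("degenerate histogram: fewer than 2 bins", call. = FALSE)
  if (m < 10 * bins)
    warning("fewer than 10 samples per bin; PTE estimate will be biased",
            call. = FALSE)
  t_idx <- seq_len(m)
  yf <- bin_phases(phase_y[t_idx + d], bins)
  yp <- bin_phases(phase_y[t_idx], bins)
  xp <- bin_phases(phase_x[t_idx], bins)
  if (length(unique(yp)) < 2L && length(unique(xp)) < 2L)
    stop("degenerate single-bin histogram", call. = FALSE)
  h_yp <- plugin_entropy(yp, bins)
  h_yfyp <- plugin_entropy((yf - 1L) * bins + yp, bins^2)
  h_ypxp <- plugin_entropy((yp - 1L) * bins + xp, bins^2)
  h_yfypxp <- plugin_entropy(((yf - 1L) * bins + (yp - 1L)) * bins + xp,
                             bins^3)
  h_yfyp - h_yp - h_yfypxp + h_ypxp
}

#' Directed PTE adjacency matrix of one trial
#'
#' Extracts the band-limited analytic phase of every node once, chooses a
#' common bin count for the whole trial (Nason--Scott rule on the pooled
#' phases with `m = samples - delay`), and fills the full directed
#' source-by-target matrix with plug-in PTE values. Diagonal is zero.
#'
#' @param trial Numeric nodes x samples matrix (one epoch).
#' @param fs Sampling rate in Hz.
#' @param cfg A [pte_config()].
#' @return N x N matrix; entry `(i, j)` is PTE from node i to node j.
#'   Row/column names are taken from `rownames(trial)` when present.
#' @examples
#' set.seed(1)
#' tr <- matrix(rnorm(3 * 400), 3, 400)
#' pte_matrix(tr, fs = 200, cfg = pte_config(band = c(2, 60)))
#' @export
pte_matrix <- function(trial, fs, cfg = pte_config()) {
  if (!is.matrix(trial) || nrow(trial) < 2L)
    stop("`trial` must be a nodes x samples matrix with >= 2 nodes",
         call. = FALSE)
  n_nodes <- nrow(trial)
  phases <- vapply(
    seq_len(n_nodes),
    function(i) {
      tryCatch(analytic_phase(trial[i, ], fs, cfg$band),
               error = function(e) stop("node ", i, ": ", conditionMessage(e),
                                        call. = FALSE))
    },
    numeric(ncol(trial))
  )  # samples x nodes
  m <- ncol(trial) - cfg$delay
  bins <- if (!is.null(cfg$bins_override)) cfg$bins_override
          else scott_bins(as.numeric(phases), m = m)
  out <- cpp_pte_matrix(phases, cfg$delay, as.integer(bins))
  if (!is.null(rownames(trial)))
    dimnames(out) <- list(rownames(trial), rownames(trial))
  attr(out, "bins") <- as.integer(bins)
  out
}

#' Trial-averaged, z-scored condition network
#'
#' Averages single-trial PTE matrices entrywise and z-scores the mean
#' matrix over its off-diagonal entries (the diagonal stays 0), yielding
#' one normalized directed network per subject and condition.
#'
#' @param trial_matrices List of N x N matrices, or an N x N x trials array.
#' @param subject,condition Optional labels stored with the result.
#' @return A `condition_network`: list with elements `matrix`, `subject`,
#'   `condition`, `normalized`.
#' @examples
#' m <- matrix(runif(16), 4, 4); diag(m) <- 0
#' condition_mean_z(list(m, m))
#' @export
condition_mean_z <- function(trial_matrices, subject = NA_character_,
                             condition = NA_character_) {
  if (is.array(trial_matrices) && length(dim(trial_matrices)) == 3L)
    trial_matrices <- lapply(seq_len(dim(trial_matrices)[3]),
                             function(k) trial_matrices[, , k])
  if (!is.list(trial_matrices) || length(trial_matrices) == 0L)
    stop("need at least one trial matrix", call. = FALSE)
  dims <- unique(lapply(trial_matrices, dim))
  if (length(dims) != 1L || dims[[1]][1] != dims[[1]][2])
    stop("trial matrices must share a common square shape", call. = FALSE)
  mn <- Reduce(`+`, trial_matrices) / length(trial_matrices)
  off <- row(mn) != col(mn)
  mu <- mean(mn[off])
  s <- sd(mn[off])
  if (s == 0) stop("zero spread across off-diagonal entries", call. = FALSE)
  z <- mn
  z[off] <- (mn[off] - mu) / s
  diag(z) <- 0
  structure(
    list(matrix = z, subject = subject, condition = condition,
         normalized = TRUE),
    class = "condition_network"
  )
}

#' @export
print.condition_network <- function(x, ...) {
  cat("<condition_network> ", x$condition, " / subject ", x$subject,
      ": ", nrow(x$matrix), " x ", ncol(x$matrix),
      if (isTRUE(x$normalized)) " (z-scored)", "\n", sep = "")
  invisible(x)
}
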