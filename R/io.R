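#' Write / read an epoch set as a plain-text directory
#'
#' One tab-separated nodes x samples matrix per trial
#' (`trial_0001.tsv`, ...) plus a JSON sidecar (`epochs.json`) holding the
#' sampling rate, per-trial condition labels, subject ID, node labels,
#' generator seed, and -- when the set was simulated -- the ground-truth
#' edge list. Values are written with 17 significant digits so a
#' round trip reproduces them bit-exactly.
#'
#' @param es An `epoch_set`.
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_epoch_set <- function(es, dir) {
  stopifnot(inherits(es, "epoch_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_trials <- dim(es$data)[1]
  for (k in seq_len(n_trials)) {
    m <- es$data[k, , ]
    utils::write.table(
      formatC(m, format = "g", digits = 17),
      file.path(dir, sprintf("trial_%04d.tsv", k)),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  gt <- attr(es, "ground_truth")
  sidecar <- list(
    fs = es$fs, subject = es$subject, node_labels = es$node_labels,
    condition = es$condition, seed = es$seed,
    n_trials = n_trials, n_nodes = dim(es$data)[2],
    n_samples = dim(es$data)[3],
    ground_truth_edges = if (!is.null(gt)) gt$coupling else NULL
  )
  jsonlite::write_json(sidecar, file.path(dir, "epochs.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "epochs.json"),
                                 simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^trial_\\d+\\.tsv$",
                           full.names = TRUE))
  if (length(files) != sidecar$n_trials)
    stop("trial file count does not match the sidecar", call. = FALSE)
  data <- array(NA_real_, dim = c(sidecar$n_trials, sidecar$n_nodes,
                                  sidecar$n_samples))
  for (k in seq_along(files)) {
    m <- as.matrix(utils::read.table(files[k], sep = "\t", header = FALSE,
                                     colClasses = "numeric"))
    if (!all(dim(m) == c(sidecar$n_nodes, sidecar$n_samples)))
      stop("corrupt trial file: ", files[k], call. = FALSE)
    data[k, , ] <- m
  }
  structure(
    list(data = data, fs = as.numeric(sidecar$fs),
         condition = sidecar$condition,
         subject = sidecar$subject, node_labels = sidecar$node_labels,
         seed = sidecar$seed),
    class = "epoch_set"
  )
}

#' Write / read a labelled matrix as TSV
#'
#' Tab-separated with a header row and a leading label column; full
#' 17-digit precision for bit-exact round trips.
#'
#' @param m Numeric matrix (row/col names used when present).
#' @param path File path.
#' @export
write_matrix_tsv <- function(m, path) {
  labels <- rownames(m)
  if (is.null(labels)) labels <- sprintf("node%03d", seq_len(nrow(m)))
  out <- cbind(label = labels, formatC(m, format = "g", digits = 17))
  colnames(out) <- c("label", if (!is.null(colnames(m))) colnames(m)
                     else labels[seq_len(ncol(m))])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read a multilayer graph
#'
#' The (K N) x (K N) matrix as labelled TSV plus a JSON sidecar naming
#' the states, node count, and subject.
#'
#' @param g A `multilayer_graph`.
#' @param prefix Path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @export
write_multilayer_graph <- function(g, prefix) {
  stopifnot(inherits(g, "multilayer_graph"))
  write_matrix_tsv(g$matrix, paste0(prefix, ".tsv"))
  jsonlite::write_json(
    list(states = g$states, n_nodes = g$n_nodes, subject = g$subject),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname write_multilayer_graph
#' @export
read_multilayer_graph <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  m <- read_matrix_tsv(paste0(prefix, ".tsv"))
  structure(list(matrix = m, states = meta$states, n_nodes = meta$n_nodes,
                 subject = meta$subject),
            class = "multilayer_graph")
}

#' Export a significant network as edge and node tables
#'
#' Writes `<prefix>_edges.tsv` (source_label, target_label, statistic, p)
#' and `<prefix>_nodes.tsv` (label, strength, degree).
#'
#' @param sn A `stat_network`.
#' @param prefix Path prefix.
#' @export
write_stat_network <- function(sn, prefix) {
  stopifnot(inherits(sn, "stat_network"))
  utils::write.table(sn$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sn$nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' BrainNet-viewer-compatible text export
#'
#' Writes the `.node` file (x, y, z, color, size, label) and `.edge`
#' file (the dense statistic matrix) of a significant network. Node
#' coordinates default to a unit circle since no anatomy is shipped;
#' supply `coords` (n x 3) to place real parcel centroids.
#'
#' @param sn A `stat_network`.
#' @param prefix Path prefix; writes `<prefix>.node` and `<prefix>.edge`.
#' @param coords Optional n x 3 coordinate matrix.
#' @export
export_brainnet <- function(sn, prefix, coords = NULL) {
  stopifnot(inherits(sn, "stat_network"))
  n <- sn$n_nodes
  if (is.null(coords)) {
    ang <- 2 * pi * (seq_len(n) - 1) / n
    coords <- cbind(cos(ang) * 50, sin(ang) * 50, 0)
  }
  node <- cbind(coords, 1, sn$nodes$strength, sn$nodes$node)
  utils::write.table(node, paste0(prefix, ".node"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  m <- matrix(0, n, n)
  if (nrow(sn$edges)) {
    i <- match(sn$edges$source, sn$nodes$node)
    j <- match(sn$edges$target, sn$nodes$node)
    m[cbind(i, j)] <- sn$edges$statistic
  }
  utils::write.table(m, paste0(prefix, ".edge"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Export a stimulus stream as an event table
#'
#' @param stream A [generate_stream()] tibble.
#' @param ps Its [build_pattern_set()].
#' @param path Output TSV path.
#' @export
write_stream_events <- function(stream, ps, path) {
  utils::write.table(stream_events(stream, ps), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
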