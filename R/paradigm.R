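#' Pattern inventory for the multifeatured statistical-learning stream
#'
#' Builds the four pattern categories of the multisensory oddball design.
#' Eleven base stimuli couple four features: each stimulus index carries a
#' shape, the color belonging to that shape, a pitch (a seeded bijection
#' pitch <-> shape defines the audiovisual stream), and the timbre
#' belonging to that pitch. Six standard triplet patterns are drawn with
#' distinct first stimuli; each deviant category is derived from a
#' standard pattern by replacing, in the third stimulus only, the violated
#' feature(s) with the value carried by the first stimulus of a different
#' standard pattern:
#' auditory deviant -- timbre; visual deviant -- color; audiovisual
#' incongruent -- shape and pitch together (timbre and color unchanged).
#'
#' @param seed Integer seed; construction is deterministic given it.
#' @return A `pattern_set`: list with `patterns` (tibble: category,
#'   pattern_id, position, shape, color, pitch, timbre), `stimuli` (the 11
#'   base stimuli), `alphabets`, `donors` (which standard pattern supplied
#'   each substituted value), and `seed`.
#' @examples
#' ps <- build_pattern_set(seed = 1)
#' dplyr::count(ps$patterns, category)
#' @export
build_pattern_set <- function(seed) {
  pitches <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "B")
  timbres <- c("reflective_string", "pop_flute", "tenor_sax", "grand_piano",
               "fingerstyle_bass", "future_flute", "swirling_piano",
               "smokey_clav", "pop_organ", "hollywood_strings",
               "electric_tremolo")
  colors <- c("192,0,0", "160,81,16", "132,140,142", "255,192,0",
              "175,170,105", "0,176,80", "70,181,211", "173,173,219",
              "0,32,96", "112,48,160", "127,127,127")
  shapes <- sprintf("shape%02d", 1:11)

  withr::local_seed(seed)
  pitch_of <- sample.int(11)  # bijection: stimulus/shape index -> pitch index
  stimuli <- tibble::tibble(
    stimulus = 1:11, shape = shapes, color = colors,
    pitch = pitches[pitch_of], timbre = timbres[pitch_of]
  )

  # six standard triplets with distinct first stimuli
  firsts <- sample.int(11, 6)
  triplets <- cbind(firsts,
                    replicate(2, sample.int(11, 6, replace = FALSE)))
  standards <- lapply(1:6, function(p) triplets[p, ])

  lookup <- function(idx) stimuli[idx, c("shape", "color", "pitch", "timbre")]

  pick_donor <- function(p, third_idx) {
    ok <- setdiff(1:6, p)
    ok <- ok[firsts[ok] != third_idx]
    if (length(ok) == 1L) ok else sample(ok, 1L)
  }

  rows <- list()
  donors <- list()
  for (p in 1:6) {
    tri <- standards[[p]]
    std <- lookup(tri)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      category = "standard", pattern_id = p, position = 1:3, std)

    for (cat in c("auditory_deviant", "visual_deviant",
                  "audiovisual_incongruent")) {
      donor <- pick_donor(p, tri[3])
      dstim <- lookup(firsts[donor])
      dev <- std
      if (cat == "auditory_deviant") dev$timbre[3] <- dstim$timbre
      if (cat == "visual_deviant") dev$color[3] <- dstim$color
      if (cat == "audiovisual_incongruent") {
        dev$shape[3] <- dstim$shape
        dev$pitch[3] <- dstim$pitch
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        category = cat, pattern_id = p, position = 1:3, dev)
      donors[[length(donors) + 1L]] <- tibble::tibble(
        category = cat, pattern_id = p, donor_pattern = donor)
    }
  }

  structure(
    list(patterns = dplyr::bind_rows(rows), stimuli = stimuli,
         alphabets = list(pitch = pitches, timbre = timbres, color = colors,
                          shape = shapes),
         donors = dplyr::bind_rows(donors), seed = seed),
    class = "pattern_set"
  )
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("<pattern_set> 4 categories x 6 triplet patterns (seed ", x$seed,
      ")\n", sep = "")
  invisible(x)
}

categories <- function() c("standard", "audiovisual_incongruent",
                           "auditory_deviant", "visual_deviant")

#' Generate a stimulus stream
#'
#' Phase 1 presents standard patterns only; each phase-2 run interleaves
#' the four categories equally and randomly (a seeded permutation of an
#' exactly balanced multiset, so the stated per-run balance holds by
#' construction). Timing metadata uses 400 ms stimuli and a 150 ms ISI.
#'
#' @param ps A [build_pattern_set()] object.
#' @param phase1_n Standard patterns in the familiarization phase
#'   (default 70).
#' @param runs Number of phase-2 runs (default 3).
#' @param patterns_per_run Patterns per run, divisible by 4 (default 460).
#' @param seed Integer seed.
#' @return A `stimulus_stream` tibble: slot, phase, run, category,
#'   pattern_id, onset_ms; attributes carry the timing metadata.
#' @examples
#' ps <- build_pattern_set(1)
#' st <- generate_stream(ps, phase1_n = 10, runs = 1,
#'                       patterns_per_run = 20, seed = 2)
#' @export
generate_stream <- function(ps, phase1_n = 70L, runs = 3L,
                            patterns_per_run = 460L, seed) {
  stopifnot(inherits(ps, "pattern_set"))
  if (patterns_per_run %% 4L != 0L)
    stop("`patterns_per_run` must be divisible by 4", call. = FALSE)
  withr::local_seed(seed)
  per_cat <- patterns_per_run %/% 4L

  phase1 <- tibble::tibble(
    phase = 1L, run = 0L, category = "standard",
    pattern_id = sample.int(6, phase1_n, replace = TRUE)
  )
  phase2 <- dplyr::bind_rows(lapply(seq_len(runs), function(r) {
    cats <- sample(rep(categories(), each = per_cat))
    tibble::tibble(phase = 2L, run = as.integer(r), category = cats,
                   pattern_id = sample.int(6, patterns_per_run,
                                           replace = TRUE))
  }))

  out <- dplyr::bind_rows(phase1, phase2)
  stim_ms <- 400 + 150  # stimulus duration + ISI
  pattern_ms <- 3 * stim_ms
  out$slot <- seq_len(nrow(out))
  out$onset_ms <- (out$slot - 1L) * pattern_ms
  out <- out[, c("slot", "phase", "run", "category", "pattern_id",
                 "onset_ms")]
  attr(out, "stimulus_ms") <- 400
  attr(out, "isi_ms") <- 150
  attr(out, "seed") <- seed
  class(out) <- c("stimulus_stream", class(out))
  out
}

#' Expand a stream into a per-stimulus event table
#'
#' @param stream A [generate_stream()] tibble.
#' @param ps The [build_pattern_set()] it was generated from.
#' @return Tibble with one row per stimulus: onset_ms, slot, category,
#'   pattern_id, stimulus_index (position in the triplet), shape, color,
#'   pitch, timbre.
#' @export
stream_events <- function(stream, ps) {
  stopifnot(inherits(ps, "pattern_set"))
  stim_ms <- attr(stream, "stimulus_ms") + attr(stream, "isi_ms")
  ev <- dplyr::left_join(
    tibble::as_tibble(stream), ps$patterns,
    by = c("category", "pattern_id"), relationship = "many-to-many"
  )
  ev$onset_ms <- ev$onset_ms + (ev$position - 1L) * stim_ms
  dplyr::select(
    dplyr::arrange(ev, .data$slot, .data$position),
    onset_ms = "onset_ms", slot = "slot", category = "category",
    pattern_id = "pattern_id", stimulus_index = "position",
    shape = "shape", color = "color", pitch = "pitch", timbre = "timbre"
  )
}

#' Empirical transitional probabilities of one feature stream
#'
#' Flattens the stimulus sequence of the chosen feature over the whole
#' stream (transitions within and across patterns both count) and returns
#' the row-normalized first-order transition matrix
#' `P(next symbol | current symbol)`.
#'
#' @param stream A [generate_stream()] tibble.
#' @param ps The matching [build_pattern_set()].
#' @param feature One of `"pitch"`, `"timbre"`, `"shape"`, `"color"`.
#' @return Symbol x symbol matrix; every row with at least one observed
#'   transition sums to 1.
#' @export
transition_probabilities <- function(stream, ps, feature) {
  feature <- match.arg(feature, c("pitch", "timbre", "shape", "color"))
  if (nrow(stream) == 0L) stop("empty stream", call. = FALSE)
  ev <- stream_events(stream, ps)
  sym <- ev[[feature]]
  alph <- ps$alphabets[[feature]]
  from <- factor(sym[-length(sym)], levels = alph)
  to <- factor(sym[-1], levels = alph)
  counts <- table(from, to)
  tot <- rowSums(counts)
  prob <- sweep(unclass(counts), 1, pmax(tot, 1), `/`)
  dimnames(prob) <- list(alph, alph)
  prob
}

#' Feature transitions that define each pattern category
#'
#' Enumerates, for one feature, the within-pattern symbol transitions of
#' the standard patterns and the deviant-defining transitions (second
#' stimulus to substituted third stimulus) of the category violating that
#' feature. Useful for checking that deviant-defining transitions are
#' rarer than standard ones in a generated stream.
#'
#' @param ps A [build_pattern_set()].
#' @param feature Feature name.
#' @return Tibble (kind, category, pattern_id, from, to) with
#'   `kind` in `standard_within` / `deviant_defining`.
#' @export
pattern_transitions <- function(ps, feature) {
  feature <- match.arg(feature, c("pitch", "timbre", "shape", "color"))
  viol <- switch(feature,
                 timbre = "auditory_deviant",
                 color = "visual_deviant",
                 pitch = "audiovisual_incongruent",
                 shape = "audiovisual_incongruent")
  grab <- function(cat, kind, positions) {
    pat <- dplyr::filter(ps$patterns, .data$category == cat)
    dplyr::bind_rows(lapply(unique(pat$pattern_id), function(p) {
      v <- pat[[feature]][pat$pattern_id == p][order(
        pat$position[pat$pattern_id == p])]
      tibble::tibble(kind = kind, category = cat, pattern_id = p,
                     from = v[positions], to = v[positions + 1L])
    }))
  }
  dplyr::bind_rows(grab("standard", "standard_within", 1:2),
                   grab(viol, "deviant_defining", 2L))
}

#' Build the 36-pair two-alternative forced-choice test
#'
#' Twelve pairs per deviant modality; each pair couples a deviant pattern
#' with its source standard pattern (each of the six patterns is used
#' twice per modality), and the presentation order within a pair is
#' counterbalanced 6/6 within each modality (18/18 overall).
#'
#' @param ps A [build_pattern_set()].
#' @param seed Integer seed.
#' @return Tibble of 36 rows: trial, modality, pattern_id, order
#'   (`"standard_first"` / `"deviant_first"`).
#' @export
build_2afc_test <- function(ps, seed) {
  stopifnot(inherits(ps, "pattern_set"))
  withr::local_seed(seed)
  modalities <- c("auditory", "visual", "audiovisual")
  rows <- dplyr::bind_rows(lapply(modalities, function(m) {
    pats <- sample(rep(1:6, 2))
    ord <- sample(rep(c("standard_first", "deviant_first"), 6))
    tibble::tibble(modality = m, pattern_id = pats, order = ord)
  }))
  rows <- rows[sample.int(nrow(rows)), ]
  rows$trial <- seq_len(nrow(rows))
  rows[, c("trial", "modality", "pattern_id", "order")]
}
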