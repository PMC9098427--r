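#' Logit-transformed proportion correct
#'
#' Two-alternative forced-choice accuracies are binomial proportions; the
#' logit transform `ln(p / (1 - p))` puts them on an unbounded scale for
#' parametric tests, with chance (p = 0.5) mapping to exactly 0. With the
#' small-sample correction (default) the proportion is shrunk as
#' `p' = (k + 0.5) / (n + 1)`, so boundary counts stay finite; without it,
#' proportions of 0 or 1 are an error.
#'
#' @param n_correct Correct-response count(s).
#' @param n_trials Trial count(s), >= 1.
#' @param correction Apply the 0.5 / (n + 1) correction (default `TRUE`).
#' @return Numeric logit value(s).
#' @examples
#' logit_proportion(18, 36, correction = FALSE)  # chance -> 0
#' logit_proportion(27, 36)
#' @export
logit_proportion <- function(n_correct, n_trials, correction = TRUE) {
  if (any(n_trials < 1)) stop("`n_trials` must be >= 1", call. = FALSE)
  if (any(n_correct < 0 | n_correct > n_trials))
    stop("`n_correct` must lie in [0, n_trials]", call. = FALSE)
  p <- if (correction) (n_correct + 0.5) / (n_trials + 1)
       else n_correct / n_trials
  if (!correction && any(p %in% c(0, 1)))
    stop("proportion of 0 or 1 has no raw logit; use `correction = TRUE`",
         call. = FALSE)
  log(p / (1 - p))
}

#' One-sample t test with Cohen's d
#'
#' @param values Numeric vector (n >= 2, nonzero SD).
#' @param mu0 Null value (default 0, the logit chance level).
#' @return Tibble: estimate (mean), t, df, p_value, cohen_d. The identity
#'   `t = d * sqrt(n)` holds exactly.
#' @examples
#' one_sample_t(c(1, 2, 3), mu0 = 0)
#' @export
one_sample_t <- function(values, mu0 = 0) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  s <- sd(values)
  if (s == 0) stop("zero standard deviation", call. = FALSE)
  m <- mean(values)
  t <- (m - mu0) / (s / sqrt(n))
  tibble::tibble(estimate = m, t = t, df = n - 1,
                 p_value = 2 * pt(-abs(t), n - 1),
                 cohen_d = (m - mu0) / s)
}

#' Independent-groups t test with Hedges' g
#'
#' Equal-variance pooled-SD two-sample t (`df = nA + nB - 2`) and the
#' small-sample-corrected standardized mean difference
#' `g = d * (1 - 3 / (4 df - 1))` with `d = (meanA - meanB) / SD_pooled`.
#' Accepts either raw vectors or summary statistics.
#'
#' @param groupA,groupB Numeric vectors (each n >= 2); or `NULL` when
#'   summaries are supplied.
#' @param summary Optional list with `meanA, sdA, nA, meanB, sdB, nB`.
#' @return Tibble: mean_a, mean_b, t, df, p_value, cohen_d, hedges_g.
#' @examples
#' independent_t_hedges(summary = list(meanA = 0.476, sdA = 0.406, nA = 13,
#'                                     meanB = 0.979, sdB = 0.484, nB = 12))
#' @export
independent_t_hedges <- function(groupA = NULL, groupB = NULL,
                                 summary = NULL) {
  if (is.null(summary)) {
    if (length(groupA) < 2 || length(groupB) < 2)
      stop("need at least 2 values per group", call. = FALSE)
    summary <- list(meanA = mean(groupA), sdA = sd(groupA),
                    nA = length(groupA),
                    meanB = mean(groupB), sdB = sd(groupB),
                    nB = length(groupB))
  }
  s <- summary
  df <- s$nA + s$nB - 2
  sp <- sqrt(((s$nA - 1) * s$sdA^2 + (s$nB - 1) * s$sdB^2) / df)
  if (sp == 0) stop("zero pooled standard deviation", call. = FALSE)
  d <- (s$meanA - s$meanB) / sp
  t <- (s$meanA - s$meanB) / (sp * sqrt(1 / s$nA + 1 / s$nB))
  tibble::tibble(mean_a = s$meanA, mean_b = s$meanB, t = t, df = df,
                 p_value = 2 * pt(-abs(t), df),
                 cohen_d = d, hedges_g = d * (1 - 3 / (4 * df - 1)))
}

#' Mixed-design ANOVA: between-subjects group x within-subjects modality
#'
#' Classical mixed-model sums of squares via `stats::aov` with a
#' subject error stratum: the group effect is tested against
#' subjects-within-group, modality and the group x modality interaction
#' against the modality x subjects-within-group residual. Partial eta
#' squared is `SS_effect / (SS_effect + SS_error)` with each effect's own
#' error term. Requires complete data (every subject observed in every
#' modality).
#'
#' @param table Data frame with columns `subject`, `group`, `modality`,
#'   and either `logit_value` or (`n_correct`, `n_trials`), from which
#'   logits are computed.
#' @return Tibble with one row per effect (group, modality,
#'   group:modality): df1, df2, F, p_value, partial_eta_sq.
#' @export
mixed_anova_2x3 <- function(table) {
  tab <- tibble::as_tibble(table)
  if (!"logit_value" %in% names(tab)) {
    if (!all(c("n_correct", "n_trials") %in% names(tab)))
      stop("need `logit_value` or `n_correct`/`n_trials` columns",
           call. = FALSE)
    tab$logit_value <- logit_proportion(tab$n_correct, tab$n_trials)
  }
  stopifnot(all(c("subject", "group", "modality") %in% names(tab)))
  cells <- table(tab$subject, tab$modality)
  if (any(cells != 1L))
    stop("design must be complete: one value per subject x modality",
         call. = FALSE)
  tab$subject <- factor(tab$subject)
  tab$group <- factor(tab$group)
  tab$modality <- factor(tab$modality)

  fit <- aov(logit_value ~ group * modality + Error(subject),
             data = tab)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject"]][[1]])
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(between))
  rn_w <- trimws(rownames(within))
  ss <- function(tabdf, rn, name) tabdf[match(name, rn), "Sum Sq"]
  df_of <- function(tabdf, rn, name) tabdf[match(name, rn), "Df"]

  eff <- tibble::tibble(
    effect = c("group", "modality", "group:modality"),
    ss = c(ss(between, rn_b, "group"), ss(within, rn_w, "modality"),
           ss(within, rn_w, "group:modality")),
    df1 = c(df_of(between, rn_b, "group"), df_of(within, rn_w, "modality"),
            df_of(within, rn_w, "group:modality")),
    ss_err = c(ss(between, rn_b, "Residuals"),
               ss(within, rn_w, "Residuals"),
               ss(within, rn_w, "Residuals")),
    df2 = c(df_of(between, rn_b, "Residuals"),
            df_of(within, rn_w, "Residuals"),
            df_of(within, rn_w, "Residuals"))
  )
  # numerically zero sums of squares (constant data) mean no effect
  tol <- 1e-12 * max(sum((tab$logit_value - mean(tab$logit_value))^2), 1)
  zero <- eff$ss <= tol
  eff$F <- (eff$ss / eff$df1) / (eff$ss_err / eff$df2)
  eff$F[zero] <- 0
  eff$p_value <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  eff$partial_eta_sq <- ifelse(zero, 0, eff$ss / (eff$ss + eff$ss_err))
  eff[, c("effect", "df1", "df2", "F", "p_value", "partial_eta_sq")]
}

#' Full 2AFC behavioral analysis
#'
#' Chains the standard analysis of a two-group, three-modality 2AFC
#' experiment: per-group, per-modality one-sample t tests of the logit
#' accuracies against the chance level 0; the group x modality mixed
#' ANOVA; and the between-group comparison of overall accuracy (total
#' correct over total trials per subject, logit-transformed) with
#' Hedges' g.
#'
#' @param table Tibble as produced by [simulate_behavior()]:
#'   subject, group, modality, n_correct, n_trials.
#' @return List with `chance_tests`, `anova`, and `group_comparison`
#'   tibbles.
#' @export
analyze_behavior <- function(table) {
  tab <- tibble::as_tibble(table)
  tab$logit_value <- logit_proportion(tab$n_correct, tab$n_trials)

  chance <- tab |>
    dplyr::group_by(.data$group, .data$modality) |>
    dplyr::reframe(one_sample_t(.data$logit_value, mu0 = 0))

  anova <- mixed_anova_2x3(tab)

  overall <- tab |>
    dplyr::group_by(.data$subject, .data$group) |>
    dplyr::summarise(n_correct = sum(.data$n_correct),
                     n_trials = sum(.data$n_trials), .groups = "drop") |>
    dplyr::mutate(logit_value = logit_proportion(.data$n_correct,
                                                 .data$n_trials))
  groups <- sort(unique(overall$group))
  if (length(groups) != 2L) stop("expected exactly two groups",
                                 call. = FALSE)
  cmp <- independent_t_hedges(
    overall$logit_value[overall$group == groups[1]],
    overall$logit_value[overall$group == groups[2]]
  )
  cmp$group_a <- groups[1]
  cmp$group_b <- groups[2]
  list(chance_tests = chance, anova = anova, group_comparison = cmp)
}
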