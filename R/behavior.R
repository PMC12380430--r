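# Palp-opening-response (POR) behavioral statistics: response probabilities,
# paired intensity tests, early/late contrasts, catch-trial drops and the
# neural-behavioral regression.

#' Per-trial POR probability
#'
#' Fraction of animals exhibiting a palp-opening response on each trial of a
#' stimulus, in trial order — the p(POR) curve.
#'
#' @param table A behavior table (see [read_behavior_table()]).
#' @param stimulus Stimulus label to summarize.
#' @return An object of class `por_summary`: `p_por` (named per-trial
#'   fractions), `n_animals`, `stimulus_label`, `trials`.
#' @export
por_probability <- function(table, stimulus) {
  sub <- table[table$stimulus_label == stimulus, , drop = FALSE]
  if (!nrow(sub))
    oa_stop("usage_error", "stimulus '%s' absent from behavior table",
            stimulus)
  trials <- sort(unique(sub$trial_id))
  p <- vapply(trials, function(t)
    mean(sub$por[sub$trial_id == t]), numeric(1))
  names(p) <- trials
  structure(
    list(p_por = p,
         n_animals = length(unique(sub$animal_id)),
         stimulus_label = stimulus,
         trials = trials),
    class = "por_summary"
  )
}

#' @export
print.por_summary <- function(x, ...) {
  cat(sprintf("p(POR) for %s over %d animals:\n", x$stimulus_label,
              x$n_animals))
  print(round(x$p_por, 3))
  invisible(x)
}

# paired t on (low - high) per-animal means; identical pairs are the
# symmetric-null center (t = 0, p = 0.5 for the left tail)
.paired_left_t <- function(lo, hi) {
  d <- lo - hi
  n <- length(d)
  if (n < 2) oa_stop("usage_error", "need at least 2 pairs")
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 0.5, df = n - 1))
    t <- sign(mean(d)) * Inf
    return(list(t = t, p = if (t < 0) 0 else 1, df = n - 1))
  }
  tt <- stats::t.test(lo, hi, paired = TRUE, alternative = "less")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Paired one-sided test of intensity discriminability
#'
#' For one odor, computes each animal's response probability at low and at
#' high intensity over the selected trials and runs a paired left-tailed
#' t-test of whether the low-intensity p(POR) is smaller than the
#' high-intensity p(POR). Pairing is on animals; every animal must appear
#' at both intensities. P-values come from the t distribution with
#' `n_pairs - 1` degrees of freedom; no multiple-testing correction is
#' applied (a Bonferroni divisor can be applied by the caller across odors).
#'
#' @param table A behavior table containing `"<odor>_L"` and `"<odor>_H"`
#'   stimuli.
#' @param odor Odor name (without intensity suffix).
#' @param trials Optional trial subset (default: all trials).
#' @return An object of class `paired_test`: `t_statistic`, `p_value`,
#'   `n_pairs`, `df`, `tail = "left"`.
#' @export
intensity_ttest <- function(table, odor, trials = NULL) {
  lab_l <- paste0(odor, "_L"); lab_h <- paste0(odor, "_H")
  for (lab in c(lab_l, lab_h))
    if (!any(table$stimulus_label == lab))
      oa_stop("usage_error", "stimulus '%s' absent from behavior table", lab)
  sub <- table[table$stimulus_label %in% c(lab_l, lab_h), , drop = FALSE]
  if (!is.null(trials)) {
    sub <- sub[sub$trial_id %in% trials, , drop = FALSE]
    if (!nrow(sub))
      oa_stop("usage_error", "no rows in the selected trials")
  }
  per <- function(lab) {
    s <- sub[sub$stimulus_label == lab, , drop = FALSE]
    tapply(s$por, s$animal_id, mean)
  }
  lo <- per(lab_l); hi <- per(lab_h)
  unpaired <- union(setdiff(names(lo), names(hi)),
                    setdiff(names(hi), names(lo)))
  if (length(unpaired))
    oa_stop("pairing_error",
            "animal(s) lacking one intensity: %s",
            paste(unpaired, collapse = ", "))
  hi <- hi[names(lo)]
  res <- .paired_left_t(as.numeric(lo), as.numeric(hi))
  structure(
    list(t_statistic = res$t, p_value = res$p, n_pairs = length(lo),
         df = res$df, tail = "left"),
    class = "paired_test"
  )
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Paired %s-tailed t-test: t = %.4g, p = %.4g (n = %d pairs)\n",
              x$tail, x$t_statistic, x$p_value, x$n_pairs))
  invisible(x)
}

#' Early- versus late-trial intensity discriminability
#'
#' Runs [intensity_ttest()] separately on the early trials (1..`split_trial`)
#' and the late trials (`split_trial + 1`..end) — the contrast showing that
#' intensity discriminability emerges only after adaptation has set in.
#'
#' @param table A behavior table.
#' @param odor Odor name.
#' @param split_trial Last early trial (default 5); must lie strictly inside
#'   the observed trial range.
#' @return A list with `early` and `late` `paired_test` results.
#' @export
early_late_comparison <- function(table, odor, split_trial = 5) {
  labs <- paste0(odor, c("_L", "_H"))
  sub <- table[table$stimulus_label %in% labs, , drop = FALSE]
  if (!nrow(sub))
    oa_stop("usage_error", "odor '%s' absent from behavior table", odor)
  max_trial <- max(sub$trial_id)
  if (split_trial < 1 || split_trial >= max_trial)
    oa_stop("usage_error",
            "split_trial (%d) must lie within the %d observed trials",
            split_trial, max_trial)
  list(early = intensity_ttest(table, odor, trials = seq_len(split_trial)),
       late = intensity_ttest(table, odor,
                              trials = (split_trial + 1):max_trial))
}

#' Regression of behavioral probability on ensemble spike counts
#'
#' Ordinary least squares of the per-trial p(POR) on the total ensemble
#' spike count of the same trial. A negative slope is the repetition-priming
#' signature: neural responses shrink across trials while behavioral
#' responses facilitate.
#'
#' @param counts Per-trial total spike counts (e.g.
#'   [ensemble_count_timecourse()]).
#' @param por A `por_summary` (or numeric vector) with one value per trial.
#' @return A `regression_fit` with an additional `slope_sign` field.
#' @export
neural_behavior_regression <- function(counts, por) {
  p <- if (inherits(por, "por_summary")) por$p_por else as.numeric(por)
  if (length(counts) != length(p))
    oa_stop("alignment_error",
            "counts (%d) and p(POR) (%d) differ in trial count",
            length(counts), length(p))
  fit <- .ols_fit(as.numeric(counts), p, "spike counts", "p(POR)")
  fit$slope_sign <- sign(fit$slope)
  fit
}

#' Catch-trial behavioral profile
#'
#' Per-trial p(POR) across the catch-trial block (pooling over the presented
#' stimulus, which differs only on the catch trial), plus the catch drop:
#' the catch-trial probability minus the mean of its two flanking
#' repeated-odor trials. A markedly negative drop shows the facilitation is
#' odor-specific.
#'
#' @param table A behavior table from a catch session.
#' @param protocol The [stimulus_protocol()] declaring the catch trial.
#' @return A list with `p_por` (per trial), `catch_index`, `catch_p`,
#'   `flanker_mean`, `catch_drop`, `n_animals`.
#' @export
catch_trial_por <- function(table, protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (is.null(protocol$catch_trial_index))
    oa_stop("usage_error", "protocol declares no catch trial")
  ci <- protocol$catch_trial_index
  trials <- sort(unique(table$trial_id))
  p <- vapply(trials, function(t)
    mean(table$por[table$trial_id == t]), numeric(1))
  names(p) <- trials
  if (!all(c(ci - 1, ci, ci + 1) %in% trials))
    oa_stop("usage_error",
            "catch trial %d needs both flanking trials in the table", ci)
  flank <- mean(p[as.character(c(ci - 1, ci + 1))])
  list(p_por = p,
       catch_index = ci,
       catch_p = unname(p[as.character(ci)]),
       flanker_mean = flank,
       catch_drop = unname(p[as.character(ci)]) - flank,
       n_animals = length(unique(table$animal_id)))
}
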