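# Mechanism-discrimination regressions (vesicle depletion vs lateral
# inhibition), ensemble spike-count timecourses, and exponential decay fits.

# shared OLS summary used by several modules; R^2 is defined as 0 (with a
# flag) when the response has zero variance, keeping pipelines total
.ols_fit <- function(x, y, xlab = "x", ylab = "y") {
  n <- length(x)
  if (n != length(y))
    oa_stop("alignment_error", "%s and %s differ in length", xlab, ylab)
  if (n < 2) oa_stop("usage_error", "need at least 2 observations")
  if (stats::var(x) == 0)
    oa_stop("degenerate_error", "all %s values are equal; OLS undefined",
            xlab)
  fit <- stats::lm(y ~ x)
  degenerate <- stats::var(y) == 0
  r2 <- if (degenerate) 0 else
    1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, n = n, degenerate_response = degenerate),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): slope %.4g, intercept %.4g, R^2 = %.3f%s\n",
              x$n, x$slope, x$intercept, x$r_squared,
              if (isTRUE(x$degenerate_response))
                " (zero-variance response)" else ""))
  if (!is.null(x$verdict)) cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Per-unit response change between two trials
#'
#' For every unit, the in-window spike count on the first and last selected
#' trials and their difference `delta = r_last - r_first`; negative deltas
#' are response reductions.
#'
#' @param tensor A [trial_tensor()].
#' @param first,last Trial indices (or labels); must differ.
#' @return A data frame with columns `unit_id`, `r_first`, `r_last`,
#'   `delta`, one row per unit.
#' @export
response_change <- function(tensor, first = 1,
                            last = dim(tensor$counts)[3]) {
  stopifnot(inherits(tensor, "trial_tensor"))
  first <- .resolve_trials(tensor, first)
  last <- .resolve_trials(tensor, last)
  if (length(first) != 1L || length(last) != 1L)
    oa_stop("usage_error", "first and last must each select one trial")
  if (first == last)
    oa_stop("usage_error", "first and last trials must differ")
  I <- dim(tensor$counts)[1]
  rf <- rowSums(matrix(tensor$counts[, , first], nrow = I))
  rl <- rowSums(matrix(tensor$counts[, , last], nrow = I))
  data.frame(unit_id = tensor$unit_labels, r_first = rf, r_last = rl,
             delta = rl - rf, stringsAsFactors = FALSE)
}

#' Discriminate adaptation mechanisms from response changes
#'
#' Ordinary least squares of the per-unit response change on the trial-1
#' response. A negative slope — strong responders losing the most spikes —
#' is the vesicle-depletion signature; a positive slope — weak responders
#' suppressed hardest — is the lateral-inhibition-facilitation signature.
#'
#' @param records Output of [response_change()] (requires at least two
#'   distinct `r_first` values).
#' @return A `regression_fit` (slope, intercept, `r_squared`, `n`) with a
#'   `verdict` field: `"depletion-like"`, `"inhibition-like"` or
#'   `"indeterminate"` (zero slope).
#' @export
depletion_vs_inhibition_fit <- function(records) {
  fit <- .ols_fit(records$r_first, records$delta, "r_first", "delta")
  fit$verdict <- if (fit$slope < 0) "depletion-like"
                 else if (fit$slope > 0) "inhibition-like"
                 else "indeterminate"
  fit
}

#' Cross-intensity consistency of per-unit adaptation
#'
#' Regresses each unit's response change at high intensity on its change at
#' low intensity of the same odor. A low R-squared means the units that
#' adapt most at one concentration are not the ones that adapt at the
#' other — per-unit adaptation is not predictable across intensities.
#'
#' @param records_high,records_low [response_change()] outputs over the same
#'   unit set (any order; units are aligned by id).
#' @return A `regression_fit` of `delta_high` on `delta_low`.
#' @export
cross_intensity_change_fit <- function(records_high, records_low) {
  if (!setequal(records_high$unit_id, records_low$unit_id) ||
      nrow(records_high) != nrow(records_low))
    oa_stop("alignment_error",
            "record lists must cover the identical unit set")
  m <- match(records_high$unit_id, records_low$unit_id)
  .ols_fit(records_low$delta[m], records_high$delta,
           "delta_low", "delta_high")
}

#' Ensemble spike-count timecourse
#'
#' Total in-window spikes summed over all units, per trial, in trial order —
#' the ensemble-level view of adaptation.
#'
#' @param tensor A [trial_tensor()].
#' @return Named numeric vector, one total per trial.
#' @export
ensemble_count_timecourse <- function(tensor) {
  stopifnot(inherits(tensor, "trial_tensor"))
  out <- apply(tensor$counts, 3, sum)
  names(out) <- tensor$trial_labels
  out
}

#' Fit an exponential adaptation decay to a count timecourse
#'
#' Fits `y_k = y_inf + (y_1 - y_inf) * exp(-(k - 1) / tau)` by profiled
#' least squares: for each candidate `tau` the two linear coefficients have
#' a closed-form solution, and the best `tau` is refined by golden-section
#' search. The recovered plateau is the asymptote-to-initial ratio of the
#' baseline-corrected fit, `(y_inf - baseline) / (y_1 - baseline)` —
#' subtract the expected baseline spike mass (e.g. from
#' [baseline_window_counts()]) to recover the evoked-response plateau.
#'
#' @param counts Numeric vector of per-trial totals in trial order
#'   (length >= 4).
#' @param baseline Expected non-evoked (spontaneous) count contribution per
#'   trial (default 0).
#' @return A list with `tau`, `y1` (fitted trial-1 value), `y_inf`
#'   (asymptote), `plateau`, `fitted` values and the residual `sse`.
#' @export
fit_adaptation_decay <- function(counts, baseline = 0) {
  y <- as.numeric(counts)
  n <- length(y)
  if (n < 4) oa_stop("usage_error", "need at least 4 trials to fit a decay")
  k <- seq_len(n)
  profile_sse <- function(tau) {
    z <- exp(-(k - 1) / tau)
    fit <- stats::lm(y ~ z)
    sum(stats::resid(fit)^2)
  }
  grid <- exp(seq(log(0.25), log(4 * n), length.out = 60))
  sses <- vapply(grid, profile_sse, numeric(1))
  i <- which.min(sses)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  tau <- stats::optimize(profile_sse, c(lo, hi))$minimum
  z <- exp(-(k - 1) / tau)
  fit <- stats::lm(y ~ z)
  a <- unname(stats::coef(fit)[1])   # asymptote
  b <- unname(stats::coef(fit)[2])   # amplitude at k = 1
  y1 <- a + b
  plateau <- if (abs(y1 - baseline) < .Machine$double.eps) NA_real_
             else (a - baseline) / (y1 - baseline)
  list(tau = tau, y1 = y1, y_inf = a, plateau = plateau,
       fitted = unname(stats::fitted(fit)), sse = sum(stats::resid(fit)^2))
}

#' Estimate per-trial baseline spike mass from pre-stimulus activity
#'
#' Uses spikes in a pre-stimulus window to estimate the spontaneous firing
#' rate, scaled to the expected non-evoked spike count contributed to one
#' trial's odor window by the whole ensemble.
#'
#' @param events A spike-event table containing pre-stimulus spikes.
#' @param protocol The session's [stimulus_protocol()].
#' @param pre_window Length-2 numeric window (seconds relative to onset)
#'   over which baseline spikes were recorded (default `c(-1, 0)`).
#' @return Expected baseline ensemble spike count per trial (scalar).
#' @export
baseline_window_counts <- function(events, protocol, pre_window = c(-1, 0)) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (pre_window[1] >= pre_window[2] ||
      pre_window[2] > protocol$odor_window_s[1])
    oa_stop("usage_error", "pre_window must precede the odor window")
  n_tr <- length(protocol$block_sequence) * protocol$n_trials_per_block
  n_pre <- sum(events$spike_time_s >= pre_window[1] &
                 events$spike_time_s < pre_window[2])
  (n_pre / (n_tr * diff(pre_window))) * diff(protocol$odor_window_s)
}
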