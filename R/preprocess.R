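# Binning spike events into Neuron x Time x Trial tensors, PSTHs,
# population vectors, and unit quality-control filtering.

#' Neuron x Time x Trial count tensor
#'
#' The central container of all ensemble analyses: an integer array of spike
#' counts indexed (unit, time bin, trial), with named axes. The trial axis
#' concatenates blocks in presentation order (stimulus identity is carried in
#' `stimulus_labels`, one per trial slice).
#'
#' @param counts 3-d integer-valued array, dimensions
#'   units x bins x trials, all values non-negative.
#' @param bin_edges_s Numeric vector of bin edges, length `n_bins + 1`.
#' @param unit_labels Character vector, one label per unit row.
#' @param trial_numbers Integer vector of 1-based within-block trial numbers,
#'   one per trial slice.
#' @param stimulus_labels Character vector of stimulus labels, one per trial
#'   slice.
#' @param block_labels Optional character vector of block labels, one per
#'   trial slice.
#' @return An object of class `trial_tensor` with fields `counts`,
#'   `bin_edges_s`, `unit_labels`, `trial_numbers`, `stimulus_labels`,
#'   `block_labels` and derived unique `trial_labels`.
#' @export
trial_tensor <- function(counts, bin_edges_s, unit_labels, trial_numbers,
                         stimulus_labels, block_labels = NULL) {
  if (!is.array(counts) || length(dim(counts)) != 3L)
    oa_stop("validation_error", "counts must be a 3-d array")
  d <- dim(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    oa_stop("validation_error", "counts must be finite and non-negative")
  if (max(abs(counts - round(counts))) > 1e-9)
    oa_stop("validation_error", "counts must be integer-valued")
  if (length(bin_edges_s) != d[2] + 1L)
    oa_stop("validation_error",
            "bin_edges_s must have length n_bins + 1 (%d), got %d",
            d[2] + 1L, length(bin_edges_s))
  if (is.unsorted(bin_edges_s, strictly = TRUE))
    oa_stop("validation_error", "bin edges must be strictly increasing")
  if (length(unit_labels) != d[1])
    oa_stop("validation_error", "unit_labels length must match unit axis")
  if (length(trial_numbers) != d[3] || length(stimulus_labels) != d[3])
    oa_stop("validation_error",
            "trial_numbers and stimulus_labels must match the trial axis")
  if (is.null(block_labels)) block_labels <- rep("b1", d[3])
  if (length(block_labels) != d[3])
    oa_stop("validation_error", "block_labels must match the trial axis")
  trial_labels <- paste0(block_labels, ":t", trial_numbers)
  if (anyDuplicated(trial_labels))
    oa_stop("validation_error", "(block, trial) pairs must be unique")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(unit_labels, NULL, trial_labels)
  structure(
    list(counts = counts,
         bin_edges_s = as.numeric(bin_edges_s),
         unit_labels = as.character(unit_labels),
         trial_numbers = as.integer(trial_numbers),
         stimulus_labels = as.character(stimulus_labels),
         block_labels = as.character(block_labels),
         trial_labels = trial_labels),
    class = "trial_tensor"
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("Trial tensor: %d units x %d bins x %d trials, %d spikes\n",
              d[1], d[2], d[3], sum(x$counts)))
  cat("  stimuli:", paste(unique(x$stimulus_labels), collapse = ", "), "\n")
  invisible(x)
}

#' Bin spike events into a trial tensor
#'
#' Counts spikes in non-overlapping half-open bins `[t, t + dt)` across the
#' odor presentation window. Spikes outside the window (including a spike
#' falling exactly on the window end) are excluded, so the total tensor mass
#' equals the number of in-window events.
#'
#' @param events A spike-event table (see [read_spike_events()]).
#' @param protocol The [stimulus_protocol()] the events follow.
#' @param units Optional character vector fixing the unit axis (useful when
#'   some units fired no spikes, or for an empty event table). Defaults to
#'   the sorted unique `unit_id` values present.
#' @return A [trial_tensor()] whose trial axis enumerates every protocol
#'   trial in presentation order.
#' @export
bin_spikes <- function(events, protocol, units = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  events <- validate_spike_events(as.data.frame(events), protocol)
  if (is.null(units)) units <- sort(unique(events$unit_id))
  units <- as.character(units)
  tt <- protocol_trial_table(protocol)
  J <- n_bins(protocol)
  I <- length(units)
  K <- nrow(tt)
  w0 <- protocol$odor_window_s[1]
  w1 <- protocol$odor_window_s[2]
  bw <- protocol$bin_width_s
  counts <- array(0L, dim = c(I, J, K))
  if (nrow(events)) {
    unknown <- setdiff(unique(events$unit_id), units)
    if (length(unknown))
      oa_stop("validation_error", "events contain unit(s) not in `units`: %s",
              paste(unknown, collapse = ", "))
    keep <- events$spike_time_s >= w0 & events$spike_time_s < w1
    ev <- events[keep, , drop = FALSE]
    if (nrow(ev)) {
      i <- match(ev$unit_id, units)
      j <- pmin(floor((ev$spike_time_s - w0) / bw) + 1L, J)
      k <- match(paste(ev$block_id, ev$trial_id), paste(tt$block, tt$trial))
      idx <- (k - 1L) * I * J + (j - 1L) * I + i
      counts <- array(tabulate(idx, nbins = I * J * K), dim = c(I, J, K))
    }
  }
  trial_tensor(counts,
               bin_edges_s = seq(w0, w1, by = bw),
               unit_labels = units,
               trial_numbers = tt$trial,
               stimulus_labels = tt$stimulus,
               block_labels = tt$block_label)
}

.resolve_trials <- function(tensor, trials) {
  K <- dim(tensor$counts)[3]
  if (is.character(trials)) {
    idx <- match(trials, tensor$trial_labels)
    if (anyNA(idx))
      oa_stop("usage_error", "unknown trial label(s): %s",
              paste(trials[is.na(idx)], collapse = ", "))
    return(idx)
  }
  if (is.logical(trials)) trials <- which(trials)
  trials <- as.integer(trials)
  if (length(trials) == 0L)
    oa_stop("usage_error", "trial selector must be non-empty")
  if (any(trials < 1L | trials > K))
    oa_stop("usage_error", "trial index outside 1..%d", K)
  trials
}

#' Peristimulus time histogram
#'
#' Mean spike count per time bin, averaged across units and the selected
#' trials. Units are spikes per bin per unit; divide by the bin width for a
#' firing rate in Hz.
#'
#' @param tensor A [trial_tensor()].
#' @param trials Trial selector: integer indices, logical mask or trial
#'   labels. Must be non-empty.
#' @return Numeric vector with one value per time bin.
#' @export
psth <- function(tensor, trials = seq_len(dim(tensor$counts)[3])) {
  stopifnot(inherits(tensor, "trial_tensor"))
  trials <- .resolve_trials(tensor, trials)
  sub <- tensor$counts[, , trials, drop = FALSE]
  apply(sub, 2, mean)
}

#' Per-trial population activity vector
#'
#' Collapses one trial slice of the tensor to a neuron-dimensional activity
#' vector. `sum_window` gives each unit's total in-window spike count (used
#' for dendrogram/classification analyses); `mean_per_bin` gives the
#' time-averaged count per bin (the correlation-analysis convention). The
#' two differ only by the positive factor `1/n_bins`, so Pearson
#' correlations between trials are identical under either reduction.
#'
#' @param tensor A [trial_tensor()].
#' @param trial A single trial index or trial label.
#' @param reduction `"sum_window"` or `"mean_per_bin"`.
#' @return An object of class `population_vector` with fields `values`
#'   (named by unit), `trial_label`, `stimulus_label`, `reduction`.
#' @export
population_vector <- function(tensor, trial,
                              reduction = c("sum_window", "mean_per_bin")) {
  stopifnot(inherits(tensor, "trial_tensor"))
  reduction <- tryCatch(match.arg(reduction), error = function(e)
    oa_stop("usage_error", "unknown reduction '%s'", reduction[1]))
  trial <- .resolve_trials(tensor, trial)
  if (length(trial) != 1L)
    oa_stop("usage_error", "population_vector takes a single trial")
  v <- rowSums(matrix(tensor$counts[, , trial], nrow = dim(tensor$counts)[1]))
  if (reduction == "mean_per_bin") v <- v / dim(tensor$counts)[2]
  names(v) <- tensor$unit_labels
  structure(
    list(values = v,
         trial_label = tensor$trial_labels[trial],
         stimulus_label = tensor$stimulus_labels[trial],
         reduction = reduction),
    class = "population_vector"
  )
}

#' Unit quality-control filter on spike-sorting summary metrics
#'
#' Applies the single-unit acceptance rule used for extracellular
#' projection-neuron recordings: a unit passes only if its cluster
#' separation exceeds 5 noise standard deviations, the fraction of its
#' spikes falling within 20 ms of another spike of the same unit is below
#' 6.5%, and its spike waveform variance is below 6.5 noise units. All
#' three inequalities are strict; a unit sitting exactly on a boundary
#' fails. Metrics are consumed as precomputed summaries — raw waveforms are
#' out of scope.
#'
#' @param metrics Data frame with columns `unit_id`,
#'   `cluster_separation_noise_sd`, `isi_violation_fraction`,
#'   `waveform_variance_noise_sd`.
#' @param separation_min Strict lower bound on cluster separation
#'   (default 5).
#' @param isi_max Strict upper bound on the 20-ms ISI-violation fraction
#'   (default 0.065).
#' @param waveform_var_max Strict upper bound on waveform variance
#'   (default 6.5).
#' @return Character vector of passing unit ids, with a logical `pass`
#'   attribute aligned to the input rows.
#' @export
unit_qc_filter <- function(metrics, separation_min = 5, isi_max = 0.065,
                           waveform_var_max = 6.5) {
  req <- c("unit_id", "cluster_separation_noise_sd",
           "isi_violation_fraction", "waveform_variance_noise_sd")
  miss <- setdiff(req, names(metrics))
  if (length(miss))
    oa_stop("validation_error", "metrics table missing column(s): %s",
            paste(miss, collapse = ", "))
  m <- metrics[req]
  num <- m[-1]
  if (any(vapply(num, function(x) anyNA(x) || !is.numeric(x), logical(1))))
    oa_stop("validation_error", "all QC metrics must be present and numeric")
  if (any(unlist(num) < 0))
    oa_stop("validation_error", "QC metrics must be non-negative")
  pass <- m$cluster_separation_noise_sd > separation_min &
    m$isi_violation_fraction < isi_max &
    m$waveform_variance_noise_sd < waveform_var_max
  structure(as.character(m$unit_id[pass]), pass = pass)
}
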