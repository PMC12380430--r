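# On-disk formats: spike-event CSV, behavior CSV, tensor container.
# All text tables are comma-delimited, UTF-8, '.' decimal, mandatory header.

.spike_cols <- c("unit_id", "block_id", "trial_id", "stimulus_label",
                 "spike_time_s")
.behavior_cols <- c("animal_id", "trial_id", "stimulus_label", "por")

.read_csv_checked <- function(path, required) {
  if (!file.exists(path))
    oa_stop("format_error", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    oa_stop("format_error", "missing required column(s): %s",
            paste(miss, collapse = ", "))
  df[required]
}

.parse_numeric_col <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad) == 0L) bad <- which(is.na(out))
  if (length(bad))
    oa_stop("parse_error", "non-numeric %s at data row %d: '%s'",
            col, bad[1], x[bad[1]])
  out
}

#' Read a spike-event table
#'
#' Reads and validates a comma-delimited spike-event file with columns
#' `unit_id, block_id, trial_id, stimulus_label, spike_time_s`. Spike times
#' are seconds relative to odor onset and may be negative (pre-stimulus
#' spikes). Every event is checked against the declared protocol: `block_id`
#' must be a 1-based block index into the protocol's block sequence,
#' `trial_id` must lie within the block length, and `stimulus_label` must
#' match the stimulus the protocol presents on that (block, trial).
#'
#' @param path Path to a CSV file.
#' @param protocol A [stimulus_protocol()] the events must conform to.
#' @return A `spike_events` data frame (also plain `data.frame`) with the
#'   five canonical columns; `trial_id` and `block_id` integer,
#'   `spike_time_s` numeric.
#' @export
read_spike_events <- function(path, protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  df <- .read_csv_checked(path, .spike_cols)
  out <- data.frame(
    unit_id = as.character(df$unit_id),
    block_id = as.integer(.parse_numeric_col(df$block_id, "block_id")),
    trial_id = as.integer(.parse_numeric_col(df$trial_id, "trial_id")),
    stimulus_label = as.character(df$stimulus_label),
    spike_time_s = .parse_numeric_col(df$spike_time_s, "spike_time_s"),
    stringsAsFactors = FALSE
  )
  validate_spike_events(out, protocol)
}

#' Validate a spike-event table against a protocol
#'
#' @param events A data frame with the spike-event columns.
#' @param protocol A [stimulus_protocol()].
#' @return The validated table, classed `spike_events`.
#' @export
validate_spike_events <- function(events, protocol) {
  miss <- setdiff(.spike_cols, names(events))
  if (length(miss))
    oa_stop("format_error", "missing required column(s): %s",
            paste(miss, collapse = ", "))
  if (nrow(events)) {
    if (any(!is.finite(events$spike_time_s)))
      oa_stop("validation_error", "spike times must be finite")
    nb <- length(protocol$block_sequence)
    if (any(events$block_id < 1L | events$block_id > nb))
      oa_stop("validation_error",
              "block_id outside 1..%d declared blocks", nb)
    if (any(events$trial_id < 1L |
            events$trial_id > protocol$n_trials_per_block))
      oa_stop("validation_error",
              "trial_id outside 1..%d trials declared by the protocol",
              protocol$n_trials_per_block)
    tt <- protocol_trial_table(protocol)
    key <- paste(events$block_id, events$trial_id)
    expected <- tt$stimulus[match(key, paste(tt$block, tt$trial))]
    bad <- which(events$stimulus_label != expected)
    if (length(bad))
      oa_stop("validation_error",
              "stimulus_label '%s' does not match protocol stimulus '%s' for block %d trial %d",
              events$stimulus_label[bad[1]], expected[bad[1]],
              events$block_id[bad[1]], events$trial_id[bad[1]])
  }
  class(events) <- c("spike_events", "data.frame")
  events
}

#' @rdname read_spike_events
#' @param events A spike-event table to write.
#' @export
write_spike_events <- function(events, path) {
  utils::write.csv(as.data.frame(events)[.spike_cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a behavioral response table
#'
#' Reads a comma-delimited table of hand-scored palp-opening responses
#' (PORs) with columns `animal_id, trial_id, stimulus_label, por`. The `por`
#' column must come from the explicit binary set `{0, 1, true, false}`
#' (case-insensitive); any other value is a parse error — there is no silent
#' coercion. Each (animal, trial, stimulus) combination must be unique.
#'
#' @param path Path to a CSV file.
#' @return A `behavior_table` data frame with logical `por`.
#' @export
read_behavior_table <- function(path) {
  df <- .read_csv_checked(path, .behavior_cols)
  por_raw <- tolower(trimws(df$por))
  lut <- c("0" = FALSE, "1" = TRUE, "false" = FALSE, "true" = TRUE)
  bad <- which(!(por_raw %in% names(lut)))
  if (length(bad))
    oa_stop("parse_error",
            "por value '%s' at data row %d is outside the binary set {0,1,true,false}",
            df$por[bad[1]], bad[1])
  out <- data.frame(
    animal_id = as.character(df$animal_id),
    trial_id = as.integer(.parse_numeric_col(df$trial_id, "trial_id")),
    stimulus_label = as.character(df$stimulus_label),
    por = unname(lut[por_raw]),
    stringsAsFactors = FALSE
  )
  validate_behavior_table(out)
}

#' Validate a behavioral response table
#'
#' @param table A data frame with behavior-table columns.
#' @return The validated table, classed `behavior_table`.
#' @export
validate_behavior_table <- function(table) {
  miss <- setdiff(.behavior_cols, names(table))
  if (length(miss))
    oa_stop("format_error", "missing required column(s): %s",
            paste(miss, collapse = ", "))
  if (!is.logical(table$por) || anyNA(table$por))
    oa_stop("validation_error", "por must be strictly binary (logical)")
  key <- paste(table$animal_id, table$trial_id, table$stimulus_label)
  if (anyDuplicated(key))
    oa_stop("validation_error",
            "duplicate (animal_id, trial_id, stimulus_label) rows: %s",
            key[duplicated(key)][1])
  if (nrow(table) && any(table$trial_id < 1L))
    oa_stop("validation_error", "trial_id must be a positive integer")
  class(table) <- c("behavior_table", "data.frame")
  table
}

#' @rdname read_behavior_table
#' @param table A behavior table to write.
#' @export
write_behavior_table <- function(table, path) {
  out <- as.data.frame(table)[.behavior_cols]
  out$por <- as.integer(out$por)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist or load a trial tensor
#'
#' Trial tensors persist in a named-axis serialized container (one dataset
#' for the counts, one per axis for the unit labels, bin edges and trial
#' metadata), so that axis order and labels survive a round trip bit-exactly
#' and silent axis transposition is impossible. A truncated or mislabelled
#' file raises an integrity error.
#'
#' @param tensor A [trial_tensor()].
#' @param path File path.
#' @return `read_tensor` returns the validated [trial_tensor()];
#'   `write_tensor` returns `path` invisibly.
#' @export
write_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "trial_tensor"))
  payload <- list(
    format = "odoradapt_trial_tensor",
    version = 1L,
    counts = unclass(tensor$counts),
    bin_edges_s = tensor$bin_edges_s,
    unit_labels = tensor$unit_labels,
    trial_numbers = tensor$trial_numbers,
    stimulus_labels = tensor$stimulus_labels,
    block_labels = tensor$block_labels
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(path) {
  if (!file.exists(path))
    oa_stop("integrity_error", "tensor file not found: %s", path)
  payload <- tryCatch(readRDS(path), error = function(e)
    oa_stop("integrity_error", "cannot read tensor container (%s)",
            conditionMessage(e)))
  if (!is.list(payload) ||
      !identical(payload$format, "odoradapt_trial_tensor"))
    oa_stop("integrity_error", "file is not an odoradapt tensor container")
  tryCatch(
    trial_tensor(counts = payload$counts,
                 bin_edges_s = payload$bin_edges_s,
                 unit_labels = payload$unit_labels,
                 trial_numbers = payload$trial_numbers,
                 stimulus_labels = payload$stimulus_labels,
                 block_labels = payload$block_labels),
    odoradapt_error = function(e)
      oa_stop("integrity_error", "tensor container fails validation: %s",
              conditionMessage(e))
  )
}
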