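#' Stimulus protocol description
#'
#' Describes a block-structured odor stimulation protocol: each block presents
#' one stimulus (an odor at one intensity) for a fixed number of trials, with
#' spikes analyzed inside a fixed odor-presentation window that is divided
#' into non-overlapping bins. A protocol may optionally declare a catch
#' (deviant-stimulus) trial embedded in each block.
#'
#' Trial numbering is 1-based within a block, so "the 26th trial" refers to
#' `trial_id == 26`. Spike times are seconds relative to odor onset
#' (onset = 0), and the analysis window is the half-open interval
#' `[odor_window_s[1], odor_window_s[2])`.
#'
#' @param block_sequence Character vector of stimulus labels, one per block,
#'   in presentation order. Labels conventionally end in `"_H"` or `"_L"`
#'   to mark high (1% v/v) and low (0.1% v/v) intensity.
#' @param n_trials_per_block Number of trials in every block.
#' @param odor_window_s Length-2 numeric, start and end of the odor
#'   presentation window in seconds (default `c(0, 4)`).
#' @param bin_width_s Width of the non-overlapping count bins in seconds
#'   (default 0.05, i.e. 50 ms). Must divide the window length.
#' @param inter_trial_interval_s Seconds between trial onsets (default 60).
#' @param reset_interval_min No-stimulation minutes separating blocks
#'   (default 15).
#' @param catch_trial_index Optional 1-based trial index at which the catch
#'   stimulus replaces the block's stimulus.
#' @param catch_stimulus Optional stimulus label presented on the catch trial.
#'
#' @return An object of class `stimulus_protocol`.
#' @seealso [protocol_trial_table()], [read_protocol()]
#' @export
stimulus_protocol <- function(block_sequence,
                              n_trials_per_block,
                              odor_window_s = c(0, 4),
                              bin_width_s = 0.05,
                              inter_trial_interval_s = 60,
                              reset_interval_min = 15,
                              catch_trial_index = NULL,
                              catch_stimulus = NULL) {
  if (!is.character(block_sequence) || length(block_sequence) < 1L)
    oa_stop("validation_error", "block_sequence must be a non-empty character vector")
  if (!is_count(n_trials_per_block) || n_trials_per_block < 1)
    oa_stop("validation_error", "n_trials_per_block must be a positive integer")
  if (!is.numeric(odor_window_s) || length(odor_window_s) != 2L ||
      any(!is.finite(odor_window_s)) || odor_window_s[1] >= odor_window_s[2])
    oa_stop("validation_error", "odor_window_s must be [start, end] with start < end")
  if (!is.numeric(bin_width_s) || length(bin_width_s) != 1L ||
      !is.finite(bin_width_s) || bin_width_s <= 0)
    oa_stop("validation_error", "bin_width_s must be a positive number")
  win <- diff(odor_window_s)
  n_bins <- win / bin_width_s
  if (abs(n_bins - round(n_bins)) > 1e-8)
    oa_stop("validation_error",
            "bin_width_s (%g) must divide the odor window length (%g)",
            bin_width_s, win)
  if (xor(is.null(catch_trial_index), is.null(catch_stimulus)))
    oa_stop("validation_error",
            "catch_trial_index and catch_stimulus must be declared together")
  if (!is.null(catch_trial_index)) {
    if (!is_count(catch_trial_index) ||
        catch_trial_index < 1 || catch_trial_index > n_trials_per_block)
      oa_stop("validation_error",
              "catch_trial_index must lie within 1..n_trials_per_block")
    if (!is.character(catch_stimulus) || length(catch_stimulus) != 1L)
      oa_stop("validation_error", "catch_stimulus must be a single label")
  }
  structure(
    list(block_sequence = as.character(block_sequence),
         n_trials_per_block = as.integer(n_trials_per_block),
         odor_window_s = as.numeric(odor_window_s),
         bin_width_s = as.numeric(bin_width_s),
         inter_trial_interval_s = as.numeric(inter_trial_interval_s),
         reset_interval_min = as.numeric(reset_interval_min),
         catch_trial_index = if (is.null(catch_trial_index)) NULL
                             else as.integer(catch_trial_index),
         catch_stimulus = catch_stimulus),
    class = "stimulus_protocol"
  )
}

#' Number of count bins in the odor window of a protocol
#'
#' @param protocol A [stimulus_protocol()].
#' @return Integer number of bins.
#' @export
n_bins <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  as.integer(round(diff(protocol$odor_window_s) / protocol$bin_width_s))
}

#' Enumerate the trials of a protocol
#'
#' Expands a protocol into one row per presented trial, in presentation order:
#' block index, block label, 1-based trial number within the block, the
#' stimulus shown on that trial (the catch stimulus on the catch trial) and
#' whether the trial is the catch trial.
#'
#' @param protocol A [stimulus_protocol()].
#' @return A data frame with columns `block`, `block_label`, `trial`,
#'   `stimulus`, `is_catch`.
#' @export
protocol_trial_table <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  nb <- length(protocol$block_sequence)
  nt <- protocol$n_trials_per_block
  out <- data.frame(
    block = rep(seq_len(nb), each = nt),
    block_label = rep(paste0("b", seq_len(nb)), each = nt),
    trial = rep(seq_len(nt), times = nb),
    stimulus = rep(protocol$block_sequence, each = nt),
    is_catch = FALSE,
    stringsAsFactors = FALSE
  )
  if (!is.null(protocol$catch_trial_index)) {
    hit <- out$trial == protocol$catch_trial_index
    out$stimulus[hit] <- protocol$catch_stimulus
    out$is_catch[hit] <- TRUE
  }
  out
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("Stimulus protocol:", length(x$block_sequence), "block(s) x",
      x$n_trials_per_block, "trials\n")
  cat("  blocks:", paste(x$block_sequence, collapse = ", "), "\n")
  cat(sprintf("  odor window [%g, %g) s, %g ms bins, ITI %g s, reset %g min\n",
              x$odor_window_s[1], x$odor_window_s[2], 1000 * x$bin_width_s,
              x$inter_trial_interval_s, x$reset_interval_min))
  if (!is.null(x$catch_trial_index))
    cat(sprintf("  catch trial %d -> %s\n", x$catch_trial_index,
                x$catch_stimulus))
  invisible(x)
}

#' Read or write a stimulus protocol config file
#'
#' Protocols persist as YAML key-value files mirroring the
#' [stimulus_protocol()] fields; reading re-validates all invariants.
#'
#' @param path File path.
#' @param protocol A [stimulus_protocol()] (for writing).
#' @return `read_protocol` returns a validated [stimulus_protocol()];
#'   `write_protocol` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path))
    oa_stop("format_error", "protocol file not found: %s", path)
  raw <- yaml::read_yaml(path)
  req <- c("block_sequence", "n_trials_per_block", "odor_window_s",
           "bin_width_s")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    oa_stop("format_error", "protocol file missing field(s): %s",
            paste(miss, collapse = ", "))
  stimulus_protocol(
    block_sequence = unlist(raw$block_sequence),
    n_trials_per_block = raw$n_trials_per_block,
    odor_window_s = unlist(raw$odor_window_s),
    bin_width_s = raw$bin_width_s,
    inter_trial_interval_s = raw$inter_trial_interval_s %||% 60,
    reset_interval_min = raw$reset_interval_min %||% 15,
    catch_trial_index = raw$catch_trial_index,
    catch_stimulus = raw$catch_stimulus
  )
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  yaml::write_yaml(protocol[!vapply(protocol, is.null, logical(1))], path)
  invisible(path)
}
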