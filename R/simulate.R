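# Seeded synthetic generators: Poisson spike-train sessions with odor-specific
# tuning, intensity-dependent ensemble rotation and trial-wise adaptation;
# catch-trial sessions; Bernoulli palp-opening-response behavior; and
# factor-structured tensors for decomposition benchmarks.

#' Adaptation mechanism specification
#'
#' Describes how trial-wise adaptation modifies odor-evoked firing:
#'
#' * `magnitude_only`: every unit's evoked rate is scaled by the common
#'   multiplier `m_k = plateau + (1 - plateau) * exp(-(k - 1) / tau_trials)`
#'   on trial `k` — response magnitude shrinks while the population-vector
#'   direction is exactly preserved.
#' * `vesicle_depletion`: suppression grows with a unit's own drive. The
#'   per-unit multiplier is
#'   `m_k(u) = 1 - strength * (1 - exp(-(k - 1) / tau_trials)) * r1(u) / max(r1)`
#'   where `r1(u)` is the unit's trial-1 evoked rate, so the strongest
#'   responders adapt the most (`strength` is a fraction in `[0, 1]`).
#' * `lateral_inhibition`: facilitating inhibition suppresses weak responders
#'   hardest. A rate of
#'   `strength * (1 - min(r1(u) / r_med, 1)) * (1 - exp(-(k - 1) / tau_trials))`
#'   Hz is subtracted from the unit's firing during the odor window, where
#'   `r_med` is the median evoked rate of the responsive units: units driven
#'   at or above the typical response level escape the strengthening
#'   inhibition entirely, while suppression grows linearly toward `strength`
#'   Hz for silent units (baseline suppression included, as odor-evoked
#'   inhibition of projection neurons produces). `strength` must not exceed
#'   the baseline rate or effective rates can go negative, which is a model
#'   error (never silently clipped).
#'
#' @param mechanism One of `"magnitude_only"`, `"vesicle_depletion"`,
#'   `"lateral_inhibition"`.
#' @param plateau Asymptotic fraction of the trial-1 evoked response retained
#'   under `magnitude_only`, in `(0, 1]` (default 0.45).
#' @param tau_trials Exponential time constant of adaptation, in trials
#'   (default 5).
#' @param strength Mechanism strength: a fraction in `[0, 1]` for
#'   `vesicle_depletion` (default 0.6), a rate in Hz for
#'   `lateral_inhibition` (default 3).
#' @return An object of class `adaptation_spec`.
#' @export
adaptation_spec <- function(mechanism = c("magnitude_only",
                                          "vesicle_depletion",
                                          "lateral_inhibition"),
                            plateau = 0.45, tau_trials = 5,
                            strength = NULL) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(plateau) || plateau <= 0 || plateau > 1)
    oa_stop("validation_error", "plateau must be in (0, 1]")
  if (!is.numeric(tau_trials) || tau_trials <= 0)
    oa_stop("validation_error", "tau_trials must be > 0")
  if (is.null(strength))
    strength <- switch(mechanism, magnitude_only = 0,
                       vesicle_depletion = 0.6, lateral_inhibition = 3)
  if (!is.numeric(strength) || strength < 0)
    oa_stop("validation_error", "strength must be >= 0")
  if (mechanism == "vesicle_depletion" && strength > 1)
    oa_stop("validation_error",
            "vesicle_depletion strength is a fraction and must be <= 1")
  structure(list(mechanism = mechanism, plateau = plateau,
                 tau_trials = tau_trials, strength = strength),
            class = "adaptation_spec")
}

#' Default rise-plateau-decay temporal response kernel
#'
#' Per-bin multiplier over the odor window with a fast onset rise, a
#' sustained plateau and a slow decay, normalized to unit peak — the typical
#' shape of odor-evoked projection-neuron firing.
#'
#' @param n_bins Number of bins across the odor window.
#' @param window_s Window length in seconds (default 4).
#' @param rise_s Onset rise time constant in seconds (default 0.15).
#' @param decay_s Slow decay time constant in seconds (default 2).
#' @param floor Late-window sustained fraction in `[0, 1)` (default 0.45).
#' @return Numeric vector of length `n_bins` with values in `[0, 1]`.
#' @export
default_temporal_kernel <- function(n_bins, window_s = 4, rise_s = 0.15,
                                    decay_s = 2, floor = 0.45) {
  t <- (seq_len(n_bins) - 0.5) * window_s / n_bins
  k <- (1 - exp(-t / rise_s)) * (floor + (1 - floor) * exp(-t / decay_s))
  k / max(k)
}

#' Synthetic projection-neuron population model
#'
#' Defines a population of Poisson-spiking units with odor-specific tuning.
#' For each odor, a random subset of units is responsive at high intensity,
#' with evoked gains drawn from a gamma distribution. Low-intensity tuning
#' equals `intensity_gain` times the high-intensity tuning for a fraction
#' `1 - rotation_fraction` of units; the remaining units have their
#' low-intensity tuning re-drawn independently, producing both an overall
#' magnitude reduction and a partial change in the activated combination —
#' including units that respond preferentially at the lower concentration.
#'
#' All tuning is generated deterministically from `seed`; a `tuning` matrix
#' (units x stimulus labels) can be supplied directly to override generation.
#'
#' @param n_units Number of units (default 80).
#' @param odors Character vector of odor names; each yields `"<odor>_H"` and
#'   `"<odor>_L"` stimulus labels (default `c("hex", "oct")`).
#' @param baseline_rate_hz Spontaneous firing rate in Hz (default 3).
#' @param responsive_fraction Probability a unit responds to a given odor
#'   (default 0.5).
#' @param gain_shape,gain_scale_hz Gamma parameters of evoked peak gains in
#'   Hz above baseline at full intensity on trial 1 (defaults 2 and 7.5,
#'   mean 15 Hz).
#' @param intensity_gain Multiplier applied to high-intensity tuning to form
#'   the conserved part of low-intensity tuning, in `(0, 1]` (default 0.5).
#' @param rotation_fraction Fraction of units whose low-intensity tuning is
#'   re-drawn, in `[0, 1]` (default 0.25).
#' @param temporal_kernel Optional per-bin multiplier vector (unit peak); if
#'   `NULL`, [default_temporal_kernel()] is evaluated at simulation time for
#'   the protocol's bin count.
#' @param adaptation An [adaptation_spec()] (default `magnitude_only`).
#' @param seed Integer seed for tuning generation.
#' @param tuning Optional non-negative matrix (units x stimuli) with stimulus
#'   labels as column names, overriding generated tuning.
#' @return An object of class `population_model`.
#' @export
population_model <- function(n_units = 80,
                             odors = c("hex", "oct"),
                             baseline_rate_hz = 3,
                             responsive_fraction = 0.5,
                             gain_shape = 2,
                             gain_scale_hz = 7.5,
                             intensity_gain = 0.5,
                             rotation_fraction = 0.25,
                             temporal_kernel = NULL,
                             adaptation = adaptation_spec(),
                             seed = 1,
                             tuning = NULL) {
  if (!is_count(n_units) || n_units < 1)
    oa_stop("validation_error", "n_units must be a positive integer")
  if (baseline_rate_hz < 0)
    oa_stop("validation_error", "baseline_rate_hz must be >= 0")
  if (intensity_gain <= 0 || intensity_gain > 1)
    oa_stop("validation_error", "intensity_gain must be in (0, 1]")
  if (rotation_fraction < 0 || rotation_fraction > 1)
    oa_stop("validation_error", "rotation_fraction must be in [0, 1]")
  if (!inherits(adaptation, "adaptation_spec"))
    oa_stop("validation_error", "adaptation must be an adaptation_spec")
  if (!is.null(temporal_kernel)) {
    if (any(temporal_kernel < 0 | temporal_kernel > 1))
      oa_stop("validation_error", "temporal_kernel values must be in [0, 1]")
  }
  if (is.null(tuning)) {
    tuning <- with_seed(seed, {
      cols <- list()
      for (od in odors) {
        resp <- stats::runif(n_units) < responsive_fraction
        g_h <- ifelse(resp,
                      stats::rgamma(n_units, shape = gain_shape,
                                    scale = gain_scale_hz), 0)
        rot <- stats::runif(n_units) < rotation_fraction
        resp_l <- stats::runif(n_units) < responsive_fraction
        g_l_new <- ifelse(resp_l,
                          stats::rgamma(n_units, shape = gain_shape,
                                        scale = gain_scale_hz), 0)
        g_l <- ifelse(rot, g_l_new, intensity_gain * g_h)
        cols[[paste0(od, "_H")]] <- g_h
        cols[[paste0(od, "_L")]] <- g_l
      }
      do.call(cbind, cols)
    })
    rownames(tuning) <- sprintf("u%03d", seq_len(n_units))
  } else {
    tuning <- as.matrix(tuning)
    if (is.null(colnames(tuning)))
      oa_stop("validation_error", "tuning matrix needs stimulus column names")
    if (nrow(tuning) != n_units)
      oa_stop("validation_error", "tuning must have n_units rows")
    if (any(tuning < 0))
      oa_stop("validation_error", "tuning gains must be >= 0")
    if (is.null(rownames(tuning)))
      rownames(tuning) <- sprintf("u%03d", seq_len(n_units))
  }
  structure(
    list(n_units = as.integer(n_units),
         odors = odors,
         baseline_rate_hz = baseline_rate_hz,
         responsive_fraction = responsive_fraction,
         gain_shape = gain_shape,
         gain_scale_hz = gain_scale_hz,
         intensity_gain = intensity_gain,
         rotation_fraction = rotation_fraction,
         temporal_kernel = temporal_kernel,
         adaptation = adaptation,
         seed = seed,
         tuning = tuning,
         unit_labels = rownames(tuning)),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("Population model: %d units, stimuli %s\n", x$n_units,
              paste(colnames(x$tuning), collapse = ", ")))
  cat(sprintf("  baseline %.2g Hz, adaptation: %s\n", x$baseline_rate_hz,
              x$adaptation$mechanism))
  invisible(x)
}

# Multiplicative (M) and subtractive (S, in Hz) adaptation terms for one
# stimulus across trials 1..n. Rows are units.
.adaptation_terms <- function(model, stimulus, n_trials) {
  ad <- model$adaptation
  k <- seq_len(n_trials)
  build <- as.numeric(1 - exp(-(k - 1) / ad$tau_trials))
  n <- model$n_units
  M <- matrix(1, n, n_trials)
  S <- matrix(0, n, n_trials)
  if (ad$mechanism == "magnitude_only") {
    mk <- ad$plateau + (1 - ad$plateau) * exp(-(k - 1) / ad$tau_trials)
    M <- matrix(mk, n, n_trials, byrow = TRUE)
  } else {
    r1 <- model$tuning[, stimulus]
    rel <- if (max(r1) > 0) r1 / max(r1) else rep(0, n)
    if (ad$mechanism == "vesicle_depletion") {
      M <- 1 - ad$strength * outer(rel, build)
    } else {
      ref <- if (any(r1 > 0)) stats::median(r1[r1 > 0]) else 1
      rel_inh <- pmin(r1 / ref, 1)
      S <- ad$strength * outer(1 - rel_inh, build)
    }
  }
  if (any(M < -1e-12))
    oa_stop("model_error",
            "adaptation produced a negative evoked-rate multiplier")
  list(M = M, S = S)
}

.model_kernel <- function(model, protocol) {
  J <- n_bins(protocol)
  k <- model$temporal_kernel %||%
    default_temporal_kernel(J, window_s = diff(protocol$odor_window_s))
  if (length(k) != J)
    oa_stop("model_error",
            "temporal_kernel length %d does not match %d protocol bins",
            length(k), J)
  k
}

# Draw one trial's spike events from piecewise-constant rates. Because the
# rate is constant within each bin, the inhomogeneous Poisson process is
# exactly a per-bin Poisson count with uniform spike times inside the bin.
.draw_trial_events <- function(lambda, protocol, pad_s, baseline) {
  J <- ncol(lambda)
  I <- nrow(lambda)
  bw <- protocol$bin_width_s
  w0 <- protocol$odor_window_s[1]
  cnt <- matrix(stats::rpois(I * J, lambda * bw), I, J)
  tot <- sum(cnt)
  unit <- integer(0); tm <- numeric(0)
  if (tot) {
    unit <- rep(rep(seq_len(I), J), as.vector(cnt))
    binj <- rep(rep(seq_len(J), each = I), as.vector(cnt))
    tm <- w0 + (binj - 1) * bw + stats::runif(tot) * bw
  }
  if (pad_s > 0 && baseline > 0) {
    for (side in c(-1, 1)) {
      nb <- stats::rpois(I, baseline * pad_s)
      if (sum(nb)) {
        unit <- c(unit, rep(seq_len(I), nb))
        t0 <- if (side < 0) w0 - pad_s else protocol$odor_window_s[2]
        tm <- c(tm, t0 + stats::runif(sum(nb)) * pad_s)
      }
    }
  }
  list(unit = unit, time = tm)
}

.simulate_engine <- function(model, protocol, seed, cross_adaptation,
                             pad_s) {
  tt <- protocol_trial_table(protocol)
  kern <- .model_kernel(model, protocol)
  labels_needed <- unique(tt$stimulus)
  missing_stim <- setdiff(labels_needed, colnames(model$tuning))
  if (length(missing_stim))
    oa_stop("model_error", "stimulus absent from tuning table: %s",
            paste(missing_stim, collapse = ", "))
  terms <- lapply(unique(tt$stimulus[!tt$is_catch]), function(s)
    .adaptation_terms(model, s, protocol$n_trials_per_block))
  names(terms) <- unique(tt$stimulus[!tt$is_catch])
  with_seed(seed, {
    rows <- vector("list", nrow(tt))
    for (r in seq_len(nrow(tt))) {
      stim <- tt$stimulus[r]
      k <- tt$trial[r]
      if (tt$is_catch[r]) {
        # adaptation state of the repeated stimulus at the catch position,
        # coupled in by the cross-adaptation coefficient
        rep_stim <- protocol$block_sequence[tt$block[r]]
        ts <- terms[[rep_stim]]
        M <- 1 - cross_adaptation * (1 - ts$M[, k])
        S <- cross_adaptation * ts$S[, k]
      } else {
        ts <- terms[[stim]]
        M <- ts$M[, k]
        S <- ts$S[, k]
      }
      evoked <- M * model$tuning[, stim]
      lambda <- model$baseline_rate_hz +
        outer(evoked, kern) - S  # S recycles down columns (per unit)
      if (any(lambda < -1e-9))
        oa_stop("model_error",
                "negative effective firing rate (min %.3g Hz) for stimulus %s trial %d",
                min(lambda), stim, k)
      lambda[lambda < 0] <- 0  # clamp numerical -0
      ev <- .draw_trial_events(lambda, protocol, pad_s,
                               model$baseline_rate_hz)
      if (length(ev$unit)) {
        rows[[r]] <- data.frame(
          unit_id = model$unit_labels[ev$unit],
          block_id = tt$block[r],
          trial_id = k,
          stimulus_label = stim,
          spike_time_s = ev$time,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out))
      out <- data.frame(unit_id = character(0), block_id = integer(0),
                        trial_id = integer(0),
                        stimulus_label = character(0),
                        spike_time_s = numeric(0))
    ord <- order(out$block_id, out$trial_id, out$unit_id, out$spike_time_s)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    validate_spike_events(out, protocol)
  })
}

#' Simulate a spike-train session
#'
#' Draws spikes for every unit and trial of the protocol from an
#' inhomogeneous Poisson process whose rate during the odor window is
#' `baseline + m_k(u) * tuning(u, stimulus) * kernel(t) - s_k(u)` (the
#' multiplicative and subtractive adaptation terms of the model's
#' [adaptation_spec()]), and `baseline` elsewhere. Identical
#' `(model, protocol, seed)` give bit-identical tables. A negative effective
#' rate raises a model error rather than being clipped.
#'
#' @param model A [population_model()].
#' @param protocol A [stimulus_protocol()] without a catch trial (use
#'   [simulate_catch_session()] for catch designs).
#' @param seed Integer seed for spike generation.
#' @param pad_s Seconds of baseline-only spiking emitted before and after
#'   the odor window (default 1), providing pre-stimulus spikes for baseline
#'   estimation.
#' @return A validated spike-event table (see [read_spike_events()]).
#' @export
simulate_session <- function(model, protocol, seed = 1, pad_s = 1) {
  stopifnot(inherits(model, "population_model"),
            inherits(protocol, "stimulus_protocol"))
  if (!is.null(protocol$catch_trial_index))
    oa_stop("usage_error",
            "protocol declares a catch trial; use simulate_catch_session()")
  .simulate_engine(model, protocol, seed, cross_adaptation = 0, pad_s = pad_s)
}

#' Simulate a catch-trial spike-train session
#'
#' Like [simulate_session()] but the protocol's catch trial presents the
#' deviant stimulus. The catch trial uses the catch stimulus' tuning at an
#' adaptation state controlled by `cross_adaptation`: with 0 the deviant is
#' presented fully unadapted (its expected counts equal its own trial-1
#' counts); with 1 it inherits the full adapted state the repeated stimulus
#' has reached at the catch position; intermediate values interpolate,
#' emulating partial cross-adaptation between chemically related stimuli.
#'
#' @inheritParams simulate_session
#' @param protocol A [stimulus_protocol()] declaring `catch_trial_index` and
#'   `catch_stimulus`.
#' @param cross_adaptation Coupling coefficient in `[0, 1]` (default 0).
#' @return A validated spike-event table.
#' @export
simulate_catch_session <- function(model, protocol, seed = 1,
                                   cross_adaptation = 0, pad_s = 1) {
  stopifnot(inherits(model, "population_model"),
            inherits(protocol, "stimulus_protocol"))
  if (is.null(protocol$catch_trial_index))
    oa_stop("usage_error", "protocol must declare a catch trial")
  if (cross_adaptation < 0 || cross_adaptation > 1)
    oa_stop("usage_error", "cross_adaptation must be in [0, 1]")
  if (!(protocol$catch_stimulus %in% colnames(model$tuning)))
    oa_stop("model_error", "catch stimulus '%s' absent from tuning table",
            protocol$catch_stimulus)
  .simulate_engine(model, protocol, seed, cross_adaptation, pad_s)
}

#' Behavioral facilitation model
#'
#' Palp-opening responses are Bernoulli draws whose probability facilitates
#' across presentations of the same stimulus:
#' `p_k = p_inf + (p0 - p_inf) * exp(-(k - 1) / tau_trials)`, with the
#' asymptote `p_inf` depending on stimulus intensity (labels ending `"_L"`
#' use `p_inf_low`, all others `p_inf_high`). On a catch trial the deviant
#' stimulus is scored at its own unadapted probability `p0_catch`
#' (defaulting to `p0`), and the repeated stimulus' facilitation clock does
#' not advance.
#'
#' @param p0 Trial-1 response probability (default 0.15).
#' @param p_inf_low,p_inf_high Asymptotic probabilities for low- and
#'   high-intensity stimuli (defaults 0.35 and 0.6). Facilitation requires
#'   `p_inf >= p0`.
#' @param tau_trials Facilitation time constant in trials (default 2).
#' @param n_animals Number of animals (default 40).
#' @param seed Integer seed.
#' @param p0_catch Optional catch-trial probability (default `p0`).
#' @return An object of class `behavior_model`.
#' @export
behavior_model <- function(p0 = 0.15, p_inf_low = 0.35, p_inf_high = 0.6,
                           tau_trials = 2, n_animals = 40, seed = 1,
                           p0_catch = NULL) {
  for (p in c(p0, p_inf_low, p_inf_high, p0_catch))
    if (!is.numeric(p) || p < 0 || p > 1)
      oa_stop("validation_error", "probabilities must be in [0, 1]")
  if (p_inf_low < p0 || p_inf_high < p0)
    oa_stop("validation_error",
            "facilitation requires p_inf >= p0 for both intensities")
  if (tau_trials <= 0)
    oa_stop("validation_error", "tau_trials must be > 0")
  if (!is_count(n_animals) || n_animals < 1)
    oa_stop("validation_error", "n_animals must be a positive integer")
  structure(list(p0 = p0, p_inf_low = p_inf_low, p_inf_high = p_inf_high,
                 tau_trials = tau_trials, n_animals = as.integer(n_animals),
                 seed = seed, p0_catch = p0_catch %||% p0),
            class = "behavior_model")
}

#' Generative per-trial response probabilities of a behavior model
#'
#' Closed-form `p_k` sequence for one block of a protocol — the oracle the
#' simulated tables converge to.
#'
#' @param model A [behavior_model()].
#' @param protocol A [stimulus_protocol()].
#' @param block Block index (default 1).
#' @return Numeric vector of probabilities, one per trial of the block.
#' @export
behavior_p_sequence <- function(model, protocol, block = 1) {
  stopifnot(inherits(model, "behavior_model"),
            inherits(protocol, "stimulus_protocol"))
  tt <- protocol_trial_table(protocol)
  tt <- tt[tt$block == block, , drop = FALSE]
  if (!nrow(tt)) oa_stop("usage_error", "block %d not in protocol", block)
  stim <- protocol$block_sequence[block]
  p_inf <- if (grepl("_L$", stim)) model$p_inf_low else model$p_inf_high
  p <- numeric(nrow(tt))
  k <- 0L
  for (r in seq_len(nrow(tt))) {
    if (tt$is_catch[r]) {
      p[r] <- model$p0_catch
    } else {
      k <- k + 1L
      p[r] <- p_inf + (model$p0 - p_inf) * exp(-(k - 1) / model$tau_trials)
    }
  }
  p
}

#' Simulate a behavioral session
#'
#' Draws per-animal binary palp-opening responses for every trial of the
#' protocol from the facilitating Bernoulli model (see [behavior_model()]).
#' Seeded and reproducible: identical `(model, protocol, seed)` give
#' bit-identical tables.
#'
#' @param model A [behavior_model()].
#' @param protocol A [stimulus_protocol()] (may declare a catch trial).
#' @param seed Integer seed.
#' @return A validated behavior table (see [read_behavior_table()]).
#' @export
simulate_behavior <- function(model, protocol, seed = 1) {
  stopifnot(inherits(model, "behavior_model"),
            inherits(protocol, "stimulus_protocol"))
  tt <- protocol_trial_table(protocol)
  animals <- sprintf("a%03d", seq_len(model$n_animals))
  with_seed(seed, {
    rows <- vector("list", length(protocol$block_sequence))
    for (b in seq_along(protocol$block_sequence)) {
      p <- behavior_p_sequence(model, protocol, block = b)
      sub <- tt[tt$block == b, , drop = FALSE]
      por <- matrix(stats::rbinom(model$n_animals * length(p), 1,
                                  rep(p, each = model$n_animals)),
                    nrow = model$n_animals)
      rows[[b]] <- data.frame(
        animal_id = rep(animals, length(p)),
        trial_id = rep(sub$trial, each = model$n_animals),
        stimulus_label = rep(sub$stimulus, each = model$n_animals),
        por = as.logical(por),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    validate_behavior_table(out)
  })
}

#' Simulate a factor-structured tensor
#'
#' Builds a three-way array as the sum of `n_factors` rank-one components
#' plus additive Gaussian noise scaled to a fraction of the signal's
#' elementwise standard deviation — the benchmark for trilinear
#' decomposition and core-consistency behavior.
#'
#' Two factor styles are available. `"neural"` (the default) emulates the
#' structure of block-design ensemble recordings: each factor is an
#' odor-specific unit ensemble (sparse gamma loadings with partial overlap
#' across factors), a smooth rise-plateau-decay temporal profile (profiles
#' correlated across factors, as odor-evoked timecourses are), and a trial
#' loading localized to that factor's contiguous stimulus block and decaying
#' across repetitions (stimulus identity blended into the trial dimension);
#' components are scaled to equal Frobenius norm. `"normal"` draws all
#' loading vectors iid standard normal — the generic well-conditioned
#' benchmark used for exact factor-recovery checks.
#'
#' @param dims Integer vector of three dimensions (default `c(80, 80, 25)`).
#' @param n_factors Ground-truth rank (default 3).
#' @param noise_sd Noise standard deviation as a multiple of the signal
#'   elementwise SD (default 0.5; use 0 for a noiseless exact-rank tensor).
#' @param seed Integer seed.
#' @param style `"neural"` or `"normal"` (see Details).
#' @param overlap For `"neural"`: probability that a unit outside a
#'   factor's own ensemble still loads on it (default 0.3).
#' @return A list with the noisy array `x`, the noiseless `signal`, the
#'   ground-truth loading matrices `A`, `B`, `C` (scaled so the signal is
#'   the sum of their rank-one outer products) and the absolute noise SD.
#' @export
simulate_factor_tensor <- function(dims = c(80, 80, 25), n_factors = 3,
                                   noise_sd = 0.5, seed = 1,
                                   style = c("neural", "normal"),
                                   overlap = 0.3) {
  style <- match.arg(style)
  if (length(dims) != 3L || any(dims < 1))
    oa_stop("usage_error", "dims must be three positive integers")
  if (n_factors < 1 || n_factors > min(dims))
    oa_stop("usage_error", "n_factors must be in 1..min(dims)")
  with_seed(seed, {
    I <- dims[1]; J <- dims[2]; K <- dims[3]
    if (style == "normal") {
      A <- matrix(stats::rnorm(I * n_factors), I)
      B <- matrix(stats::rnorm(J * n_factors), J)
      C <- matrix(stats::rnorm(K * n_factors), K)
    } else {
      grp <- sample(rep(seq_len(n_factors), length.out = I))
      A <- vapply(seq_len(n_factors), function(f)
        stats::rgamma(I, 2, 1) * ((grp == f) | (stats::runif(I) < overlap)),
        numeric(I))
      tt <- (seq_len(J) - 0.5) / J * 4
      shapes <- list(c(0.1, 0.8, 0.1), c(0.2, 2.5, 0.5), c(0.6, 4, 0.3))
      B <- vapply(seq_len(n_factors), function(f) {
        p <- shapes[[((f - 1) %% 3) + 1]]
        k <- (1 - exp(-tt / p[1])) * (p[3] + (1 - p[3]) * exp(-tt / p[2]))
        k / max(k)
      }, numeric(J))
      block <- sort(rep(seq_len(n_factors), length.out = K))
      C <- vapply(seq_len(n_factors), function(f) {
        idx <- which(block == f)
        v <- numeric(K)
        v[idx] <- 0.45 + 0.55 * exp(-(seq_along(idx) - 1) / 4)
        v
      }, numeric(K))
    }
    signal <- array(0, dims)
    for (f in seq_len(n_factors)) {
      comp <- array(tcrossprod(A[, f, drop = FALSE],
                               khatri_rao(C[, f, drop = FALSE],
                                          B[, f, drop = FALSE])), dims)
      if (style == "neural") {
        nf <- sqrt(sum(comp^2))
        C[, f] <- C[, f] / nf
        comp <- comp / nf
      }
      signal <- signal + comp
    }
    s <- stats::sd(as.vector(signal))
    x <- signal
    if (noise_sd > 0)
      x <- signal + array(stats::rnorm(prod(dims), sd = noise_sd * s),
                          dim = dims)
    list(x = x, signal = signal, A = A, B = B, C = C,
         noise_sd_abs = noise_sd * s)
  })
}
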