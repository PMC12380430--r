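test_that("response-change records are exact per-unit count differences", {
  counts <- array(0L, dim = c(2, 4, 2))
  counts[1, , 1] <- c(3L, 3L, 2L, 2L)   # 10 spikes trial 1
  counts[1, , 2] <- c(1L, 1L, 1L, 1L)   # 4 spikes trial 2
  counts[2, , 1] <- c(1L, 0L, 0L, 0L)
  tens <- trial_tensor(counts, bin_edges_s = seq(0, 0.2, by = 0.05),
                       unit_labels = c("u1", "u2"), trial_numbers = 1:2,
                       stimulus_labels = rep("hex_H", 2))
  rec <- response_change(tens, 1, 2)
  expect_equal(nrow(rec), 2)                      # one record per unit
  expect_equal(rec$delta, rec$r_last - rec$r_first)
  expect_equal(rec$delta[1], -6)
  expect_error(response_change(tens, 1, 1), class = "odoradapt_usage_error")
})

test_that("mechanism regression handles exact, degenerate and noisy designs", {
  r1 <- c(2, 4, 6, 10)
  exact <- data.frame(unit_id = paste0("u", 1:4), r_first = r1,
                      r_last = 0.5 * r1, delta = -0.5 * r1)
  fit <- depletion_vs_inhibition_fit(exact)
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$verdict, "depletion-like")

  flat <- exact; flat$delta <- 0; flat$r_last <- flat$r_first
  fit0 <- depletion_vs_inhibition_fit(flat)
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$r_squared, 0)
  expect_true(fit0$degenerate_response)

  same_x <- exact; same_x$r_first <- 5
  expect_error(depletion_vs_inhibition_fit(same_x),
               class = "odoradapt_degenerate_error")

  # simulated depletion beats a label-permutation null computed by brute force
  proto <- proto_one_block(25)
  pm <- population_model(n_units = 200, seed = 3,
                         adaptation = adaptation_spec("vesicle_depletion"))
  ev <- simulate_session(pm, proto, seed = 4, pad_s = 0)
  rec <- response_change(bin_spikes(ev, proto, units = pm$unit_labels),
                         1, 25)
  obs <- depletion_vs_inhibition_fit(rec)
  expect_lt(obs$slope, 0)
  set.seed(11)
  null_r2 <- replicate(200, {
    shuf <- rec; shuf$delta <- sample(shuf$delta)
    depletion_vs_inhibition_fit(shuf)$r_squared
  })
  expect_gt(obs$r_squared, quantile(null_r2, 0.99))
})

test_that("R-squared is invariant to affine rescaling of both variables", {
  set.seed(5)
  rec <- data.frame(unit_id = paste0("u", 1:50),
                    r_first = rpois(50, 20), r_last = rpois(50, 12))
  rec$delta <- rec$r_last - rec$r_first
  base <- depletion_vs_inhibition_fit(rec)$r_squared
  scaled <- rec
  scaled$r_first <- 3.7 * rec$r_first + 11
  scaled$delta <- -2.2 * rec$delta + 5
  expect_equal(depletion_vs_inhibition_fit(scaled)$r_squared, base,
               tolerance = 1e-12)
})

test_that("cross-intensity fits separate shared from independent adaptation", {
  rec <- function(delta) data.frame(unit_id = paste0("u", seq_along(delta)),
                                    r_first = 10, r_last = 10 + delta,
                                    delta = delta)
  d <- c(-3, -1, 0, 2, 5)
  same <- cross_intensity_change_fit(rec(d), rec(d))
  expect_equal(same$slope, 1, tolerance = 1e-12)
  expect_equal(same$r_squared, 1, tolerance = 1e-12)

  other <- rec(d); other$unit_id <- paste0("w", 1:5)
  expect_error(cross_intensity_change_fit(rec(d), other),
               class = "odoradapt_alignment_error")

  # alignment is by unit id, not row order
  rev_low <- rec(d)[5:1, ]
  expect_equal(cross_intensity_change_fit(rec(d), rev_low)$r_squared, 1,
               tolerance = 1e-12)

  # shared multiplicative adaptation across intensities: strong coupling
  proto <- stimulus_protocol(c("hex_H", "hex_L"), 25)
  r2_shared <- sapply(1:3, function(i) {
    pm <- population_model(seed = 20 + i, rotation_fraction = 0,
                           intensity_gain = 1,
                           adaptation = adaptation_spec(plateau = 0.45))
    ev <- simulate_session(pm, proto, seed = 30 + i, pad_s = 0)
    tt <- bin_spikes(ev, proto, units = pm$unit_labels)
    cross_intensity_change_fit(response_change(tt, 1, 25),
                               response_change(tt, 26, 50))$r_squared
  })
  # independently generated populations: per-unit changes decouple
  r2_indep <- sapply(1:3, function(i) {
    proto1 <- proto_one_block(25)
    pmA <- population_model(seed = 40 + i)
    pmB <- population_model(seed = 60 + i)
    evA <- simulate_session(pmA, proto1, seed = 50 + i, pad_s = 0)
    evB <- simulate_session(pmB, proto1, seed = 70 + i, pad_s = 0)
    cross_intensity_change_fit(
      response_change(bin_spikes(evA, proto1, units = pmA$unit_labels), 1, 25),
      response_change(bin_spikes(evB, proto1, units = pmB$unit_labels), 1, 25)
    )$r_squared
  })
  expect_gt(min(r2_shared), 0.4)
  expect_lt(max(r2_indep), 0.1)
  expect_gt(min(r2_shared), 3 * max(r2_indep))
})

test_that("ensemble timecourses conserve mass and recover the decay", {
  zero <- make_tensor(array(0L, dim = c(3, 80, 7)))
  expect_equal(unname(ensemble_count_timecourse(zero)), rep(0, 7))

  pm <- population_model(n_units = 10, seed = 1)
  proto <- proto_one_block(4)
  tt <- bin_spikes(simulate_session(pm, proto, seed = 2),
                   proto, units = pm$unit_labels)
  tc <- ensemble_count_timecourse(tt)
  expect_equal(sum(tc), sum(tt$counts))

  # exponential fit recovers a noiseless decay exactly
  k <- 1:25
  y <- 120 * (0.4 + 0.6 * exp(-(k - 1) / 5))
  fit <- fit_adaptation_decay(y)
  expect_equal(fit$plateau, 0.4, tolerance = 1e-6)
  expect_equal(fit$tau, 5, tolerance = 1e-3)

  # plateau recovery from simulated sessions with baseline correction
  proto25 <- proto_one_block(25)
  plats <- sapply(1:5, function(i) {
    pm <- population_model(seed = 100 + i,
                           adaptation = adaptation_spec(plateau = 0.4,
                                                        tau_trials = 5))
    ev <- simulate_session(pm, proto25, seed = 200 + i)
    tt <- bin_spikes(ev, proto25, units = pm$unit_labels)
    fit_adaptation_decay(ensemble_count_timecourse(tt),
                         baseline = baseline_window_counts(ev, proto25))$plateau
  })
  expect_lt(abs(median(plats) - 0.4), 0.04)
})
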