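test_that("simulation is seed-deterministic and silent when unstimulated", {
  proto <- proto_one_block(3)
  pm <- population_model(n_units = 10, seed = 1)
  a <- simulate_session(pm, proto, seed = 9)
  b <- simulate_session(pm, proto, seed = 9)
  expect_identical(a, b)
  c2 <- simulate_session(pm, proto, seed = 10)
  expect_false(identical(a, c2))

  # zero baseline and zero tuning -> zero spikes
  silent <- population_model(
    n_units = 4, baseline_rate_hz = 0, seed = 1,
    tuning = matrix(0, 4, 1, dimnames = list(NULL, "hex_H")))
  expect_equal(nrow(simulate_session(silent, proto, seed = 1)), 0)

  bm <- behavior_model(n_animals = 5)
  expect_identical(simulate_behavior(bm, proto, seed = 3),
                   simulate_behavior(bm, proto, seed = 3))
})

test_that("spike counts follow the inhomogeneous Poisson mean", {
  # 1 unit, 10 Hz flat kernel, no adaptation, 4-s window: mean count ~ 40
  proto <- stimulus_protocol("hex_H", 1000)
  pm <- population_model(
    n_units = 1, baseline_rate_hz = 0,
    temporal_kernel = rep(1, 80),
    adaptation = adaptation_spec(plateau = 1),
    tuning = matrix(10, 1, 1, dimnames = list(NULL, "hex_H")),
    seed = 1)
  ev <- simulate_session(pm, proto, seed = 11, pad_s = 0)
  tens <- bin_spikes(ev, proto, units = pm$unit_labels)
  counts <- ensemble_count_timecourse(tens)
  se <- sqrt(40 / 1000)
  expect_lt(abs(mean(counts) - 40), 3 * se)
  # Poisson dispersion: variance tracks the mean
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.25)
})

test_that("magnitude-only adaptation shrinks counts but preserves direction", {
  proto <- proto_one_block(25)
  ratios <- cosines <- numeric(5)
  for (i in 1:5) {
    pm <- population_model(
      seed = 20 + i, baseline_rate_hz = 0,
      adaptation = adaptation_spec(plateau = 0.4, tau_trials = 5))
    ev <- simulate_session(pm, proto, seed = 30 + i, pad_s = 0)
    tt <- bin_spikes(ev, proto, units = pm$unit_labels)
    v1 <- population_vector(tt, 1)$values
    v25 <- population_vector(tt, 25)$values
    cosines[i] <- sum(v1 * v25) / sqrt(sum(v1^2) * sum(v25^2))
    ratios[i] <- sum(v25) / sum(v1)
  }
  m25 <- 0.4 + 0.6 * exp(-24 / 5)   # analytic multiplier at trial 25
  expect_true(all(cosines >= 0.95))
  expect_lt(abs(mean(ratios) - m25), 0.05)
})

test_that("mechanism parameterizations leave their regression signatures", {
  proto <- proto_one_block(25)
  for (i in 1:3) {
    dep <- population_model(n_units = 200, seed = 40 + i,
                            adaptation = adaptation_spec("vesicle_depletion"))
    ev <- simulate_session(dep, proto, seed = 50 + i, pad_s = 0)
    fit <- depletion_vs_inhibition_fit(
      response_change(bin_spikes(ev, proto, units = dep$unit_labels), 1, 25))
    expect_lt(fit$slope, 0)
    expect_equal(fit$verdict, "depletion-like")

    inh <- population_model(n_units = 200, seed = 40 + i,
                            adaptation = adaptation_spec("lateral_inhibition"))
    ev2 <- simulate_session(inh, proto, seed = 50 + i, pad_s = 0)
    fit2 <- depletion_vs_inhibition_fit(
      response_change(bin_spikes(ev2, proto, units = inh$unit_labels), 1, 25))
    expect_gt(fit2$slope, 0)
    expect_equal(fit2$verdict, "inhibition-like")
  }
})

test_that("negative effective rates are a model error, never clipped", {
  proto <- proto_one_block(5)
  pm <- population_model(n_units = 10, baseline_rate_hz = 1, seed = 1,
                         adaptation = adaptation_spec("lateral_inhibition",
                                                      strength = 5))
  expect_error(simulate_session(pm, proto, seed = 1),
               class = "odoradapt_model_error")
})

test_that("catch sessions honor the cross-adaptation coupling", {
  protoc <- stimulus_protocol("hex_H", 30, catch_trial_index = 26,
                              catch_stimulus = "iaa_H")
  pm <- population_model(odors = c("hex", "iaa"), seed = 61,
                         adaptation = adaptation_spec(plateau = 0.45,
                                                      tau_trials = 5))
  kern <- default_temporal_kernel(80)
  kmass <- sum(kern) * 0.05
  base_mass <- pm$baseline_rate_hz * 4 * pm$n_units

  # decoupled: catch expectation = unadapted deviant response
  ev0 <- simulate_catch_session(pm, protoc, seed = 62, cross_adaptation = 0)
  t0 <- bin_spikes(ev0, protoc, units = pm$unit_labels)
  catch0 <- sum(t0$counts[, , 26])
  exp0 <- base_mass + sum(pm$tuning[, "iaa_H"]) * kmass
  expect_lt(abs(catch0 - exp0), 3 * sqrt(exp0))

  # fully coupled: catch expectation carries the adapted multiplier
  ev1 <- simulate_catch_session(pm, protoc, seed = 63, cross_adaptation = 1)
  t1 <- bin_spikes(ev1, protoc, units = pm$unit_labels)
  catch1 <- sum(t1$counts[, , 26])
  m26 <- 0.45 + 0.55 * exp(-25 / 5)
  exp1 <- base_mass + m26 * sum(pm$tuning[, "iaa_H"]) * kmass
  expect_lt(abs(catch1 - exp1), 3 * sqrt(exp1))

  # catch stimulus must exist in the tuning table
  pm_bad <- population_model(odors = "hex", seed = 1)
  expect_error(simulate_catch_session(pm_bad, protoc, seed = 1),
               class = "odoradapt_model_error")
  expect_error(simulate_session(pm, protoc, seed = 1),
               class = "odoradapt_usage_error")
  expect_error(simulate_catch_session(pm, proto_one_block(5), seed = 1),
               class = "odoradapt_usage_error")
})

test_that("behavioral facilitation follows its closed form", {
  proto <- stimulus_protocol("iaa_H", 10)
  # degenerate endpoints
  all0 <- behavior_model(p0 = 0, p_inf_low = 0, p_inf_high = 0,
                         n_animals = 6)
  expect_true(all(!simulate_behavior(all0, proto, seed = 2)$por))
  all1 <- behavior_model(p0 = 1, p_inf_low = 1, p_inf_high = 1,
                         n_animals = 6)
  expect_true(all(simulate_behavior(all1, proto, seed = 2)$por))

  # closed-form Bernoulli mean at trial 10 with 500 animals
  bm <- behavior_model(p0 = 0.2, p_inf_high = 0.8, p_inf_low = 0.8,
                       tau_trials = 2, n_animals = 500)
  tab <- simulate_behavior(bm, proto, seed = 77)
  p10 <- 0.8 + (0.2 - 0.8) * exp(-9 / 2)
  est <- por_probability(tab, "iaa_H")$p_por["10"]
  expect_lt(abs(est - p10), 3 * sqrt(p10 * (1 - p10) / 500))
  expect_equal(behavior_p_sequence(bm, proto)[10], p10)

  expect_error(behavior_model(p0 = 0.5, p_inf_low = 0.2),
               class = "odoradapt_validation_error")
})

test_that("intensity rotation separates high and low ensembles", {
  proto <- proto_two_by_two(10)
  pm <- population_model(seed = 88)
  ev <- simulate_session(pm, proto, seed = 89)
  tt <- bin_spikes(ev, proto, units = pm$unit_labels)
  cm <- trial_correlation_matrix(tt)$values
  hexH <- which(tt$stimulus_labels == "hex_H")
  hexL <- which(tt$stimulus_labels == "hex_L")
  within <- mean(c(cm[hexH, hexH][upper.tri(diag(10))],
                   cm[hexL, hexL][upper.tri(diag(10))]))
  between <- mean(cm[hexH, hexL])
  expect_gt(within, between)
})
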