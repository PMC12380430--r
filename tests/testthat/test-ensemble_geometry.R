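test_that("Pearson correlation matches direct arithmetic and its invariances", {
  x <- c(1, 2, 4); y <- c(1, 3, 5)
  # direct covariance / sd formula computed by hand
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_trial_correlation(x, y), oracle, tolerance = 1e-12)
  expect_equal(pearson_trial_correlation(x, x), 1)
  expect_equal(pearson_trial_correlation(x, 2.5 * x + 3), 1)
  expect_equal(pearson_trial_correlation(x, -0.3 * x + 1), -1)
  expect_error(pearson_trial_correlation(x, rep(2, 3)),
               class = "odoradapt_degenerate_error")
  expect_error(pearson_trial_correlation(x, y[1:2]),
               class = "odoradapt_usage_error")
})

test_that("trial correlation matrices are symmetric, scale-invariant block structures", {
  # duplicated trials correlate at exactly 1
  counts <- array(0L, dim = c(4, 3, 3))
  counts[, , 1] <- counts[, , 2] <- matrix(c(5L, 1L, 0L, 2L), 4, 3)
  counts[, , 3] <- matrix(c(0L, 3L, 4L, 1L), 4, 3)
  tens <- trial_tensor(counts, bin_edges_s = seq(0, 0.15, by = 0.05),
                       unit_labels = paste0("u", 1:4), trial_numbers = 1:3,
                       stimulus_labels = rep("hex_H", 3))
  cm <- trial_correlation_matrix(tens)
  expect_identical(cm$values, t(cm$values))
  expect_equal(unname(diag(cm$values)), rep(1, 3))
  expect_equal(cm$values[1, 2], 1)

  # Pearson depends only on direction: both reductions agree exactly
  cm2 <- trial_correlation_matrix(tens, "sum_window")
  expect_equal(cm$values, cm2$values, tolerance = 1e-12)

  # zero-variance trial is identified by label
  counts[, , 3] <- 2L
  flat <- trial_tensor(counts, bin_edges_s = seq(0, 0.15, by = 0.05),
                       unit_labels = paste0("u", 1:4), trial_numbers = 1:3,
                       stimulus_labels = rep("hex_H", 3))
  expect_error(trial_correlation_matrix(flat), regexp = "t3",
               class = "odoradapt_degenerate_error")

  # simulated two-odor session: within-odor exceeds between-odor correlation
  proto <- stimulus_protocol(c("hex_H", "oct_H"), 10)
  pm <- population_model(seed = 14)
  tt <- bin_spikes(simulate_session(pm, proto, seed = 15), proto,
                   units = pm$unit_labels)
  R <- trial_correlation_matrix(tt)$values
  within <- mean(R[1:10, 1:10][upper.tri(diag(10))])
  between <- mean(R[1:10, 11:20])
  expect_gt(within, between + 0.3)
})

test_that("complete-linkage dendrograms match the brute-force oracle", {
  # two internally identical groups -> zero-height merges, one top merge
  v <- matrix(c(1, 2, 5, 3,
                1, 2, 5, 3,
                4, 0, 1, 2,
                4, 0, 1, 2), nrow = 4)
  counts <- array(0L, c(4, 1, 4)); counts[, 1, ] <- v
  tens <- trial_tensor(counts, bin_edges_s = c(0, 0.05),
                       unit_labels = paste0("u", 1:4), trial_numbers = 1:4,
                       stimulus_labels = rep("hex_H", 4))
  hc <- cluster_dendrogram(trial_correlation_matrix(tens))
  expect_equal(hc$height[1:2], c(0, 0), tolerance = 1e-12)
  expect_equal(length(hc$height), 3)
  expect_equal(sort(unname(cutree(hc, 2))), c(1, 1, 2, 2))

  # 4 trials with hand-specified correlations vs exhaustive linkage oracle
  R <- matrix(c(1.0, 0.9, 0.3, 0.1,
                0.9, 1.0, 0.4, 0.2,
                0.3, 0.4, 1.0, 0.6,
                0.1, 0.2, 0.6, 1.0), 4, 4)
  cm <- structure(list(values = R, trial_labels = paste0("t", 1:4),
                       stimulus_labels = rep("s", 4),
                       reduction = "mean_per_bin"),
                  class = "trial_correlation_matrix")
  hc2 <- cluster_dendrogram(cm)
  oracle <- complete_linkage_oracle(1 - R)
  expect_equal(unname(hc2$height), oracle$heights, tolerance = 1e-12)
  # identical input gives identical trees (reproducibility)
  hc3 <- cluster_dendrogram(cm)
  expect_identical(hc2$merge, hc3$merge)
  expect_identical(hc2$order, hc3$order)
})

test_that("dendrogram cuts separate odors then intensities on simulated data", {
  proto <- proto_two_by_two(10)
  pm <- population_model(seed = 33)
  tt <- bin_spikes(simulate_session(pm, proto, seed = 34), proto,
                   units = pm$unit_labels)
  hc <- cluster_dendrogram(trial_correlation_matrix(tt))
  odor <- sub("_.$", "", tt$stimulus_labels)
  expect_equal(ari(cutree(hc, 2), odor), 1)
  expect_equal(ari(cutree(hc, 4), tt$stimulus_labels), 1)
})

test_that("leave-one-trial-out classification behaves from separation to chance", {
  # perfectly separated deterministic classes
  counts <- array(0L, c(4, 1, 6))
  counts[, 1, 1:3] <- matrix(c(9L, 1L, 0L, 1L), 4, 3) +
    matrix(c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 1L), 4, 3)
  counts[, 1, 4:6] <- matrix(c(0L, 2L, 8L, 1L), 4, 3) +
    matrix(c(1L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 1L, 0L, 0L), 4, 3)
  tens <- trial_tensor(counts, bin_edges_s = c(0, 0.05),
                       unit_labels = paste0("u", 1:4), trial_numbers = 1:6,
                       stimulus_labels = rep(c("A", "B"), each = 3))
  res <- classify_trials(tens)
  expect_equal(res$overall_accuracy, 1)
  expect_equal(unname(res$per_class), c(1, 1))

  expect_error(classify_trials(tens, labels = c("A", rep("B", 5))),
               class = "odoradapt_usage_error")
  expect_error(classify_trials(tens, labels = rep("A", 6)),
               class = "odoradapt_usage_error")

  # simulated separation stays above chance; shuffled labels fall to chance
  proto <- stimulus_protocol(c("hex_H", "oct_H"), 10)
  pm <- population_model(seed = 44)
  tt <- bin_spikes(simulate_session(pm, proto, seed = 45), proto,
                   units = pm$unit_labels)
  real <- classify_trials(tt)
  expect_gt(real$overall_accuracy, 0.75)
  set.seed(9)
  accs <- replicate(30, {
    classify_trials(tt, labels = sample(tt$stimulus_labels))$overall_accuracy
  })
  se <- sqrt(0.5 * 0.5 / (20 * 30))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.05)
})

test_that("catch-trial correlation profiles dip only at the deviant", {
  protoc <- stimulus_protocol("hex_H", 30, catch_trial_index = 26,
                              catch_stimulus = "iaa_H")
  pm <- population_model(odors = c("hex", "iaa"), seed = 55)
  ev <- simulate_catch_session(pm, protoc, seed = 56)
  tt <- bin_spikes(ev, protoc, units = pm$unit_labels)
  r <- catch_trial_correlation(tt, 1)
  expect_equal(unname(r[1]), 1)
  expect_lt(r[26], 0.5)                 # deviant decorrelates sharply
  expect_gt(min(r[-26]), 0.8)           # repeats keep their direction
  expect_equal(which.min(r), 26L, ignore_attr = TRUE)
})

test_that("trajectories preserve shape under magnitude adaptation and contract distances", {
  proto <- stimulus_protocol(c("hex_H", "oct_H"), 25)
  pm <- population_model(seed = 41)
  tt <- bin_spikes(simulate_session(pm, proto, seed = 51), proto,
                   units = pm$unit_labels)
  m <- cp_als(tt, 3, restarts = 3, seed = 61)
  trj <- trial_trajectories(m, proto)
  expect_length(trj, 50)
  expect_equal(nrow(trj[[1]]$points), 80)
  # basis orthonormality
  B <- trj[[1]]$basis
  expect_equal(crossprod(B), diag(3), tolerance = 1e-8)
  expect_true(all(trj[[1]]$explained_var >= 0))

  # direction maintained within odor; path length shrinks with adaptation
  expect_gt(trajectory_direction_cosine(trj[[1]], trj[[25]]), 0.9)
  expect_lt(trajectory_direction_cosine(trj[[1]], trj[[26]]),
            trajectory_direction_cosine(trj[[1]], trj[[25]]))
  L <- vapply(trj, trajectory_path_length, numeric(1))
  m25 <- 0.45 + 0.55 * exp(-24 / 5)
  expect_lt(L[25] / L[1], 0.75)
  expect_gt(L[25] / L[1], 0.2)

  # projection is a contraction: projected distances never exceed the
  # distances between the centered full-space bin vectors
  Xhat <- reconstruct_tensor(m)
  M <- matrix(Xhat, dim(Xhat)[1])
  Xc <- M - rowMeans(M)
  raw <- trial_trajectories(m, proto, smooth_points = 1)
  set.seed(3)
  for (i in 1:20) {
    k <- sample(50, 1); t1 <- sample(80, 2)
    full_d <- sqrt(sum((Xc[, (k - 1) * 80 + t1[1]] -
                          Xc[, (k - 1) * 80 + t1[2]])^2))
    proj_d <- sqrt(sum((raw[[k]]$points[t1[1], ] -
                          raw[[k]]$points[t1[2], ])^2))
    expect_lte(proj_d, full_d + 1e-8)
  }
})

test_that("constant activity collapses trajectories to the origin", {
  counts <- array(2L, c(5, 8, 3))
  tens <- trial_tensor(counts, bin_edges_s = seq(0, 0.4, by = 0.05),
                       unit_labels = paste0("u", 1:5), trial_numbers = 1:3,
                       stimulus_labels = rep("hex_H", 3))
  m <- cp_als(tens, 1, restarts = 2, seed = 1)
  trj <- trial_trajectories(m)
  expect_true(all(abs(trj[[1]]$points) < 1e-8))
  expect_true(all(abs(trj[[3]]$points) < 1e-8))
})
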