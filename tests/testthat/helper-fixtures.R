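# Shared fixtures and independent oracles used across the suite.

# canonical protocols
proto_one_block <- function(n_trials = 25, stimulus = "hex_H")
  stimulus_protocol(stimulus, n_trials)

proto_two_by_two <- function(n_trials = 25)
  stimulus_protocol(c("hex_H", "hex_L", "oct_H", "oct_L"), n_trials)

# a small hand-buildable tensor: counts[unit, bin, trial]
make_tensor <- function(counts) {
  d <- dim(counts)
  trial_tensor(counts,
               bin_edges_s = seq(0, by = 0.05, length.out = d[2] + 1),
               unit_labels = paste0("u", seq_len(d[1])),
               trial_numbers = seq_len(d[3]),
               stimulus_labels = rep("hex_H", d[3]))
}

# write a CSV fixture from a data frame
write_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# adjusted Rand index via the established implementation
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# all permutations of 1..n (brute-force matching oracle)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in all_perms(n - 1))
      out[[length(out) + 1L]] <- c(i, rest[p])
  }
  out
}

# brute-force permutation/sign congruence between a ground-truth factor set
# and a fitted cp_model: returns the smallest per-mode cosine over the best
# permutation
min_congruence <- function(truth, fit) {
  Fn <- ncol(truth$A)
  cos1 <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  best <- -Inf
  for (p in all_perms(Fn)) {
    worst <- Inf
    for (f in seq_len(Fn)) {
      worst <- min(worst,
                   cos1(truth$A[, f], fit$A[, p[f]]),
                   cos1(truth$B[, f], fit$B[, p[f]]),
                   cos1(truth$C[, f], fit$C[, p[f]]))
    }
    best <- max(best, worst)
  }
  best
}

# exhaustive complete-linkage oracle: greedy agglomeration recomputing the
# max inter-cluster distance at every step, independent of stats::hclust
complete_linkage_oracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- max(D[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    merges[[length(merges) + 1L]] <-
      sort(c(clusters[[best[2]]], clusters[[best[3]]]))
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  list(heights = heights, merges = merges)
}
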