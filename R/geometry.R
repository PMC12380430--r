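# Population-vector geometry: low-dimensional trial trajectories,
# trial-correlation matrices, complete-linkage dendrograms, leave-one-out
# trial classification, and catch-trial correlation profiles.

#' Pearson correlation between two population vectors
#'
#' The standard Pearson coefficient `cov(x, y) / (sd(x) * sd(y))` between
#' two neuron-dimensional activity vectors — the similarity measure behind
#' all correlation, clustering and classification analyses. Because the
#' coefficient is invariant to positive rescaling, it depends only on the
#' direction of the population vectors, not their magnitude: the level at
#' which magnitude (adaptation) and direction (identity/intensity) are
#' dissociated.
#'
#' @param v1,v2 [population_vector()] objects or numeric vectors of equal
#'   length (at least 2), each with nonzero variance.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_trial_correlation <- function(v1, v2) {
  x <- if (inherits(v1, "population_vector")) v1$values else as.numeric(v1)
  y <- if (inherits(v2, "population_vector")) v2$values else as.numeric(v2)
  if (length(x) != length(y))
    oa_stop("usage_error", "vectors must have equal length")
  if (length(x) < 2)
    oa_stop("usage_error", "vectors must have length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    oa_stop("degenerate_error",
            "correlation undefined for a zero-variance vector")
  stats::cor(x, y)
}

.trial_vector_matrix <- function(tensor, reduction) {
  d <- dim(tensor$counts)
  if (reduction == "concat_bins") {
    V <- matrix(tensor$counts, d[1] * d[2], d[3])
  } else {
    V <- apply(tensor$counts, 3, function(s) rowSums(matrix(s, d[1])))
    V <- matrix(V, d[1], d[3])
    if (reduction == "mean_per_bin") V <- V / d[2]
  }
  colnames(V) <- tensor$trial_labels
  V
}

#' All-pairs trial correlation matrix
#'
#' Pearson correlations between the per-trial population vectors of every
#' pair of trials, ordered as presented (blocks in protocol order, earlier
#' trials first), so same-stimulus blocks form diagonal blocks.
#'
#' @param tensor A [trial_tensor()] with at least 2 trials.
#' @param reduction `"mean_per_bin"` (time-averaged vectors, the default),
#'   `"sum_window"` (identical correlations, different scale) or
#'   `"concat_bins"` (concatenated per-bin vectors).
#' @return An object of class `trial_correlation_matrix` with fields
#'   `values` (symmetric, unit diagonal), `trial_labels`,
#'   `stimulus_labels`, `reduction`.
#' @export
trial_correlation_matrix <- function(tensor,
                                     reduction = c("mean_per_bin",
                                                   "sum_window",
                                                   "concat_bins")) {
  stopifnot(inherits(tensor, "trial_tensor"))
  reduction <- match.arg(reduction)
  K <- dim(tensor$counts)[3]
  if (K < 2) oa_stop("usage_error", "need at least 2 trials")
  V <- .trial_vector_matrix(tensor, reduction)
  sds <- apply(V, 2, stats::sd)
  if (any(sds == 0))
    oa_stop("degenerate_error",
            "zero-variance population vector in trial(s): %s",
            paste(tensor$trial_labels[sds == 0], collapse = ", "))
  R <- stats::cor(V)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  structure(
    list(values = R,
         trial_labels = tensor$trial_labels,
         stimulus_labels = tensor$stimulus_labels,
         reduction = reduction),
    class = "trial_correlation_matrix"
  )
}

#' Complete-linkage dendrogram of trials
#'
#' Agglomerative hierarchical clustering of trials on the correlation
#' distance `d = 1 - r`, merging so that the furthest pairwise distance
#' within any cluster is minimized (complete linkage). Leaves carry the
#' trial labels (block and trial number).
#'
#' @param cmat A [trial_correlation_matrix()].
#' @return An `hclust` tree (merge heights, order, labels) with the trials'
#'   stimulus labels attached as attribute `stimulus_labels`; use
#'   [stats::cutree()] to extract flat clusterings.
#' @export
cluster_dendrogram <- function(cmat) {
  stopifnot(inherits(cmat, "trial_correlation_matrix"))
  d <- stats::as.dist(1 - cmat$values)
  hc <- stats::hclust(d, method = "complete")
  hc$labels <- cmat$trial_labels
  attr(hc, "stimulus_labels") <- cmat$stimulus_labels
  hc
}

#' Leave-one-trial-out nearest-centroid trial classification
#'
#' Classifies each trial's population vector by Pearson similarity to the
#' per-class centroid (mean vector) computed with the held-out trial
#' removed, recomputing centroids per fold. This is the simplest classifier
#' consistent with the correlation-based similarity used throughout the
#' analyses; the cross-validation scheme is this package's interpretation
#' and is labelled as such in the report.
#'
#' @param tensor A [trial_tensor()].
#' @param labels Class label per trial (default: the tensor's stimulus
#'   labels). At least 2 classes with at least 2 trials each.
#' @param reduction Population-vector reduction (default `"sum_window"`).
#' @return An object of class `trial_classification`: `overall_accuracy`,
#'   named `per_class` accuracies, the `confusion` table
#'   (true x predicted), `n_trials`, and the `scheme` description.
#' @export
classify_trials <- function(tensor, labels = NULL,
                            reduction = "sum_window") {
  stopifnot(inherits(tensor, "trial_tensor"))
  labels <- as.character(labels %||% tensor$stimulus_labels)
  K <- dim(tensor$counts)[3]
  if (length(labels) != K)
    oa_stop("usage_error", "need one label per trial")
  tab <- table(labels)
  if (length(tab) < 2)
    oa_stop("usage_error", "need at least 2 classes")
  if (any(tab < 2))
    oa_stop("usage_error",
            "every class needs >= 2 trials (cannot leave one out): %s",
            paste(names(tab)[tab < 2], collapse = ", "))
  V <- .trial_vector_matrix(tensor, reduction)
  classes <- sort(names(tab))
  pred <- character(K)
  for (t in seq_len(K)) {
    sims <- vapply(classes, function(cl) {
      idx <- setdiff(which(labels == cl), t)
      centroid <- rowMeans(V[, idx, drop = FALSE])
      if (stats::sd(centroid) == 0 || stats::sd(V[, t]) == 0)
        oa_stop("degenerate_error",
                "zero-variance vector in classification fold")
      stats::cor(V[, t], centroid)
    }, numeric(1))
    pred[t] <- classes[which.max(sims)]
  }
  confusion <- table(true = factor(labels, classes),
                     predicted = factor(pred, classes))
  per_class <- diag(confusion) / rowSums(confusion)
  structure(
    list(overall_accuracy = mean(pred == labels),
         per_class = per_class,
         confusion = confusion,
         n_trials = K,
         scheme = "leave-one-trial-out nearest centroid, Pearson similarity (package interpretation)"),
    class = "trial_classification"
  )
}

#' @export
print.trial_classification <- function(x, ...) {
  cat(sprintf("Trial classification (%s)\n", x$scheme))
  cat(sprintf("  overall accuracy: %.3f over %d trials\n",
              x$overall_accuracy, x$n_trials))
  print(round(x$per_class, 3))
  invisible(x)
}

#' Correlation of every trial with a reference trial
#'
#' Pearson correlation between each trial's population vector and the
#' reference trial's vector, in trial order — the catch-trial profile: a
#' deviant stimulus embedded in a block of repeats shows up as a sharp dip
#' against an otherwise high, direction-preserved background.
#'
#' @param tensor A [trial_tensor()].
#' @param reference_trial Trial index or label (default 1).
#' @param reduction Population-vector reduction (default `"sum_window"`).
#' @return Named numeric vector of correlations, one per trial.
#' @export
catch_trial_correlation <- function(tensor, reference_trial = 1,
                                    reduction = "sum_window") {
  stopifnot(inherits(tensor, "trial_tensor"))
  ref <- .resolve_trials(tensor, reference_trial)
  if (length(ref) != 1L)
    oa_stop("usage_error", "reference_trial must select a single trial")
  V <- .trial_vector_matrix(tensor, reduction)
  sds <- apply(V, 2, stats::sd)
  if (any(sds == 0))
    oa_stop("degenerate_error",
            "zero-variance population vector in trial(s): %s",
            paste(tensor$trial_labels[sds == 0], collapse = ", "))
  out <- as.vector(stats::cor(V[, ref], V))
  names(out) <- tensor$trial_labels
  out
}

.running_mean <- function(x, w) {
  if (w <= 1) return(x)
  h <- (w - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Trial-by-trial low-dimensional odor response trajectories
#'
#' Reconstructs the denoised tensor from a CP model, unfolds it along the
#' trial dimension into a units x (bins * trials) time series (odor-window
#' bins only), mean-centers the bin vectors over all time steps, projects
#' them onto the three eigenvectors of the response covariance matrix with
#' the largest eigenvalues, and smooths each trial's point sequence with a
#' three-point running average (shrunken two-point windows at the ends).
#' Each trial yields one closed-loop trajectory whose length tracks
#' response magnitude and whose direction tracks the activated combination
#' of neurons.
#'
#' @param model A [cp_als()] fit carrying trial metadata (fitted from a
#'   [trial_tensor()]).
#' @param protocol Optional [stimulus_protocol()]; when supplied, its bin
#'   count is checked against the model's time dimension.
#' @param smooth_points Running-average window (default 3; 1 disables).
#' @param trials Optional subset of trial indices to return (projection is
#'   always computed from all trials).
#' @return A list of `odor_trajectory` objects, each with `points` (bins x
#'   3 coordinates), `trial_label`, `stimulus_label`, the shared `basis`
#'   (units x 3 orthonormal projection vectors) and `explained_var` (three
#'   variance fractions).
#' @export
trial_trajectories <- function(model, protocol = NULL, smooth_points = 3,
                               trials = NULL) {
  stopifnot(inherits(model, "cp_model"))
  if (is.null(model$meta))
    oa_stop("usage_error",
            "model carries no trial metadata; fit it to a trial_tensor")
  J <- model$dims[2]; K <- model$dims[3]
  if (!is.null(protocol) && n_bins(protocol) != J)
    oa_stop("usage_error",
            "protocol declares %d bins but the model has %d",
            n_bins(protocol), J)
  Xhat <- reconstruct_tensor(model)
  M <- matrix(Xhat, model$dims[1])          # units x (J*K), bins fastest
  Xc <- M - rowMeans(M)
  covm <- tcrossprod(Xc) / (ncol(Xc) - 1)
  eg <- eigen(covm, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (max(ev) <= 1e-12 * max(1, mean(M^2))) {
    # constant activity: every trajectory collapses to the origin
    V <- diag(1, model$dims[1])[, 1:3, drop = FALSE]
    eg$vectors <- diag(1, model$dims[1])
    ev <- rep(0, length(ev))
  } else if (sum(ev > max(ev) * 1e-12) < 3) {
    oa_stop("degenerate_error",
            "fewer than 3 non-degenerate covariance eigenvalues")
  }
  V <- eg$vectors[, 1:3, drop = FALSE]
  for (f in 1:3) {                           # deterministic sign
    s <- sign(V[which.max(abs(V[, f])), f]); if (s == 0) s <- 1
    V[, f] <- s * V[, f]
  }
  explained <- if (sum(ev) > 0) ev[1:3] / sum(ev) else rep(0, 3)
  coords <- crossprod(Xc, V)                 # (J*K) x 3
  idx <- trials %||% seq_len(K)
  lapply(idx, function(k) {
    pts <- coords[(k - 1) * J + seq_len(J), , drop = FALSE]
    pts <- apply(pts, 2, .running_mean, w = smooth_points)
    structure(
      list(points = pts,
           trial_label = model$meta$trial_labels[k],
           stimulus_label = model$meta$stimulus_labels[k],
           basis = V,
           explained_var = explained),
      class = "odor_trajectory"
    )
  })
}

#' Orientation similarity between two trajectories
#'
#' Cosine similarity between the two trajectories' shapes: each trial's
#' points are centered on their own mean (removing the trial's position in
#' state space) and the flattened shapes compared. Under pure magnitude
#' adaptation the trajectory shape of a later trial is the first trial's
#' shape scaled by the adaptation multiplier, so this cosine stays near 1
#' while the path length shrinks; different odors trace differently
#' oriented loops and score much lower.
#'
#' @param a,b `odor_trajectory` objects with equal point counts.
#' @return Cosine in `[-1, 1]`.
#' @export
trajectory_direction_cosine <- function(a, b) {
  pa <- scale(a$points, scale = FALSE)
  pb <- scale(b$points, scale = FALSE)
  if (!identical(dim(pa), dim(pb)))
    oa_stop("usage_error", "trajectories must have equal point counts")
  den <- sqrt(sum(pa^2) * sum(pb^2))
  if (den == 0)
    oa_stop("degenerate_error", "degenerate (single-point) trajectory")
  sum(pa * pb) / den
}

#' Path length of a trajectory
#'
#' Sum of Euclidean segment lengths along the ordered points — under pure
#' magnitude adaptation, later trials' path lengths shrink by the
#' adaptation multiplier while the trajectory direction is preserved.
#'
#' @param traj An `odor_trajectory` (or a points matrix).
#' @return Scalar path length.
#' @export
trajectory_path_length <- function(traj) {
  pts <- if (inherits(traj, "odor_trajectory")) traj$points else traj
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}
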