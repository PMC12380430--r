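# Trilinear CP/PARAFAC decomposition by alternating least squares, the
# core-consistency diagnostic (CORCONDIA), factor-number selection and
# tensor reconstruction. x_ijk ~ sum_f a_if * b_jf * c_kf + e_ijk.

#' Column-wise Khatri-Rao product
#'
#' @param X,Y Matrices with the same number of columns.
#' @return Matrix of dimension `nrow(X) * nrow(Y)` x `ncol(X)` whose f-th
#'   column is `kronecker(X[, f], Y[, f])`.
#' @export
khatri_rao <- function(X, Y) {
  if (ncol(X) != ncol(Y))
    oa_stop("usage_error", "khatri_rao needs equal column counts")
  out <- matrix(0, nrow(X) * nrow(Y), ncol(X))
  for (f in seq_len(ncol(X))) out[, f] <- kronecker(X[, f], Y[, f])
  out
}

.as_array3 <- function(x) {
  if (inherits(x, "trial_tensor")) return(unclass(x$counts) * 1.0)
  if (is.array(x) && length(dim(x)) == 3L) return(x * 1.0)
  oa_stop("usage_error", "expected a trial_tensor or a 3-d array")
}

# mode-n matrix product of a 3-d array
.ttm <- function(X, M, mode) {
  d <- dim(X)
  perm <- c(mode, setdiff(1:3, mode))
  Xp <- aperm(X, perm)
  Y <- M %*% matrix(Xp, d[mode])
  Y <- array(Y, c(nrow(M), d[setdiff(1:3, mode)]))
  aperm(Y, order(perm))
}

# least-squares solve of t(G) \ t(W), with pseudo-inverse fallback for
# rank-deficient Gram matrices
.solve_gram <- function(W, G) {
  tryCatch(W %*% solve(G), error = function(e) W %*% MASS::ginv(G))
}

#' Fit a CP/PARAFAC model by alternating least squares
#'
#' Approximates a Neuron x Time x Trial tensor as a sum of `n_factors`
#' rank-one outer products, cyclically solving each loading matrix as a
#' least-squares problem with the other two fixed. The reconstruction error
#' is non-increasing across iterations; the fit is restarted from several
#' random initializations and the best fit kept. After fitting, the columns
#' of the neuron (`A`) and time (`B`) loadings are scaled to unit Euclidean
#' norm with all scale absorbed into the trial loadings (`C`), the sign of
#' each column is fixed so the largest-magnitude element of each `A` column
#' is positive, and factors are ordered by decreasing `C` column norm —
#' making serialization and factor matching deterministic.
#'
#' @param x A [trial_tensor()] or plain 3-d array; must not be all zero.
#' @param n_factors Number of factors `F`, between 1 and the smallest tensor
#'   dimension.
#' @param restarts Number of random initializations (default 10).
#' @param tol Convergence tolerance on the relative change of the fit
#'   fraction (default 1e-8).
#' @param max_iter Maximum ALS iterations per restart (default 500).
#' @param seed Integer seed for the random initializations.
#' @param nonneg If `TRUE`, loadings are projected onto the non-negative
#'   orthant after each update (exploratory option; the per-iteration error
#'   monotonicity guarantee then no longer holds).
#' @return An object of class `cp_model`: loading matrices `A`
#'   (units x F), `B` (bins x F), `C` (trials x F), `n_factors`,
#'   `fit_fraction` (`1 - ||E||^2 / ||X||^2`), `n_iterations`, `converged`,
#'   the per-iteration `sse_history` of the winning restart, and the axis
#'   labels when `x` was a [trial_tensor()].
#' @export
cp_als <- function(x, n_factors, restarts = 10, tol = 1e-8, max_iter = 500,
                   seed = 1, nonneg = FALSE) {
  X <- .as_array3(x)
  d <- dim(X)
  if (!is_count(n_factors) || n_factors < 1)
    oa_stop("usage_error", "n_factors must be a positive integer")
  if (n_factors > min(d))
    oa_stop("usage_error",
            "n_factors (%d) exceeds the smallest tensor dimension (%d)",
            n_factors, min(d))
  normX2 <- sum(X^2)
  if (normX2 == 0)
    oa_stop("degenerate_error", "cannot decompose an all-zero tensor")
  Fn <- as.integer(n_factors)
  X1 <- matrix(X, d[1])                       # I x JK, j fastest
  X2 <- matrix(aperm(X, c(2, 1, 3)), d[2])    # J x IK, i fastest
  X3 <- matrix(aperm(X, c(3, 1, 2)), d[3])    # K x IJ, i fastest

  best <- NULL
  for (r in seq_len(restarts)) {
    state <- with_seed(seed + r - 1, {
      A <- matrix(stats::runif(d[1] * Fn), d[1])
      B <- matrix(stats::runif(d[2] * Fn), d[2])
      C <- matrix(stats::runif(d[3] * Fn), d[3])
      sse_hist <- numeric(0)
      fit_prev <- -Inf
      converged <- FALSE
      it <- 0L
      while (it < max_iter) {
        it <- it + 1L
        A <- .solve_gram(X1 %*% khatri_rao(C, B),
                         crossprod(C) * crossprod(B))
        if (nonneg) A <- pmax(A, 0)
        B <- .solve_gram(X2 %*% khatri_rao(C, A),
                         crossprod(C) * crossprod(A))
        if (nonneg) B <- pmax(B, 0)
        C <- .solve_gram(X3 %*% khatri_rao(B, A),
                         crossprod(B) * crossprod(A))
        if (nonneg) C <- pmax(C, 0)
        sse <- sum((X1 - tcrossprod(A, khatri_rao(C, B)))^2)
        sse_hist <- c(sse_hist, sse)
        fit <- 1 - sse / normX2
        if (abs(fit - fit_prev) <
            tol * max(abs(fit_prev), .Machine$double.eps)) {
          converged <- TRUE
          break
        }
        fit_prev <- fit
      }
      list(A = A, B = B, C = C, sse = sse_hist[length(sse_hist)],
           sse_history = sse_hist, n_iterations = it,
           converged = converged)
    })
    if (is.null(best) || state$sse < best$sse) best <- state
  }

  # normalize: unit-norm A and B columns, scale into C, deterministic signs
  A <- best$A; B <- best$B; C <- best$C
  for (f in seq_len(Fn)) {
    na <- sqrt(sum(A[, f]^2)); nb <- sqrt(sum(B[, f]^2))
    if (na > 0) { A[, f] <- A[, f] / na } else na <- 1
    if (nb > 0) { B[, f] <- B[, f] / nb } else nb <- 1
    C[, f] <- C[, f] * na * nb
    sa <- sign(A[which.max(abs(A[, f])), f]); if (sa == 0) sa <- 1
    sb <- sign(B[which.max(abs(B[, f])), f]); if (sb == 0) sb <- 1
    A[, f] <- sa * A[, f]
    B[, f] <- sb * B[, f]
    C[, f] <- sa * sb * C[, f]
  }
  ord <- order(colSums(C^2), decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  B <- B[, ord, drop = FALSE]
  C <- C[, ord, drop = FALSE]

  meta <- NULL
  if (inherits(x, "trial_tensor"))
    meta <- x[c("unit_labels", "bin_edges_s", "trial_numbers",
                "stimulus_labels", "block_labels", "trial_labels")]
  structure(
    list(A = A, B = B, C = C, n_factors = Fn,
         fit_fraction = max(0, min(1, 1 - best$sse / normX2)),
         n_iterations = best$n_iterations,
         converged = best$converged,
         sse_history = best$sse_history,
         dims = d, meta = meta),
    class = "cp_model"
  )
}

#' @export
print.cp_model <- function(x, ...) {
  cat(sprintf(
    "CP model: %d factor(s) on a %s tensor; fit fraction %.4f (%s in %d iter)\n",
    x$n_factors, paste(x$dims, collapse = " x "), x$fit_fraction,
    if (x$converged) "converged" else "not converged", x$n_iterations))
  invisible(x)
}

#' Core-consistency diagnostic (CORCONDIA)
#'
#' Computes the least-squares Tucker core `G` for the fixed CP loadings
#' (via the factor-matrix pseudo-inverses) and measures its distance from
#' the ideal superdiagonal core `T` (ones on the superdiagonal):
#' `100 * (1 - sum((G - T)^2) / sum(T^2))`. The value is at most 100
#' (attained when the trilinear structure is exact) and unbounded below;
#' values dropping sharply indicate that `F` exceeds the trilinear rank.
#'
#' @param x The tensor the model was fitted to.
#' @param model A [cp_als()] fit with matching dimensions.
#' @return Core-consistency percentage (scalar).
#' @export
core_consistency <- function(x, model) {
  X <- .as_array3(x)
  stopifnot(inherits(model, "cp_model"))
  if (!identical(dim(X), model$dims))
    oa_stop("usage_error",
            "model dimensions (%s) do not match tensor (%s)",
            paste(model$dims, collapse = "x"),
            paste(dim(X), collapse = "x"))
  Fn <- model$n_factors
  G <- .ttm(.ttm(.ttm(X, MASS::ginv(model$A), 1),
                 MASS::ginv(model$B), 2),
            MASS::ginv(model$C), 3)
  Tsup <- array(0, c(Fn, Fn, Fn))
  for (f in seq_len(Fn)) Tsup[f, f, f] <- 1
  100 * (1 - sum((G - Tsup)^2) / Fn)
}

#' Select the number of CP factors by core consistency
#'
#' Fits each candidate factor count and keeps the largest candidate whose
#' core consistency stays at or above the threshold — the usual reading of
#' the diagnostic, where over-factored models collapse. If no candidate
#' qualifies, the smallest candidate is returned with a warning flag set.
#'
#' @param x A [trial_tensor()] or 3-d array.
#' @param candidates Ascending integer vector of factor counts to try
#'   (default `1:5`).
#' @param threshold_pct Core-consistency acceptance threshold in percent
#'   (default 50).
#' @param ... Passed to [cp_als()] (`restarts`, `tol`, `max_iter`, `seed`).
#' @return An object of class `corcon_report`: `per_F` (named numeric of
#'   core consistencies), `selected_F`, `threshold_pct`, `warning_flag`,
#'   and the fitted `models` list.
#' @export
select_num_factors <- function(x, candidates = 1:5, threshold_pct = 50,
                               ...) {
  if (!length(candidates) || is.unsorted(candidates, strictly = TRUE))
    oa_stop("usage_error", "candidates must be non-empty and ascending")
  X <- .as_array3(x)
  models <- lapply(candidates, function(f) cp_als(X, f, ...))
  per_F <- vapply(models, function(m) core_consistency(X, m), numeric(1))
  names(per_F) <- as.character(candidates)
  names(models) <- as.character(candidates)
  ok <- which(per_F >= threshold_pct)
  warning_flag <- length(ok) == 0L
  selected <- if (warning_flag) candidates[1] else candidates[max(ok)]
  structure(list(per_F = per_F, selected_F = as.integer(selected),
                 threshold_pct = threshold_pct,
                 warning_flag = warning_flag, models = models),
            class = "corcon_report")
}

#' @export
print.corcon_report <- function(x, ...) {
  cat("Core-consistency scan (threshold", x$threshold_pct, "%):\n")
  for (f in names(x$per_F))
    cat(sprintf("  F = %s: %8.2f %%%s\n", f, x$per_F[[f]],
                if (as.integer(f) == x$selected_F) "  <- selected" else ""))
  if (x$warning_flag)
    cat("  warning: no candidate met the threshold; smallest returned\n")
  invisible(x)
}

#' Reconstruct the denoised tensor from a CP model
#'
#' Computes `xhat_ijk = sum_f a_if * b_jf * c_kf`, the model's rank-F
#' approximation. The result is real-valued (not re-integerized).
#'
#' @param model A [cp_als()] fit.
#' @return A 3-d numeric array with the model's dimensions (and the original
#'   axis labels as `dimnames` when available).
#' @export
reconstruct_tensor <- function(model) {
  stopifnot(inherits(model, "cp_model"))
  out <- array(tcrossprod(model$A, khatri_rao(model$C, model$B)),
               dim = model$dims)
  if (!is.null(model$meta))
    dimnames(out) <- list(model$meta$unit_labels, NULL,
                          model$meta$trial_labels)
  out
}
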