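#' Symmetric relative mean squared error (percent)
#'
#' `MSE_rel = 2 ||Y_pred - Y_true||_F^2 / (||Y_pred||_F^2 + ||Y_true||_F^2)`,
#' reported in percent. The denominator averages the squared norms of both
#' arguments, so experiments with small signal cannot dominate and the
#' error is bounded: 0% iff the arguments are equal, 200% when exactly one
#' of them is zero. Symmetric and invariant to common positive rescaling.
#'
#' @param Y_pred,Y_true numeric vectors or matrices of equal shape, not
#'   both identically zero.
#' @return percentage in \[0, 200\].
#' @export
mse_rel <- function(Y_pred, Y_true) {
  if (length(Y_pred) != length(Y_true)) stop("shape mismatch")
  denom <- sum(Y_pred^2) + sum(Y_true^2)
  if (denom == 0) stop("both arguments are identically zero (0/0)")
  200 * sum((Y_pred - Y_true)^2) / denom
}

#' Classical relative mean squared error (percent)
#'
#' The usual data-normalized ratio
#' `||Y_pred - Y_true||_F^2 / ||Y_true||_F^2`, in percent. Unbounded when
#' the truth is small; provided for comparison with [mse_rel].
#'
#' @inheritParams mse_rel
#' @return nonnegative percentage (unbounded).
#' @export
naive_relative_mse <- function(Y_pred, Y_true) {
  if (length(Y_pred) != length(Y_true)) stop("shape mismatch")
  denom <- sum(Y_true^2)
  if (denom == 0) stop("Y_true is identically zero")
  100 * sum((Y_pred - Y_true)^2) / denom
}

#' Closed-form leave-one-out coefficient matrix
#'
#' Given the column-stochastic kernel matrix `A_c` evaluated at the
#' injection centers, the leave-one-out coefficients are obtained by
#' zeroing the diagonal and renormalizing each column:
#' `(A_c^CV)[i, j] = A_c[i, j] / (1 - A_c[j, j])` for `i != j`, 0 on the
#' diagonal. Column j then equals the coefficients of a model refit
#' without experiment j, evaluated at its own injection center — the
#' closed-form shortcut that makes leave-one-out cross-validation cheap
#' for this linear smoother.
#'
#' Columns whose diagonal entry is 1 (an experiment alone in its division)
#' admit no leave-one-out prediction: they are zeroed, flagged in the
#' `no_loo_support` attribute and a warning is issued.
#'
#' @param A_c m x m column-stochastic kernel matrix (see
#'   [centroid_coefficients]).
#' @return m x m matrix with zero diagonal and columns summing to 1, with
#'   attribute `no_loo_support` (integer indices of flagged columns).
#' @export
loo_coefficients <- function(A_c) {
  m <- ncol(A_c)
  if (nrow(A_c) != m) stop("A_c must be square")
  d <- diag(A_c)
  lone <- which(1 - d <= 1e-12)
  Acv <- A_c
  diag(Acv) <- 0
  keep <- setdiff(seq_len(m), lone)
  if (length(keep) > 0L) {
    Acv[, keep] <- sweep(Acv[, keep, drop = FALSE], 2, 1 - d[keep], "/")
  }
  if (length(lone) > 0L) {
    Acv[, lone] <- 0
    warning(sprintf("no LOO support for experiment(s) %s (alone in their division)",
                    paste(lone, collapse = ", ")))
  }
  attr(Acv, "no_loo_support") <- lone
  Acv
}

#' Leave-one-out predictions for all experiments
#'
#' `Yhat = Ybar %*% A_c^CV`: column e is the projection pattern predicted
#' at experiment e's injection center by a model fit without experiment e.
#' Identical (to floating tolerance) to brute-force refitting m times.
#'
#' @param experiments an [experiment_set]; every evaluated experiment's
#'   division needs at least 2 experiments (lone ones are flagged).
#' @param sigma_by_division bandwidth(s), as in [compute_coefficients].
#' @return n x m matrix of held-out predictions, with attribute
#'   `no_loo_support` listing flagged columns (all zero).
#' @export
loo_predictions <- function(experiments, sigma_by_division) {
  model <- fit_kernel_model(experiments, sigma_by_division)
  Acv <- loo_coefficients(centroid_coefficients(model))
  Yhat <- model$Ybar %*% Acv
  attr(Yhat, "no_loo_support") <- attr(Acv, "no_loo_support")
  Yhat
}

#' Default bandwidth search grid
#'
#' 11 logarithmically spaced values spanning 4 to 50 lattice units (100 um
#' voxels), the grid used for nested cross-validated bandwidth selection.
#'
#' @param lo,hi,k grid range and size.
#' @return numeric vector of length `k`.
#' @export
default_sigma_grid <- function(lo = 4, hi = 50, k = 11) {
  exp(seq(log(lo), log(hi), length.out = k))
}

# modal value of x; ties broken toward the largest value
.modal_largest <- function(x) {
  tab <- table(x)
  cands <- as.numeric(names(tab)[tab == max(tab)])
  max(cands)
}

#' Nested leave-one-out cross-validation with bandwidth selection
#'
#' For each major division (independently, since the estimator decouples
#' across divisions) and each outer held-out experiment, an inner
#' closed-form leave-one-out pass over the remaining experiments selects
#' the bandwidth from `sigma_grid` (minimizing the stacked symmetric
#' relative error; ties go to the larger, smoother bandwidth). The outer
#' model is then fit on those experiments with the selected bandwidth and
#' evaluated on the held-out experiment at its injection center.
#'
#' Per-division errors aggregate held-out predictions into a single
#' stacked-matrix [mse_rel] (Frobenius form), so experiments with larger
#' signal carry more weight. Regional errors apply the aggregation
#' operator to both prediction and truth first. Training errors use the
#' in-sample centroid predictions `Ybar %*% A_c` under the bandwidth
#' selected most often across outer folds (ties to larger). The power to
#' predict (PTP) restricts the same error to held-out experiments whose
#' source region contains at least `min_replicates` experiments in total.
#'
#' @param experiments an [experiment_set].
#' @param sigma_grid candidate bandwidths (default [default_sigma_grid]).
#' @param min_replicates minimum number of same-region experiments
#'   (including the held-out one) for an experiment to enter the PTP
#'   subset; the default 2 means "at least one other injection in that
#'   region".
#' @return An `eval_report`: a data.frame with one row per evaluated
#'   division and columns `division`, `n_experiments`, `n_replicated`,
#'   `sigma`, `voxel_mse_rel`, `voxel_mse_rel_train`, `region_mse_rel`,
#'   `region_mse_rel_train`, `ptp`, `ptp_train`, plus attribute
#'   `fold_sigmas` (list of per-fold selected bandwidths). Divisions with
#'   fewer than 3 experiments are skipped with a warning. PTP is `NA`
#'   where the replicated subset is empty.
#' @export
nested_cv <- function(experiments, sigma_grid = default_sigma_grid(),
                      min_replicates = 2) {
  if (length(sigma_grid) == 0L) stop("sigma_grid must be nonempty")
  sigma_grid <- sort(as.numeric(sigma_grid))
  lat <- experiments$lattice
  ec <- experiment_centroids(experiments)
  Ybar <- ybar_matrix(experiments)
  ops <- regionalization_operators(lat)
  exp_region <- lat$region[ec$voxels]

  rows <- list()
  fold_sigmas <- list()
  for (k in sort(unique(ec$divisions))) {
    idx <- which(ec$divisions == k)
    mk <- length(idx)
    if (mk < 3L) {
      warning(sprintf("division %d has %d experiment(s) (<3); skipped", k, mk))
      next
    }
    # squared distances between snapped centers (points, rows index the
    # kernel/experiment, cols index the evaluation point)
    pts <- lat$coords[ec$voxels[idx], , drop = FALSE]
    cen <- ec$centroids[idx, , drop = FALSE]
    D2 <- outer(rowSums(cen^2), rowSums(pts^2), "+") - 2 * cen %*% t(pts)
    D2[D2 < 0] <- 0
    Yk <- Ybar[, idx, drop = FALSE]

    sel <- numeric(mk)
    Yhat_val <- matrix(0, nrow(Ybar), mk)
    for (o in seq_len(mk)) {
      S <- setdiff(seq_len(mk), o)
      best_err <- Inf; best_sig <- sigma_grid[1]
      for (sig in sigma_grid) {
        Ks <- exp(-D2[S, S, drop = FALSE] / (2 * sig^2))
        cs <- colSums(Ks)
        if (any(cs == 0)) {  # total underflow: weight the nearest neighbor
          for (j in which(cs == 0)) Ks[which.min(D2[S, S[j]]), j] <- 1
          cs <- colSums(Ks)
        }
        Ac <- sweep(Ks, 2, cs, "/")
        Acv <- suppressWarnings(loo_coefficients(Ac))
        err <- mse_rel(Yk[, S, drop = FALSE] %*% Acv, Yk[, S, drop = FALSE])
        if (err <= best_err) { best_err <- err; best_sig <- sig }
      }
      sel[o] <- best_sig
      w <- exp(-D2[S, o] / (2 * best_sig^2))
      if (sum(w) == 0) w[which.min(D2[S, o])] <- 1
      Yhat_val[, o] <- Yk[, S, drop = FALSE] %*% (w / sum(w))
    }

    # training predictions under the most frequently selected bandwidth
    sig_train <- .modal_largest(sel)
    Kt <- exp(-D2 / (2 * sig_train^2))
    Ac_train <- sweep(Kt, 2, colSums(Kt), "/")
    Yhat_train <- Yk %*% Ac_train

    YkR <- as.matrix(ops$Pi %*% Yk)
    reps <- which(tabulate(exp_region[idx],
                           lat$n_regions)[exp_region[idx]] >= min_replicates)
    rows[[length(rows) + 1L]] <- data.frame(
      division = k, n_experiments = mk, n_replicated = length(reps),
      sigma = sig_train,
      voxel_mse_rel = mse_rel(Yhat_val, Yk),
      voxel_mse_rel_train = mse_rel(Yhat_train, Yk),
      region_mse_rel = mse_rel(as.matrix(ops$Pi %*% Yhat_val), YkR),
      region_mse_rel_train = mse_rel(as.matrix(ops$Pi %*% Yhat_train), YkR),
      ptp = if (length(reps) > 0)
        mse_rel(as.matrix(ops$Pi %*% Yhat_val[, reps, drop = FALSE]),
                YkR[, reps, drop = FALSE]) else NA_real_,
      ptp_train = if (length(reps) > 0)
        mse_rel(as.matrix(ops$Pi %*% Yhat_train[, reps, drop = FALSE]),
                YkR[, reps, drop = FALSE]) else NA_real_)
    fold_sigmas[[as.character(k)]] <- sel
  }
  if (length(rows) == 0L) stop("no division has >= 3 experiments")
  report <- do.call(rbind, rows)
  attr(report, "fold_sigmas") <- fold_sigmas
  class(report) <- c("eval_report", "data.frame")
  report
}

#' Power to predict: held-out error on replicated injections
#'
#' Restricts the leave-one-out regional error to experiments whose source
#' region received at least `min_replicates` injections in total (default
#' 2: at least one other injection in that region). Without a replicate,
#' the model's only information about a region's projections comes from
#' the smoothness assumption, so this subset measures predictive power
#' where direct evidence exists.
#'
#' @param experiments an [experiment_set].
#' @param loo_pred n x m matrix of held-out predictions
#'   ([loo_predictions]).
#' @param min_replicates minimum same-region experiment count (including
#'   the experiment itself).
#' @param regionalized aggregate predictions and truth to regions before
#'   computing the error (default TRUE, the Region PTP of the model
#'   comparison); FALSE computes the voxel-level equivalent.
#' @return data.frame with one row per division: `division`,
#'   `n_replicated`, `ptp` (`NA` where the subset is empty).
#' @export
power_to_predict <- function(experiments, loo_pred, min_replicates = 2,
                             regionalized = TRUE) {
  lat <- experiments$lattice
  ec <- experiment_centroids(experiments)
  exp_region <- lat$region[ec$voxels]
  Ybar <- ybar_matrix(experiments)
  drop_cols <- attr(loo_pred, "no_loo_support")
  if (regionalized) {
    ops <- regionalization_operators(lat)
    loo_pred <- as.matrix(ops$Pi %*% loo_pred)
    Ybar <- as.matrix(ops$Pi %*% Ybar)
  }
  region_counts <- tabulate(exp_region, lat$n_regions)
  out <- lapply(sort(unique(ec$divisions)), function(k) {
    idx <- which(ec$divisions == k)
    reps <- idx[region_counts[exp_region[idx]] >= min_replicates]
    reps <- setdiff(reps, drop_cols)
    data.frame(division = k, n_replicated = length(reps),
               ptp = if (length(reps) > 0)
                 mse_rel(loo_pred[, reps, drop = FALSE],
                         Ybar[, reps, drop = FALSE]) else NA_real_)
  })
  do.call(rbind, out)
}
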