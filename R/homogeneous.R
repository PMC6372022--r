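#' Fit the regionally homogeneous baseline model
#'
#' Fits an r x r nonnegative matrix `W_homog` to regionalized data by
#' nonnegative least squares:
#' `W_homog = argmin_{W >= 0} || W X^R - Y^R ||_F^2`,
#' with `X^R = Pi X` and `Y^R = Pi Y` the regionalized raw injection and
#' projection densities. The Frobenius objective separates over target
#' regions, so each row is an independent NNLS problem (solved with the
#' Lawson-Hanson algorithm). Entry (i, j) is the expected fluorescence
#' volume in region i per unit of virus in region j (a normalized
#' connection strength); exact zeros are permitted and are this model's
#' characteristic failure mode on sparse data.
#'
#' @param experiments an [experiment_set].
#' @param ops optional precomputed [regionalization_operators].
#' @return An object of class `homogeneous_model`: list with `W` (r x r
#'   nonnegative), `residual_norms` (per target row), `design_rank` and
#'   `n_regions`. A message notes a rank-deficient design (the fit still
#'   proceeds; NNLS handles it).
#' @export
fit_homogeneous <- function(experiments, ops = NULL) {
  lat <- experiments$lattice
  if (is.null(ops)) ops <- regionalization_operators(lat)
  Xm <- vapply(experiments$experiments, `[[`, numeric(lat$n), "X")
  Ym <- vapply(experiments$experiments, `[[`, numeric(lat$n), "Y")
  XR <- as.matrix(ops$Pi %*% Xm)  # r x m
  YR <- as.matrix(ops$Pi %*% Ym)
  .fit_homogeneous_regional(XR, YR)
}

# row-separable NNLS on already-regionalized design/response (r x m each)
.fit_homogeneous_regional <- function(XR, YR) {
  r <- nrow(XR)
  C <- t(XR)  # m x r design shared by every target row
  design_rank <- qr(C)$rank
  if (design_rank < r) {
    message(sprintf("regionalized design has rank %d < %d regions; NNLS proceeds but some sources are unconstrained",
                    design_rank, r))
  }
  W <- matrix(0, r, r)
  resn <- numeric(r)
  for (i in seq_len(r)) {
    fit <- pracma::lsqnonneg(C, YR[i, ])
    W[i, ] <- fit$x
    resn[i] <- sqrt(fit$resid.norm)
  }
  structure(list(W = W, residual_norms = resn, design_rank = design_rank,
                 n_regions = r),
            class = "homogeneous_model")
}

#' @export
print.homogeneous_model <- function(x, ...) {
  cat(sprintf("homogeneous_model: %d x %d nonnegative regional matrix (%.0f%% zero entries)\n",
              x$n_regions, x$n_regions, 100 * mean(x$W == 0)))
  invisible(x)
}

#' Regional prediction of the homogeneous model
#'
#' `W_homog %*% (Pi X)`: unlike the voxel model (which predicts from a
#' unit injection at the center of mass), the homogeneous model predicts
#' the projection of the full injection vector.
#'
#' @param model a `homogeneous_model`.
#' @param X length-n voxel injection-density vector.
#' @param ops [regionalization_operators] for the lattice.
#' @return length-r predicted regional projection.
#' @export
predict_homogeneous <- function(model, X, ops) {
  if (length(X) != ncol(ops$Pi)) stop("X length does not match lattice")
  if (model$n_regions != nrow(ops$Pi)) stop("parcellation mismatch")
  as.numeric(model$W %*% (ops$Pi %*% X))
}

#' Compare the regionalized voxel model with the homogeneous model
#'
#' Evaluates both models on identical leave-one-out folds. The voxel
#' model uses the closed-form LOO at the bandwidths stored in
#' `voxel_model`; the homogeneous model is refit from scratch on each
#' fold (no closed form exists for NNLS). Each model is scored in
#' regional space against its own fitting target: the regionalized
#' normalized projection density `Pi Ybar` for the voxel model and the
#' regionalized raw projection density `Pi Y` for the homogeneous model —
#' the two predictions are deliberately different objects (unit-centroid
#' injection vs full injection).
#'
#' @param voxel_model a `kernel_model` fit on `experiments`.
#' @param homog_model a `homogeneous_model` fit on `experiments` (used for
#'   compatibility checks and in-sample diagnostics; LOO folds refit it).
#' @param experiments the shared [experiment_set].
#' @param min_replicates PTP subset threshold, as in [power_to_predict].
#' @return An object of class `model_comparison`: list with
#'   `by_division` (data.frame: `division`, `n_experiments`,
#'   `voxel_region_mse_rel`, `homog_region_mse_rel`, `voxel_ptp`,
#'   `homog_ptp`, `n_replicated`) and `by_experiment` (data.frame:
#'   `experiment`, `division`, `voxel_r2`, `homog_r2` — squared Pearson
#'   correlations between predicted and observed regional weights).
#' @export
compare_models <- function(voxel_model, homog_model, experiments,
                           min_replicates = 2) {
  lat <- experiments$lattice
  if (!identical(lat$n, voxel_model$lattice$n) ||
      homog_model$n_regions != lat$n_regions) {
    stop("models and experiments must share one lattice/parcellation")
  }
  ops <- regionalization_operators(lat)
  ec <- experiment_centroids(experiments)
  m <- n_experiments(experiments)
  exp_region <- lat$region[ec$voxels]
  region_counts <- tabulate(exp_region, lat$n_regions)

  # voxel model: closed-form LOO, regionalized
  Yhat_vox <- loo_predictions(experiments, voxel_model$sigma_by_division)
  drop_cols <- attr(Yhat_vox, "no_loo_support")
  YR_vox_pred <- as.matrix(ops$Pi %*% Yhat_vox)
  YR_vox_true <- as.matrix(ops$Pi %*% ybar_matrix(experiments))

  # homogeneous model: brute-force refit per fold
  Xm <- vapply(experiments$experiments, `[[`, numeric(lat$n), "X")
  Ym <- vapply(experiments$experiments, `[[`, numeric(lat$n), "Y")
  XR <- as.matrix(ops$Pi %*% Xm)
  YR <- as.matrix(ops$Pi %*% Ym)
  YR_hom_pred <- matrix(0, lat$n_regions, m)
  for (e in seq_len(m)) {
    fit <- suppressMessages(
      .fit_homogeneous_regional(XR[, -e, drop = FALSE],
                                YR[, -e, drop = FALSE]))
    YR_hom_pred[, e] <- fit$W %*% XR[, e]
  }

  by_div <- lapply(sort(unique(ec$divisions)), function(k) {
    idx <- setdiff(which(ec$divisions == k), drop_cols)
    reps <- idx[region_counts[exp_region[idx]] >= min_replicates]
    data.frame(
      division = k, n_experiments = length(idx),
      n_replicated = length(reps),
      voxel_region_mse_rel = mse_rel(YR_vox_pred[, idx, drop = FALSE],
                                     YR_vox_true[, idx, drop = FALSE]),
      homog_region_mse_rel = mse_rel(YR_hom_pred[, idx, drop = FALSE],
                                     YR[, idx, drop = FALSE]),
      voxel_ptp = if (length(reps) > 0)
        mse_rel(YR_vox_pred[, reps, drop = FALSE],
                YR_vox_true[, reps, drop = FALSE]) else NA_real_,
      homog_ptp = if (length(reps) > 0)
        mse_rel(YR_hom_pred[, reps, drop = FALSE],
                YR[, reps, drop = FALSE]) else NA_real_)
  })
  r2 <- function(pred, obs) {
    if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
    stats::cor(pred, obs)^2
  }
  by_exp <- data.frame(
    experiment = seq_len(m), division = ec$divisions,
    voxel_r2 = vapply(seq_len(m), function(e)
      r2(YR_vox_pred[, e], YR_vox_true[, e]), numeric(1)),
    homog_r2 = vapply(seq_len(m), function(e)
      r2(YR_hom_pred[, e], YR[, e]), numeric(1)))
  structure(list(by_division = do.call(rbind, by_div),
                 by_experiment = by_exp),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  d <- x$by_division
  wins <- sum(d$voxel_region_mse_rel < d$homog_region_mse_rel)
  cat(sprintf("model_comparison: voxel model lower Region MSE_rel in %d/%d divisions\n",
              wins, nrow(d)))
  print(d, row.names = FALSE)
  invisible(x)
}
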