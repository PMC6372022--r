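#' Gaussian radial basis kernel
#'
#' `K_sigma(d) = exp(-d^2 / (2 sigma^2))`, the spatial kernel used to
#' weight experiments by the distance between a source voxel and an
#' injection centroid. Monotone decreasing in `d`, equal to 1 at `d = 0`.
#'
#' @param d nonnegative distance(s), lattice units.
#' @param sigma positive bandwidth (lattice units).
#' @return kernel weight(s) in (0, 1].
#' @export
gaussian_kernel <- function(d, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(d < 0)) stop("distances must be nonnegative")
  exp(-d^2 / (2 * sigma^2))
}

# kernel weights of experiments (rows) at arbitrary points (cols), with the
# division restriction and the underflow fallback applied.
# centroids: m x 3; divisions: per-experiment division; points: p x 3;
# point_division: per-point division; sigma_by_division: length-s vector.
# Returns m x p column-stochastic matrix (all-zero columns only where the
# point's division has no experiments).
.kernel_coefficients <- function(centroids, divisions, points,
                                 point_division, sigma_by_division,
                                 warn_empty = TRUE) {
  m <- nrow(centroids); p <- nrow(points)
  A <- matrix(0, m, p)
  s <- length(sigma_by_division)
  empty <- integer(0)
  for (k in seq_len(s)) {
    cols <- which(point_division == k)
    if (length(cols) == 0L) next
    rows <- which(divisions == k)
    if (length(rows) == 0L) {
      empty <- c(empty, k)
      next
    }
    # p_k x m_k distances between points in division k and its centroids
    d2 <- outer(rowSums(points[cols, , drop = FALSE]^2),
                rowSums(centroids[rows, , drop = FALSE]^2), "+") -
      2 * points[cols, , drop = FALSE] %*% t(centroids[rows, , drop = FALSE])
    d2[d2 < 0] <- 0  # guard tiny negative values from cancellation
    if (anyNA(d2)) stop("NaN distances encountered")
    Kmat <- exp(-d2 / (2 * sigma_by_division[k]^2))  # p_k x m_k
    norms <- rowSums(Kmat)
    under <- norms == 0
    if (any(under)) {
      # all kernel weights underflowed: fall back to the nearest experiment
      nn <- apply(d2[under, , drop = FALSE], 1, which.min)
      Kmat[under, ] <- 0
      Kmat[cbind(which(under), nn)] <- 1
      norms[under] <- 1
    }
    A[rows, cols] <- t(Kmat / norms)
  }
  if (warn_empty && length(empty) > 0L) {
    warning(sprintf("no injections in division(s) %s; their columns are zero",
                    paste(empty, collapse = ", ")))
  }
  A
}

#' Nadaraya-Watson coefficient matrix
#'
#' Computes the m x n coefficient matrix A with entries
#' `alpha_ej = K_sigma(||v_j - c_e||) / sum_f K_sigma(||v_j - c_f||)`,
#' where both sums run only over experiments whose centroid lies in the
#' same major division as voxel j. Columns over divisions containing at
#' least one experiment sum to 1; entries pairing a voxel with an
#' experiment from another division are exactly 0. Divisions with voxels
#' but no experiments yield all-zero columns and a warning.
#'
#' When every kernel weight at a voxel underflows to zero (a distant voxel
#' under a tiny bandwidth) the full weight is assigned to the nearest
#' experiment, preserving the column-sum-1 invariant and the nearest-
#' injection limit as `sigma -> 0`.
#'
#' @param experiments an [experiment_set].
#' @param sigma_by_division positive bandwidth(s), lattice units: either a
#'   single value recycled to all divisions or one value per division.
#' @return m x n matrix A.
#' @export
compute_coefficients <- function(experiments, sigma_by_division) {
  lat <- experiments$lattice
  sig <- .expand_sigma(sigma_by_division, lat$n_divisions)
  ec <- experiment_centroids(experiments)
  .kernel_coefficients(ec$centroids, ec$divisions, lat$coords,
                       lat$division, sig)
}

.expand_sigma <- function(sigma, s) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (length(sigma) == 1L) rep(sigma, s)
  else if (length(sigma) == s) as.numeric(sigma)
  else stop("sigma_by_division must have length 1 or one value per division")
}

#' Fit the factored voxel connectome model
#'
#' Assembles the rank-m factorization `W = Ybar %*% A` of the voxel
#' connectome without materializing the n x n matrix W: `Ybar` (n x m)
#' collects the normalized projection densities and `A` (m x n) the
#' division-restricted Nadaraya-Watson coefficients.
#'
#' @inheritParams compute_coefficients
#' @return An object of class `kernel_model` with fields `Ybar` (n x m),
#'   `A` (m x n), `sigma_by_division`, `lattice`, `centroid_voxels` and
#'   `centroid_divisions`.
#' @export
fit_kernel_model <- function(experiments, sigma_by_division) {
  lat <- experiments$lattice
  sig <- .expand_sigma(sigma_by_division, lat$n_divisions)
  ec <- experiment_centroids(experiments)
  structure(
    list(Ybar = ybar_matrix(experiments),
         A = compute_coefficients(experiments, sig),
         sigma_by_division = sig,
         lattice = lat,
         centroid_voxels = ec$voxels,
         centroid_divisions = ec$divisions),
    class = "kernel_model")
}

#' @export
print.kernel_model <- function(x, ...) {
  cat(sprintf("kernel_model: rank-%d factored connectome on %d voxels\n",
              ncol(x$Ybar), nrow(x$Ybar)))
  cat("sigma by division:",
      paste(signif(x$sigma_by_division, 4), collapse = " "), "\n")
  invisible(x)
}

#' Predicted projection pattern from one source voxel
#'
#' Column j of the connectome, `W[, j] = Ybar %*% A[, j]`: a convex
#' combination of the normalized projection densities of the experiments
#' in the source voxel's division.
#'
#' @param model a [fit_kernel_model] result.
#' @param source_voxel voxel index.
#' @return length-n nonnegative vector.
#' @export
predict_projection <- function(model, source_voxel) {
  a <- model$A[, source_voxel]
  if (sum(a) == 0) {
    stop("no model support at source: its division has no experiments")
  }
  as.numeric(model$Ybar %*% a)
}

#' Virtual injection: mean prediction over a set of source voxels
#'
#' The model-predicted projection pattern of a simultaneous injection into
#' a set of voxels: the average of the corresponding columns of W,
#' computed through the rank-m factorization as
#' `Ybar %*% rowMeans(A[, sources])` so W is never formed.
#'
#' @param model a `kernel_model`.
#' @param source_voxels integer vector of voxel indices (nonempty, all in
#'   divisions containing experiments).
#' @return length-n nonnegative vector.
#' @export
virtual_injection <- function(model, source_voxels) {
  if (length(source_voxels) == 0L) stop("empty source set")
  a_cols <- model$A[, source_voxels, drop = FALSE]
  if (any(colSums(a_cols) == 0)) {
    stop("no model support at source: a division has no experiments")
  }
  as.numeric(model$Ybar %*% rowMeans(a_cols))
}

#' Materialize a dense block of the voxel connectome
#'
#' Computes `W[targets, sources] = Ybar[targets, ] %*% A[, sources]`. The
#' full W is quadratic in the voxel count and is never needed; this
#' extracts a requested block, refusing blocks beyond a memory budget.
#'
#' @param model a `kernel_model`.
#' @param source_voxels,target_voxels integer index vectors.
#' @param max_entries refuse blocks with more than this many entries
#'   (default 5e7, ~400 MB of doubles).
#' @return dense `length(target_voxels)` x `length(source_voxels)` matrix.
#' @export
materialize_submatrix <- function(model, source_voxels, target_voxels,
                                  max_entries = 5e7) {
  nt <- length(target_voxels); ns <- length(source_voxels)
  if (as.double(nt) * ns > max_entries) {
    stop("requested block exceeds the memory budget; extract it in chunks")
  }
  model$Ybar[target_voxels, , drop = FALSE] %*%
    model$A[, source_voxels, drop = FALSE]
}

#' Kernel coefficients evaluated at the injection centers
#'
#' The m x m matrix `A_c = A %*% C`, where C is the indicator matrix of
#' snapped centroid voxels: column e holds the coefficients of the model
#' evaluated at experiment e's own injection center, so `Ybar %*% A_c` is
#' the in-sample prediction of every experiment's projections.
#'
#' @param model a `kernel_model`.
#' @return m x m column-stochastic matrix.
#' @export
centroid_coefficients <- function(model) {
  model$A[, model$centroid_voxels, drop = FALSE]
}
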