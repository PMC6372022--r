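#' Configuration for the synthetic tracing-data generator
#'
#' Collects the study-design parameters of a simulated tracing dataset:
#' a box lattice split into contiguous division slabs (each subdivided
#' into nested regions), a smooth nonnegative ground-truth connectome,
#' and simulated injections. Defaults emulate the conditions the method
#' targets: 100 um voxels, injections of radius 3 voxels (0.3 mm), about
#' one injection per (5 voxel)^3 of tissue (0.5 mm typical spacing
#' between a voxel and its nearest injection), a within-division
#' smoothness scale in the middle of the default bandwidth search grid,
#' and moderate multiplicative lognormal fluorescence noise.
#'
#' @param dims integer length-3 lattice dimensions (voxels per axis).
#' @param n_divisions number of major divisions (contiguous slabs along
#'   the first axis).
#' @param n_regions total number of regions (distributed over divisions,
#'   contiguous bands along the second axis).
#' @param m number of simulated experiments (centroids cycle through the
#'   divisions so each division is populated evenly).
#' @param injection_radius injection radius in voxels (0 = point
#'   injection at the centroid voxel); default 3 voxels = 0.3 mm.
#' @param sigma_true within-division smoothness scale of the ground
#'   truth, lattice units; default is a mid-grid point of
#'   [default_sigma_grid] (~11 voxels).
#' @param anchors_per_division number of random anchor patterns whose
#'   kernel interpolation forms each division's smooth columns.
#' @param noise_sd standard deviation (natural-log scale) of the
#'   mean-preserving multiplicative lognormal noise on projections;
#'   0 disables noise.
#' @param detection_threshold projection densities below this value are
#'   zeroed, mimicking fluorescence segmentation detection limits.
#' @param heterogeneous `TRUE` (default): columns vary smoothly within
#'   divisions (the voxel model's regime). `FALSE`: columns are constant
#'   within each region, i.e. the ground truth is the spread of an r x r
#'   regional matrix (the homogeneous model's generative regime).
#' @param add_identity add the identity to the ground-truth connectome
#'   (unit self-projection at the injected voxel). This is the regime
#'   exactly consistent with the normalized projection density
#'   `(Y + X)/sum(X)`, which folds the injected unit mass back into the
#'   response; disable for analyses of the pure cross-voxel kernel.
#' @param zero_injection_site zero the simulated projection density over
#'   the injection site (the injection/projection split of the real
#'   segmentation); the normalized density restores the injected mass.
#' @param seed integer seed consumed by [make_ground_truth] and
#'   [simulate_experiments]; `NULL` uses the current RNG state.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(dims = c(60, 10, 10), n_divisions = 2,
                             n_regions = 10, m = 40, injection_radius = 3,
                             sigma_true = default_sigma_grid()[5],
                             anchors_per_division = 8, noise_sd = 0.3,
                             detection_threshold = 1e-10,
                             heterogeneous = TRUE, add_identity = TRUE,
                             zero_injection_site = TRUE, seed = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L), n_divisions >= 1,
            n_regions >= n_divisions, m >= 1, injection_radius >= 0,
            sigma_true > 0, anchors_per_division >= 1, noise_sd >= 0,
            detection_threshold >= 0)
  if (dims[1] < n_divisions) stop("first axis shorter than division count")
  structure(list(dims = dims, n_divisions = n_divisions,
                 n_regions = n_regions, m = m,
                 injection_radius = injection_radius,
                 sigma_true = sigma_true,
                 anchors_per_division = anchors_per_division,
                 noise_sd = noise_sd,
                 detection_threshold = detection_threshold,
                 heterogeneous = heterogeneous,
                 add_identity = add_identity,
                 zero_injection_site = zero_injection_site, seed = seed),
            class = "synthetic_config")
}

#' Build a box lattice with nested slab parcellation
#'
#' Deterministically partitions a `dims[1] x dims[2] x dims[3]` box into
#' `n_divisions` contiguous slabs along the first axis; each division is
#' subdivided into its share of the `n_regions` regions as contiguous
#' bands along the second axis.
#'
#' @param config a [synthetic_config].
#' @return a [voxel_lattice].
#' @export
make_lattice <- function(config) {
  dims <- config$dims
  s <- config$n_divisions; r <- config$n_regions
  coords <- as.matrix(expand.grid(x = seq_len(dims[1]) - 1,
                                  y = seq_len(dims[2]) - 1,
                                  z = seq_len(dims[3]) - 1))
  storage.mode(coords) <- "double"
  # near-equal split of r regions over s divisions
  reg_per_div <- diff(round(seq(0, r, length.out = s + 1)))
  if (any(reg_per_div < 1)) stop("regions not partitionable over divisions")
  if (any(reg_per_div > dims[2])) {
    stop("second axis too short for the per-division region count")
  }
  div_of_x <- cut(coords[, 1], breaks = round(seq(0, dims[1],
                                                  length.out = s + 1)) - 0.5,
                  labels = FALSE, include.lowest = TRUE)
  region <- integer(nrow(coords))
  offset <- 0L
  for (k in seq_len(s)) {
    rk <- reg_per_div[k]
    in_div <- div_of_x == k
    band <- cut(coords[in_div, 2],
                breaks = round(seq(0, dims[2], length.out = rk + 1)) - 0.5,
                labels = FALSE, include.lowest = TRUE)
    region[in_div] <- offset + band
    offset <- offset + rk
  }
  voxel_lattice(coords, div_of_x, region)
}

#' Generate a smooth nonnegative ground-truth connectome
#'
#' Heterogeneous regime: for each division, `anchors_per_division` anchor
#' voxels are drawn with random nonnegative brain-wide target patterns;
#' each source column in the division is the Gaussian-kernel
#' (bandwidth `sigma_true`) Nadaraya-Watson interpolation of its
#' division's anchor patterns. Columns therefore vary smoothly with the
#' source voxel within a division and change sharply across division
#' boundaries (disjoint anchor sets). Homogeneous regime
#' (`heterogeneous = FALSE`): a random nonnegative r x r regional matrix
#' is spread uniformly over voxels, making columns constant within each
#' region. Optionally the identity is added (unit self-projection).
#'
#' The connectome is kept in factored form `W = P U (+ I)` with `P`
#' (n x a) the target patterns and `U` (a x n) column-stochastic,
#' division-blocked source weights; use [gt_column], [gt_apply] or
#' [gt_matrix] to query it.
#'
#' @param lattice a [voxel_lattice] (from [make_lattice]).
#' @param config a [synthetic_config]; `config$seed` (if non-NULL) seeds
#'   the generator.
#' @return An object of class `ground_truth`: list with `P`, `U`,
#'   `add_identity`, `heterogeneous`, `M` (the regional matrix, in the
#'   homogeneous regime) and `n`.
#' @export
make_ground_truth <- function(lattice, config) {
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  n <- lattice$n
  if (config$heterogeneous) {
    a_per <- config$anchors_per_division
    s <- lattice$n_divisions
    P <- matrix(0, n, a_per * s)
    U <- matrix(0, a_per * s, n)
    for (k in seq_len(s)) {
      vox_k <- which(lattice$division == k)
      anchors <- sample(vox_k, min(a_per, length(vox_k)))
      arange <- (k - 1) * a_per + seq_along(anchors)
      # sparse nonnegative brain-wide target patterns, lognormal amplitudes
      P[, arange] <- stats::rlnorm(n * length(anchors),
                                   meanlog = -3, sdlog = 1) *
        (stats::runif(n * length(anchors)) < 0.5)
      d2 <- outer(rowSums(lattice$coords[anchors, , drop = FALSE]^2),
                  rowSums(lattice$coords[vox_k, , drop = FALSE]^2), "+") -
        2 * lattice$coords[anchors, , drop = FALSE] %*%
        t(lattice$coords[vox_k, , drop = FALSE])
      d2[d2 < 0] <- 0
      K <- exp(-d2 / (2 * config$sigma_true^2))
      U[arange, vox_k] <- sweep(K, 2, colSums(K), "/")
    }
    M <- NULL
  } else {
    ops <- regionalization_operators(lattice)
    r <- lattice$n_regions
    M <- matrix(stats::rlnorm(r * r, meanlog = -1, sdlog = 1) *
                  (stats::runif(r * r) < 0.6), r, r)
    P <- as.matrix(ops$Pi_dagger %*% M)  # n x r
    U <- as.matrix(ops$Pi)               # r x n
  }
  structure(list(P = P, U = U, add_identity = config$add_identity,
                 heterogeneous = config$heterogeneous, M = M, n = n),
            class = "ground_truth")
}

#' Query the factored ground-truth connectome
#'
#' `gt_column` extracts one source column, `gt_apply` computes `W %*% X`
#' for a vector or matrix, and `gt_matrix` materializes the dense n x n
#' matrix (refusing to exceed `max_entries`).
#'
#' @param gt a `ground_truth` object.
#' @param j source voxel index.
#' @return `gt_column`: length-n vector.
#' @export
gt_column <- function(gt, j) {
  col <- as.numeric(gt$P %*% gt$U[, j])
  if (gt$add_identity) col[j] <- col[j] + 1
  col
}

#' @rdname gt_column
#' @param X length-n vector or n x k matrix.
#' @export
gt_apply <- function(gt, X) {
  out <- gt$P %*% (gt$U %*% X)
  if (gt$add_identity) out <- out + X
  if (is.null(dim(X))) as.numeric(out) else as.matrix(out)
}

#' @rdname gt_column
#' @param max_entries refuse materialization above this entry count.
#' @export
gt_matrix <- function(gt, max_entries = 5e7) {
  if (as.double(gt$n)^2 > max_entries) {
    stop("dense ground truth exceeds the memory budget")
  }
  W <- gt$P %*% gt$U
  if (gt$add_identity) W <- W + diag(gt$n)
  W
}

#' Simulate tracing experiments from a ground-truth connectome
#'
#' Draws `m` injection centroids (cycling through divisions so all are
#' populated; centroid voxels are distinct within a division while
#' possible), builds a spherical top-hat injection of the configured
#' radius clipped to the centroid's division, computes the projection
#' response `Y = W_true X`, optionally zeroes Y over the injection site
#' (the injection/projection split of real segmentation), applies
#' mean-preserving multiplicative lognormal noise to the remaining
#' signal, and zeroes entries below the detection threshold. Normalized
#' projection densities and centroids then follow the standard
#' construction.
#'
#' The returned set carries an attribute `centroid_spacing`: a data.frame
#' of the mean nearest-neighbor centroid distance per division, the
#' sampling-density diagnostic relevant to how far information must be
#' interpolated.
#'
#' @param gt a `ground_truth` from [make_ground_truth].
#' @param lattice the matching [voxel_lattice].
#' @param config a [synthetic_config]; `config$seed` (if non-NULL) seeds
#'   the simulation.
#' @return an [experiment_set] of `config$m` experiments.
#' @export
simulate_experiments <- function(gt, lattice, config) {
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  m <- config$m
  s <- lattice$n_divisions
  div_seq <- rep(seq_len(s), length.out = m)
  chosen <- integer(m)
  for (k in seq_len(s)) {
    slots <- which(div_seq == k)
    vox_k <- which(lattice$division == k)
    chosen[slots] <- if (length(vox_k) >= length(slots)) {
      sample(vox_k, length(slots))
    } else {
      sample(vox_k, length(slots), replace = TRUE)
    }
  }
  exps <- vector("list", m)
  for (e in seq_len(m)) {
    cvox <- chosen[e]
    k <- lattice$division[cvox]
    if (config$injection_radius > 0) {
      d2 <- colSums((t(lattice$coords) - lattice$coords[cvox, ])^2)
      site <- which(d2 <= config$injection_radius^2 &
                      lattice$division == k)
    } else {
      site <- cvox
    }
    X <- numeric(lattice$n)
    X[site] <- 1
    Y <- gt_apply(gt, X)
    if (config$zero_injection_site) Y[site] <- 0
    if (config$noise_sd > 0) {
      pos <- Y > 0
      Y[pos] <- Y[pos] * stats::rlnorm(sum(pos),
                                       meanlog = -config$noise_sd^2 / 2,
                                       sdlog = config$noise_sd)
    }
    Y[Y < config$detection_threshold] <- 0
    exps[[e]] <- tracing_experiment(X, Y, lattice)
  }
  out <- experiment_set(exps, lattice, allow_spanning = TRUE)
  cen <- experiment_centroids(out)
  spacing <- lapply(sort(unique(cen$divisions)), function(k) {
    idx <- which(cen$divisions == k)
    if (length(idx) < 2) {
      return(data.frame(division = k, mean_nn_distance = NA_real_))
    }
    D <- as.matrix(stats::dist(cen$centroids[idx, , drop = FALSE]))
    diag(D) <- Inf
    data.frame(division = k, mean_nn_distance = mean(apply(D, 1, min)))
  })
  attr(out, "centroid_spacing") <- do.call(rbind, spacing)
  out
}
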