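# fixtures built in code; all tiny

# a hand-sized lattice: dims x-by-y-by-z box, s division slabs along x,
# regions nested as y-bands (thin wrapper over the generator for brevity)
tiny_config <- function(dims = c(6, 6, 6), s = 2, r = 4, m = 6, ...) {
  synthetic_config(dims = dims, n_divisions = s, n_regions = r, m = m, ...)
}

tiny_lattice <- function(...) make_lattice(tiny_config(...))

# a two-experiment set in one division with controlled centroids:
# point injections at the given voxel indices, projections given as columns
point_experiments <- function(lattice, voxels, Y = NULL) {
  exps <- lapply(seq_along(voxels), function(i) {
    X <- numeric(lattice$n); X[voxels[i]] <- 1
    Yi <- if (is.null(Y)) stats::runif(lattice$n) else Y[, i]
    tracing_experiment(X, Yi, lattice)
  })
  experiment_set(exps, lattice, allow_spanning = TRUE)
}

# simulated set under a seeded config; returns list(cfg, lattice, gt, set)
simulated_fixture <- function(..., seed = 42) {
  cfg <- tiny_config(..., seed = seed)
  lat <- make_lattice(cfg)
  gt <- make_ground_truth(lat, cfg)
  es <- suppressMessages(simulate_experiments(gt, lat, cfg))
  list(cfg = cfg, lattice = lat, gt = gt, set = es)
}

# brute-force LOO reference: refit without experiment e, predict at its center
brute_force_loo <- function(es, sigma) {
  lat <- es$lattice
  ec <- experiment_centroids(es)
  sapply(seq_len(n_experiments(es)), function(e) {
    sub <- experiment_set(es$experiments[-e], lat, allow_spanning = TRUE)
    predict_projection(fit_kernel_model(sub, sigma), ec$voxels[e])
  })
}
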