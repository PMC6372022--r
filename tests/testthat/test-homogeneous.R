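test_that("one region, one experiment: exact scalar solve", {
  # X sums to 2, Y sums to 6 in a single region -> weight 6/2 = 3
  lat <- voxel_lattice(cbind(0:3, 0, 0), division = rep(1, 4),
                       region = rep(1, 4))
  e <- tracing_experiment(c(1, 1, 0, 0), c(0, 0, 2, 4), lat)
  hm <- fit_homogeneous(experiment_set(list(e), lat))
  expect_equal(hm$W[1, 1], 3)
})

test_that("noiseless regionally homogeneous data is recovered exactly", {
  fx <- simulated_fixture(dims = c(12, 8, 8), s = 2, r = 6, m = 24,
                          injection_radius = 2, noise_sd = 0,
                          heterogeneous = FALSE, add_identity = FALSE,
                          zero_injection_site = FALSE, seed = 43)
  hm <- suppressMessages(fit_homogeneous(fx$set))
  expect_lt(norm(hm$W - fx$gt$M, "F") / norm(fx$gt$M, "F"), 1e-6)
})

test_that("nonnegativity binds: a negative response gives a zero row", {
  XR <- matrix(c(1, 0.5, 2, 1), 1, 4)
  YR <- -XR
  fit <- kernelconn:::.fit_homogeneous_regional(XR, YR)
  expect_equal(fit$W[1, 1], 0)
})

test_that("fitted rows satisfy the NNLS optimality conditions", {
  fx <- simulated_fixture(dims = c(12, 8, 8), s = 2, r = 6, m = 20,
                          injection_radius = 2, noise_sd = 0.3, seed = 47)
  hm <- suppressMessages(fit_homogeneous(fx$set))
  ops <- regionalization_operators(fx$lattice)
  Xm <- vapply(fx$set$experiments, `[[`, numeric(fx$lattice$n), "X")
  Ym <- vapply(fx$set$experiments, `[[`, numeric(fx$lattice$n), "Y")
  XR <- as.matrix(ops$Pi %*% Xm)
  YR <- as.matrix(ops$Pi %*% Ym)
  C <- t(XR)
  scale <- max(colSums(C^2))
  for (i in seq_len(nrow(hm$W))) {
    w <- hm$W[i, ]
    grad <- as.numeric(crossprod(C, C %*% w - YR[i, ]))  # d/dw of 0.5||.||^2
    # KKT: gradient ~0 on the active set, >= 0 where w is pinned at 0
    expect_true(all(grad[w > 0] > -1e-6 * scale))
    expect_true(all(abs(grad[w > 0]) < 1e-6 * scale))
    expect_true(all(grad[w == 0] > -1e-6 * scale))
  }
})

test_that("homogeneous predictions are linear in the regionalized injection", {
  fx <- simulated_fixture(dims = c(12, 8, 8), s = 2, r = 6, m = 20,
                          injection_radius = 2, seed = 53)
  hm <- suppressMessages(fit_homogeneous(fx$set))
  ops <- regionalization_operators(fx$lattice)
  lat <- fx$lattice
  # unit injection fully inside region j returns column j
  j <- 3
  X <- as.numeric(lat$region == j) / sum(lat$region == j)
  expect_equal(predict_homogeneous(hm, X, ops), as.numeric(hm$W[, j]))
  # dense oracle on an arbitrary injection
  set.seed(1)
  X2 <- runif(lat$n)
  expect_equal(predict_homogeneous(hm, X2, ops),
               as.numeric(hm$W %*% as.numeric(ops$Pi %*% X2)))
  expect_error(predict_homogeneous(hm, X2[-1], ops), "length")
})

test_that("model comparison favors each model in its own regime", {
  run <- function(seed, hetero, radius) {
    cfg <- synthetic_config(dims = c(24, 12, 12), n_divisions = 2,
                            n_regions = 6, m = 36,
                            injection_radius = radius, sigma_true = 5,
                            anchors_per_division = 12, noise_sd = 0.2,
                            heterogeneous = hetero, seed = seed)
    lat <- make_lattice(cfg)
    gt <- make_ground_truth(lat, cfg)
    es <- suppressMessages(simulate_experiments(gt, lat, cfg))
    cvrep <- suppressWarnings(nested_cv(es))
    sig <- rep(mean(cvrep$sigma), lat$n_divisions)
    sig[cvrep$division] <- cvrep$sigma
    vm <- fit_kernel_model(es, sig)
    hm <- suppressMessages(fit_homogeneous(es))
    cmp <- suppressMessages(compare_models(vm, hm, es))
    d <- cmp$by_division
    list(wins = sum(d$voxel_region_mse_rel < d$homog_region_mse_rel),
         ndiv = nrow(d), cmp = cmp)
  }
  het <- run(1, hetero = TRUE, radius = 2)
  expect_gt(het$wins, het$ndiv / 2)
  hom <- run(1, hetero = FALSE, radius = 4)
  expect_lt(hom$wins, hom$ndiv / 2 + 1)
  # comparison report carries per-experiment explained variance in [0, 1]
  r2 <- het$cmp$by_experiment[, c("voxel_r2", "homog_r2")]
  expect_true(all(r2 >= 0 & r2 <= 1, na.rm = TRUE))
})
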