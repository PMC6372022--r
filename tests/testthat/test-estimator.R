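test_that("Gaussian kernel closed form and domain checks", {
  expect_equal(gaussian_kernel(0, 2), 1)
  expect_equal(gaussian_kernel(3, 3), exp(-1 / 2))
  expect_equal(gaussian_kernel(2, 1), exp(-2))
  expect_true(all(diff(gaussian_kernel(0:10, 2)) < 0))
  expect_error(gaussian_kernel(1, 0), "sigma")
  expect_error(gaussian_kernel(-1, 1), "nonnegative")
})

test_that("coefficients are division-blocked, nonnegative, column-stochastic", {
  fx <- simulated_fixture(m = 6, seed = 11)
  A <- compute_coefficients(fx$set, 3)
  lat <- fx$lattice
  ec <- experiment_centroids(fx$set)
  expect_true(all(A >= 0))
  expect_equal(colSums(A), rep(1, lat$n), tolerance = 1e-12)
  # experiments never influence voxels outside their centroid's division
  for (e in seq_len(n_experiments(fx$set))) {
    other <- lat$division != ec$divisions[e]
    expect_true(all(A[e, other] == 0))
  }
})

test_that("coefficient toy cases match the closed form", {
  lat <- voxel_lattice(cbind(0:3, 0, 0), division = rep(1, 4),
                       region = rep(1, 4))
  # single experiment: weight 1 everywhere in its division
  es1 <- point_experiments(lat, 2)
  expect_equal(compute_coefficients(es1, 1), matrix(1, 1, 4))
  # two experiments at distances 1 and 2 from voxel at x = 1, sigma = 1
  es2 <- point_experiments(lat, c(1, 4))  # centroids x = 0 and x = 3
  A <- compute_coefficients(es2, 1)
  a1 <- exp(-0.5) / (exp(-0.5) + exp(-2))
  expect_equal(A[, 2], c(a1, 1 - a1), tolerance = 1e-12)
  expect_equal(a1, 0.8175745, tolerance = 1e-6)
  # equidistant voxel gets a 50/50 split
  pm <- voxel_lattice(cbind(c(0, 1, 2), 0, 0), division = rep(1, 3),
                      region = rep(1, 3))
  Aeq <- compute_coefficients(point_experiments(pm, c(1, 3)), 1)
  expect_equal(Aeq[, 2], c(0.5, 0.5))
})

test_that("a division without experiments yields zero columns and a warning", {
  lat <- tiny_lattice(dims = c(6, 2, 2), s = 2, r = 2)
  vox1 <- which(lat$division == 1)[1]
  es <- point_experiments(lat, vox1)
  expect_warning(A <- compute_coefficients(es, 2), "no injections")
  expect_true(all(A[, lat$division == 2] == 0))
  model <- suppressWarnings(fit_kernel_model(es, 2))
  expect_error(predict_projection(model, which(lat$division == 2)[1]),
               "no model support")
})

test_that("predictions are convex combinations of the division's patterns", {
  fx <- simulated_fixture(m = 6, seed = 13)
  model <- fit_kernel_model(fx$set, 2.5)
  lat <- fx$lattice
  ec <- experiment_centroids(fx$set)
  for (k in 1:2) {
    j <- which(lat$division == k)[5]
    p <- predict_projection(model, j)
    Yk <- model$Ybar[, ec$divisions == k, drop = FALSE]
    expect_true(all(p >= apply(Yk, 1, min) - 1e-12))
    expect_true(all(p <= apply(Yk, 1, max) + 1e-12))
  }
})

test_that("sigma limits: nearest-injection at 0+, division mean at infinity", {
  fx <- simulated_fixture(m = 6, seed = 17, injection_radius = 0,
                          noise_sd = 0)
  model_small <- fit_kernel_model(fx$set, 1e-3)
  ec <- experiment_centroids(fx$set)
  for (e in c(1, 4)) {
    expect_equal(predict_projection(model_small, ec$voxels[e]),
                 fx$set$experiments[[e]]$Ybar, tolerance = 1e-10)
  }
  model_big <- fit_kernel_model(fx$set, 1e6)
  lat <- fx$lattice
  for (k in 1:2) {
    in_k <- ec$divisions == k
    mean_pattern <- rowMeans(model_big$Ybar[, in_k, drop = FALSE])
    j <- which(lat$division == k)[3]
    expect_equal(predict_projection(model_big, j), mean_pattern,
                 tolerance = 1e-9)
  }
})

test_that("divisions are decoupled: permuting one leaves the other alone", {
  fx <- simulated_fixture(m = 8, seed = 19)
  lat <- fx$lattice
  ec <- experiment_centroids(fx$set)
  in2 <- which(ec$divisions == 2)
  perm <- seq_len(n_experiments(fx$set))
  perm[in2] <- rev(in2)
  es_perm <- experiment_set(fx$set$experiments[perm], lat,
                            allow_spanning = TRUE)
  m1 <- fit_kernel_model(fx$set, 2)
  m2 <- fit_kernel_model(es_perm, 2)
  j <- which(lat$division == 1)[7]
  expect_equal(predict_projection(m1, j), predict_projection(m2, j))
})

test_that("virtual injections average columns through the factorization", {
  fx <- simulated_fixture(m = 6, seed = 23)
  model <- fit_kernel_model(fx$set, 2)
  lat <- fx$lattice
  sources <- which(lat$division == 1)[c(2, 9, 17)]
  # singleton reduces to a plain column prediction
  expect_equal(virtual_injection(model, sources[1]),
               predict_projection(model, sources[1]))
  # mean of explicit columns (dense oracle)
  dense <- sapply(sources, function(j) predict_projection(model, j))
  expect_equal(virtual_injection(model, sources), rowMeans(dense),
               tolerance = 1e-12)
  expect_error(virtual_injection(model, integer(0)), "empty")
})

test_that("materialized blocks tile the dense product", {
  fx <- simulated_fixture(dims = c(5, 4, 3), s = 1, r = 2, m = 4, seed = 29)
  model <- fit_kernel_model(fx$set, 2)
  n <- fx$lattice$n
  W <- materialize_submatrix(model, seq_len(n), seq_len(n))
  expect_equal(W, model$Ybar %*% model$A, tolerance = 1e-12)
  expect_equal(materialize_submatrix(model, 3, 5)[1, 1], W[5, 3])
  blocks <- cbind(materialize_submatrix(model, 1:2, seq_len(n)),
                  materialize_submatrix(model, 3:n, seq_len(n)))
  expect_equal(blocks, W)
  expect_error(materialize_submatrix(model, seq_len(n), seq_len(n),
                                     max_entries = 10), "budget")
})

test_that("nearby sources give nearby predictions (source smoothness)", {
  fx <- simulated_fixture(m = 8, seed = 31)
  model <- fit_kernel_model(fx$set, 3)
  lat <- fx$lattice
  j <- which(lat$division == 1)[1]
  adjacent <- which(lat$division == 1 &
                      sqrt(colSums((t(lat$coords) - lat$coords[j, ])^2)) == 1)
  far <- which(lat$division == 1)
  far <- far[which.max(colSums((t(lat$coords[far, ]) - lat$coords[j, ])^2))]
  pj <- predict_projection(model, j)
  d_adj <- max(sapply(adjacent, function(i)
    sqrt(sum((predict_projection(model, i) - pj)^2))))
  d_far <- sqrt(sum((predict_projection(model, far) - pj)^2))
  expect_lt(d_adj, d_far)
})
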