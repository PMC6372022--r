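test_that("relative error metrics reproduce the worked scalar example", {
  # prediction 1 vs truth 0.25: bounded metric ~106%, classical ratio 900%
  expect_equal(mse_rel(1, 0.25), 2 * (1 - 0.25)^2 / (1 + 0.25^2) * 100)
  expect_equal(round(mse_rel(1, 0.25)), 106)
  expect_equal(naive_relative_mse(1, 0.25), 900)
  expect_equal(mse_rel(2, 2), 0)
  expect_equal(naive_relative_mse(2 * c(1, 3), c(1, 3)), 100)
})

test_that("mse_rel is symmetric, scale-free, and capped at 200", {
  set.seed(1)
  for (i in 1:5) {
    a <- runif(20); b <- runif(20)
    expect_equal(mse_rel(a, b), mse_rel(b, a))
    expect_equal(mse_rel(3.7 * a, 3.7 * b), mse_rel(a, b),
                 tolerance = 1e-12)
    expect_equal(mse_rel(a, numeric(20)), 200)
    expect_lte(mse_rel(a, b), 200)
  }
  expect_error(mse_rel(numeric(3), numeric(3)), "zero")
  expect_error(mse_rel(1:3, 1:4), "shape")
  expect_error(naive_relative_mse(1:3, numeric(3)), "zero")
})

test_that("mse_rel approximates the classical ratio for small errors", {
  set.seed(2)
  Y <- runif(50, 0.5, 1)
  delta <- runif(50, -1, 1)
  delta <- delta / sqrt(sum(delta^2)) * 0.05 * sqrt(sum(Y^2))
  eps2 <- sum(delta^2) / sum(Y^2)  # ~2.5e-3
  expect_equal(mse_rel(Y + delta, Y) / naive_relative_mse(Y + delta, Y),
               1, tolerance = 2 * eps2)
})

test_that("closed-form LOO coefficients match their definition", {
  # two experiments: each must predict from the other, regardless of sigma
  A2 <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2)
  expect_equal(unclass(loo_coefficients(A2))[1:2, 1:2],
               matrix(c(0, 1, 1, 0), 2, 2))
  # columns renormalize to 1 with a zero diagonal
  set.seed(3)
  K <- matrix(runif(25), 5, 5)
  Ac <- sweep(K, 2, colSums(K), "/")
  Acv <- loo_coefficients(Ac)
  expect_equal(diag(Acv), numeric(5))
  expect_equal(colSums(Acv), rep(1, 5))
  # a lone experiment (diagonal 1) is flagged and zeroed
  Alone <- diag(1, 3); Alone[, 2] <- c(0.5, 0.4, 0.1)
  Alone[2, c(1, 3)] <- 0; Alone[1, 1] <- 1; Alone[3, 3] <- 1
  expect_warning(out <- loo_coefficients(Alone), "no LOO support")
  expect_identical(attr(out, "no_loo_support"), c(1L, 3L))
  expect_equal(out[, 1], numeric(3))
})

test_that("closed-form LOO equals brute-force refitting", {
  # several seeded fixtures spanning division counts and sizes
  specs <- list(list(m = 5, s = 2), list(m = 8, s = 2), list(m = 9, s = 3),
                list(m = 12, s = 3), list(m = 20, s = 2))
  for (i in seq_along(specs)) {
    fx <- simulated_fixture(dims = c(9, 6, 6), s = specs[[i]]$s,
                            r = 2 * specs[[i]]$s, m = specs[[i]]$m,
                            injection_radius = 1, seed = 100 + i)
    Yhat <- loo_predictions(fx$set, 2.5)
    ref <- brute_force_loo(fx$set, 2.5)
    expect_lt(max(abs(Yhat - ref)), 1e-10)
  }
})

test_that("LOO limits: pairs swap patterns; sigma -> Inf averages the rest", {
  fx <- simulated_fixture(dims = c(8, 4, 4), s = 2, r = 2, m = 4,
                          injection_radius = 0, noise_sd = 0, seed = 5)
  ec <- experiment_centroids(fx$set)
  Ybar <- ybar_matrix(fx$set)
  stopifnot(all(tabulate(ec$divisions) == 2))  # 2 per division
  Yhat <- loo_predictions(fx$set, 3)
  for (e in seq_len(4)) {
    partner <- setdiff(which(ec$divisions == ec$divisions[e]), e)
    expect_equal(Yhat[, e], Ybar[, partner])
  }
  fx2 <- simulated_fixture(dims = c(8, 4, 4), s = 1, r = 2, m = 5,
                           injection_radius = 0, seed = 6)
  Yhat2 <- loo_predictions(fx2$set, 1e6)
  Ybar2 <- ybar_matrix(fx2$set)
  for (e in 1:5) {
    expect_equal(Yhat2[, e], rowMeans(Ybar2[, -e]), tolerance = 1e-9)
  }
})

test_that("the default bandwidth grid is 11 log-spaced values on [4, 50]", {
  g <- default_sigma_grid()
  expect_length(g, 11)
  expect_equal(g[1], 4)
  expect_equal(g[11], 50)
  expect_equal(diff(log(g)), rep(log(50 / 4) / 10, 10))
})

test_that("nested_cv with a single-point grid reduces to plain LOO", {
  fx <- simulated_fixture(m = 8, seed = 9)
  rep1 <- nested_cv(fx$set, sigma_grid = 3)
  Yhat <- loo_predictions(fx$set, 3)
  ec <- experiment_centroids(fx$set)
  Ybar <- ybar_matrix(fx$set)
  for (k in rep1$division) {
    idx <- which(ec$divisions == k)
    expect_equal(rep1$voxel_mse_rel[rep1$division == k],
                 mse_rel(Yhat[, idx], Ybar[, idx]))
    expect_equal(rep1$sigma[rep1$division == k], 3)
  }
  expect_error(nested_cv(fx$set, sigma_grid = numeric(0)), "nonempty")
})

test_that("divisions with too few experiments are skipped with a warning", {
  lat <- tiny_lattice(dims = c(8, 4, 4), s = 2, r = 2)
  vox <- c(which(lat$division == 1)[c(1, 10, 30)], which(lat$division == 2)[1])
  set.seed(10)
  es <- point_experiments(lat, vox)
  expect_warning(rep <- nested_cv(es, sigma_grid = c(2, 4)), "skipped")
  expect_identical(rep$division, 1L)
})

test_that("power to predict restricts the error to replicated regions", {
  # 6 experiments in one division: 2+2 in two regions, 2 singletons
  lat <- tiny_lattice(dims = c(8, 8, 2), s = 1, r = 4)
  regions <- lat$region
  vox <- c(which(regions == 1)[c(1, 5)], which(regions == 2)[c(2, 9)],
           which(regions == 3)[3], which(regions == 4)[7])
  set.seed(11)
  es <- point_experiments(lat, vox)
  Yhat <- loo_predictions(es, 3)
  ptp <- power_to_predict(es, Yhat)
  ops <- regionalization_operators(lat)
  YR_pred <- as.matrix(ops$Pi %*% Yhat)
  YR_true <- as.matrix(ops$Pi %*% ybar_matrix(es))
  expect_identical(ptp$n_replicated, 4L)
  expect_equal(ptp$ptp, mse_rel(YR_pred[, 1:4], YR_true[, 1:4]))
  # all regions distinct: empty subset reported as NA, not zero
  es_distinct <- point_experiments(lat, vox[c(1, 3, 5, 6)])
  Yd <- loo_predictions(es_distinct, 3)
  ptp_d <- power_to_predict(es_distinct, Yd)
  expect_true(is.na(ptp_d$ptp))
  # every experiment in one region: PTP equals the full division error
  es_same <- point_experiments(lat, which(regions == 1)[c(1, 4, 9)])
  Ys <- loo_predictions(es_same, 3)
  ptp_s <- power_to_predict(es_same, Ys)
  full <- mse_rel(as.matrix(ops$Pi %*% Ys),
                  as.matrix(ops$Pi %*% ybar_matrix(es_same)))
  expect_equal(ptp_s$ptp, full)
})
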