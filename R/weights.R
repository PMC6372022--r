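#' Inverse-gamma distribution
#'
#' Density, CDF and quantile function of the inverse-gamma distribution
#' with shape `a` and rate (scale of the reciprocal) `b`:
#' `f(x) = b^a / Gamma(a) * x^(-a-1) * exp(-b/x)` for `x > 0`. If
#' `Z ~ Gamma(shape = a, rate = b)` then `1/Z` follows this law. Provided
#' as a candidate family for connection-weight distribution fits.
#'
#' @param x,q,p numeric vectors.
#' @param shape,rate positive parameters.
#' @param log,lower.tail as in the standard distribution functions.
#' @return numeric vector.
#' @export
dinvgamma <- function(x, shape, rate, log = FALSE) {
  out <- ifelse(x > 0,
                shape * base::log(rate) - lgamma(shape) -
                  (shape + 1) * base::log(x) - rate / x,
                -Inf)
  if (log) out else exp(out)
}

#' @rdname dinvgamma
#' @export
pinvgamma <- function(q, shape, rate, lower.tail = TRUE) {
  out <- ifelse(q > 0,
                stats::pgamma(1 / q, shape = shape, rate = rate,
                              lower.tail = FALSE), 0)
  if (lower.tail) out else 1 - out
}

#' @rdname dinvgamma
#' @export
qinvgamma <- function(p, shape, rate) {
  1 / stats::qgamma(1 - p, shape = shape, rate = rate)
}

#' @importFrom mclust Mclust mclustBIC
NULL

.filter_positive <- function(weights) {
  w <- as.numeric(weights)
  bad <- sum(!is.finite(w) | w <= 0)
  if (bad > 0) {
    message(sprintf("excluding %d nonpositive/non-finite value(s): zeros are absent connections, not weights",
                    bad))
  }
  w[is.finite(w) & w > 0]
}

#' Fit candidate distributions to connection weights
#'
#' Maximum-likelihood fits of four candidate families — lognormal,
#' inverse-gamma, exponential, normal — to a sample of positive
#' connection weights, ranked by the Bayesian information criterion
#' `BIC = -2 loglik + p log(N)`. The BIC-best family is then checked
#' with a Kolmogorov-Smirnov test against its fitted CDF, and a
#' Shapiro-Wilk normality test is run on the log10-transformed weights.
#' Nonpositive weights are excluded with a message (zeros encode absent
#' connections).
#'
#' Note the KS p-value is computed against the fitted CDF as if its
#' parameters were known; estimating them from the same sample biases the
#' p-value upward (anti-conservative rejection is not an issue, but
#' non-rejection is weaker evidence than the nominal level suggests).
#' The Shapiro-Wilk statistic is limited to 5000 observations; larger
#' samples are thinned to 5000 evenly spaced order statistics and the
#' report says so.
#'
#' @param weights numeric vector; at least 20 positive values.
#' @return An object of class `distribution_fit_report`: list with
#'   `fits` (data.frame: family, parameters, loglik, bic, with `NA` for
#'   families whose fit failed, e.g. under degenerate variance),
#'   `best_family`, `ks` (htest or NA), `shapiro_log10` (htest),
#'   `shapiro_subsampled` (logical), `n`.
#' @export
fit_weight_distributions <- function(weights) {
  w <- .filter_positive(weights)
  N <- length(w)
  if (N < 20) stop("need at least 20 positive weights")

  families <- list(
    lognormal = list(dist = "lnorm", npar = 2, start = NULL),
    invgamma = list(dist = "invgamma", npar = 2,
                    start = local({
                      mu <- mean(w); v <- stats::var(w)
                      a <- max(mu^2 / v + 2, 2.1)
                      list(shape = a, rate = mu * (a - 1))
                    })),
    exponential = list(dist = "exp", npar = 1, start = NULL),
    normal = list(dist = "norm", npar = 2, start = NULL))

  rows <- list(); pars <- list()
  for (fam in names(families)) {
    f <- families[[fam]]
    fit <- tryCatch(suppressWarnings({
      if (is.null(f$start)) fitdistrplus::fitdist(w, f$dist)
      else fitdistrplus::fitdist(w, f$dist, start = f$start,
                                 optim.method = "L-BFGS-B",
                                 lower = c(1e-8, 1e-8))
    }), error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$loglik)) {
      rows[[fam]] <- data.frame(family = fam, loglik = NA_real_,
                                bic = NA_real_)
      pars[[fam]] <- NULL
    } else {
      rows[[fam]] <- data.frame(family = fam, loglik = fit$loglik,
                                bic = -2 * fit$loglik + f$npar * log(N))
      pars[[fam]] <- fit$estimate
    }
  }
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  if (all(is.na(fits$bic))) stop("no candidate family could be fitted")
  best <- fits$family[which.min(fits$bic)]

  ks <- tryCatch({
    est <- as.list(pars[[best]])
    pfun <- switch(best, lognormal = "plnorm", invgamma = "pinvgamma",
                   exponential = "pexp", normal = "pnorm")
    suppressWarnings(do.call(stats::ks.test, c(list(w, pfun), est)))
  }, error = function(e) NA)

  lw <- log10(w)
  sub <- N > 5000
  if (sub) lw <- sort(lw)[round(seq(1, N, length.out = 5000))]
  shap <- tryCatch(stats::shapiro.test(lw), error = function(e) NA)

  structure(list(fits = fits, parameters = pars, best_family = best,
                 ks = ks, shapiro_log10 = shap, shapiro_subsampled = sub,
                 n = N),
            class = "distribution_fit_report")
}

#' @export
print.distribution_fit_report <- function(x, ...) {
  cat(sprintf("distribution_fit_report on %d positive weights; BIC-best family: %s\n",
              x$n, x$best_family))
  print(x$fits, row.names = FALSE)
  invisible(x)
}

#' Gaussian mixture model on log10 connection weights
#'
#' Fits univariate Gaussian mixtures with unequal component variances to
#' `log10(weights)` for each candidate component count and selects the
#' count minimizing `BIC = -2 loglik + p log(N)`. The EM fits are
#' initialized by model-based hierarchical clustering, which is
#' deterministic, so repeated calls reproduce the same selection.
#'
#' @param weights positive connection weights (nonpositive values are
#'   excluded with a message).
#' @param k_range candidate component counts (default 1:6, spanning the
#'   unimodal-to-multimodal range relevant for brain-wide vs
#'   within-division weight sets).
#' @return list with `k` (selected count), `bic` (data.frame per k; `NA`
#'   rows for counts whose EM failed, with a warning), `means`,
#'   `variances`, `proportions` of the selected mixture, `n`.
#' @export
fit_log_weight_gmm <- function(weights, k_range = 1:6) {
  w <- .filter_positive(weights)
  N <- length(w)
  if (N < 20) stop("need at least 20 positive weights")
  k_range <- as.integer(k_range)
  lw <- log10(w)
  fits <- list(); bics <- numeric(0)
  for (k in k_range) {
    fit <- tryCatch(
      suppressWarnings(Mclust(lw, G = k, modelNames = "V",
                              verbose = FALSE)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$loglik)) {
      warning(sprintf("GMM with %d component(s) did not converge; skipped", k))
      bics <- c(bics, NA_real_)
      fits[[as.character(k)]] <- NULL
    } else {
      bics <- c(bics, -2 * fit$loglik + fit$df * log(N))
      fits[[as.character(k)]] <- fit
    }
  }
  if (all(is.na(bics))) stop("no mixture size converged")
  k_best <- k_range[which.min(bics)]
  best <- fits[[as.character(k_best)]]
  par <- best$parameters
  list(k = k_best,
       bic = data.frame(k = k_range, bic = bics),
       means = as.numeric(par$mean),
       variances = as.numeric(par$variance$sigmasq),
       proportions = as.numeric(par$pro),
       n = N)
}

#' Pairwise distances between region centroids
#'
#' Euclidean distances (lattice units) between the voxel-coordinate
#' centroids of all regions: the inter-region distance used by the
#' distance-dependence analysis.
#'
#' @param lattice a [voxel_lattice].
#' @return r x r symmetric matrix.
#' @export
region_distance_matrix <- function(lattice) {
  cent <- apply(lattice$coords, 2, function(col)
    tapply(col, lattice$region, mean))
  as.matrix(stats::dist(cent))
}

#' Distance dependence of connection weights
#'
#' Fits the decay of extant (positive) connection weights with
#' inter-region distance three ways: (i) linear least squares in log-log
#' space, `log10(weight) = beta1 * log10(distance) + beta0`; (ii) a
#' power law `w = a * d^beta` by Levenberg-Marquardt nonlinear least
#' squares on the linear scale; (iii) an exponential decay
#' `w = a * exp(-d / lambda)`, also Levenberg-Marquardt. RMSEs of the
#' two nonlinear fits are on the weight scale and directly comparable;
#' the log-log fit's RMSE is on the log10 scale and labelled as such.
#'
#' @param weights,distances paired vectors; pairs with nonpositive weight
#'   or distance are dropped; at least 3 pairs must remain.
#' @return An object of class `distance_fit_report`: list with
#'   `loglog` (`beta0`, `beta1`, `rmse_log10`), `power` (`a`, `beta`,
#'   `rmse`) and `exponential` (`a`, `lambda`, `rmse`); a nonlinear fit
#'   that fails to converge yields `NA` entries with a warning.
#' @export
fit_distance_dependence <- function(weights, distances) {
  if (length(weights) != length(distances)) stop("paired vectors required")
  ok <- is.finite(weights) & is.finite(distances) & weights > 0 &
    distances > 0
  w <- as.numeric(weights[ok]); d <- as.numeric(distances[ok])
  if (length(w) < 3) stop("need at least 3 extant weight-distance pairs")

  ll <- stats::lm(log10(w) ~ log10(d))
  beta0 <- unname(stats::coef(ll)[1]); beta1 <- unname(stats::coef(ll)[2])
  rmse_log <- sqrt(mean(stats::resid(ll)^2))

  rmse <- function(fit) sqrt(mean(stats::resid(fit)^2))
  pow <- tryCatch({
    fit <- minpack.lm::nlsLM(w ~ a * d^b,
                             start = list(a = 10^beta0, b = beta1),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    list(a = unname(stats::coef(fit)["a"]),
         beta = unname(stats::coef(fit)["b"]), rmse = rmse(fit))
  }, error = function(e) {
    warning("power-law LM fit did not converge")
    list(a = NA_real_, beta = NA_real_, rmse = NA_real_)
  })
  el <- stats::lm(log(w) ~ d)
  expo <- tryCatch({
    lam0 <- unname(-1 / min(stats::coef(el)[2], -1e-8))
    fit <- minpack.lm::nlsLM(w ~ a * exp(-d / lambda),
                             start = list(a = unname(exp(stats::coef(el)[1])),
                                          lambda = lam0),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    list(a = unname(stats::coef(fit)["a"]),
         lambda = unname(stats::coef(fit)["lambda"]), rmse = rmse(fit))
  }, error = function(e) {
    warning("exponential LM fit did not converge")
    list(a = NA_real_, lambda = NA_real_, rmse = NA_real_)
  })

  structure(list(loglog = list(beta0 = beta0, beta1 = beta1,
                               rmse_log10 = rmse_log),
                 power = pow, exponential = expo, n = length(w)),
            class = "distance_fit_report")
}

#' @export
print.distance_fit_report <- function(x, ...) {
  cat(sprintf("distance_fit_report (%d pairs)\n", x$n))
  cat(sprintf("  log-log linear: log10(w) = %.3f log10(d) + %.3f (RMSE %.3g, log10 scale)\n",
              x$loglog$beta1, x$loglog$beta0, x$loglog$rmse_log10))
  cat(sprintf("  power law (LM): w = %.3g * d^%.3f (RMSE %.3g)\n",
              x$power$a, x$power$beta, x$power$rmse))
  cat(sprintf("  exponential (LM): w = %.3g * exp(-d/%.3f) (RMSE %.3g)\n",
              x$exponential$a, x$exponential$lambda, x$exponential$rmse))
  invisible(x)
}
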