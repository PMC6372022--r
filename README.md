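# kernelconn

Voxel-scale brain connectome inference by division-restricted
Nadaraya–Watson kernel regression.

## What problem this solves

Anterograde viral tracing experiments label the outgoing axonal
projections of an injected brain location: each experiment yields a
per-voxel injection density `X` and projection density `Y` on a common
voxel lattice. With far fewer experiments than source voxels, estimating
a voxel-to-voxel connectivity matrix `W` such that `Y ≈ W X` requires a
structural assumption. This package implements the estimator built on
the assumption that **outgoing projection patterns vary smoothly with
the source voxel within each major brain division** and may change
sharply across division boundaries:

    W_ij = Σ_{e: c_e ∈ S_k} Ybar_ie · α_ej,
    α_ej = K_σ(‖v_j − c_e‖) / Σ_{f: c_f ∈ S_k} K_σ(‖v_j − c_f‖),

where `Ybar = (Y + X) / ΣX` is the normalized projection density, `c_e`
the injection centroid, `K_σ` a Gaussian kernel, and `S_k` the major
division containing source voxel `v_j`. The estimate is nonnegative, is
stored as the rank-m factorization `W = Ybar · A` without ever
materializing the n×n matrix, and its bandwidth `σ` is selected per
division by nested leave-one-out cross-validation using the closed-form
LOO identity available to linear smoothers.

Around the core estimator the package provides, as a coherent toolkit:

- bounded symmetric relative error (`mse_rel`, capped at 200%) and the
  *power to predict* (error restricted to replicated source regions);
- voxel→region aggregation operators and three regional weight
  normalizations (`regionalize_connectome`);
- a regionally homogeneous baseline fit by nonnegative least squares and
  a fold-matched model comparison (`fit_homogeneous`, `compare_models`);
- connection-weight distribution model selection by BIC, Gaussian
  mixtures on log weights, and power-law vs exponential distance-decay
  fits (`fit_weight_distributions`, `fit_log_weight_gmm`,
  `fit_distance_dependence`);
- a fully seeded synthetic-data generator — lattice, parcellation,
  smooth ground-truth connectome, simulated injections — so the entire
  pipeline is testable without any external dataset
  (`synthetic_config`, `make_lattice`, `make_ground_truth`,
  `simulate_experiments`).

Intended users: researchers working with mesoscale tracing data or
studying network-inference methodology who need a transparent, testable
reference implementation.

## Worked example

Simulate a heterogeneous ground truth, fit and cross-validate the kernel
model, and compare it with the homogeneous baseline:

```r
library(kernelconn)

cfg <- synthetic_config(dims = c(24, 12, 12), n_divisions = 2,
                        n_regions = 6, m = 36, injection_radius = 2,
                        sigma_true = 5, anchors_per_division = 12,
                        noise_sd = 0.2, seed = 7)
lattice <- make_lattice(cfg)
truth <- make_ground_truth(lattice, cfg)
experiments <- simulate_experiments(truth, lattice, cfg)

report <- nested_cv(experiments)
report[, c("division", "n_experiments", "sigma", "voxel_mse_rel",
           "region_mse_rel", "ptp")]
#>   division n_experiments sigma voxel_mse_rel region_mse_rel        ptp
#> 1        1            18     4      8.127184     0.02657992 0.02657992
#> 2        2            18     4      8.183468     0.02724336 0.02724336

model <- fit_kernel_model(experiments, report$sigma)
homog <- fit_homogeneous(experiments)
compare_models(model, homog, experiments)
#> model_comparison: voxel model lower Region MSE_rel in 2/2 divisions
#>  division n_experiments n_replicated voxel_region_mse_rel homog_region_mse_rel
#>         1            18           18           0.02657992           0.03680432
#>         2            18           18           0.02724336           0.03871456
```

Reading the numbers: the nested CV selected a bandwidth of 4 lattice
units in both divisions; held-out voxel-level error is ≈8% (bounded
scale, max 200%), dropping to ≈0.03% after aggregating predictions to
regions; and the kernel model predicts held-out experiments better than
the regionally homogeneous baseline in both divisions, as expected when
the ground truth varies within regions.

Regional weights and their distance dependence:

```r
wr <- regionalize_connectome(model, "norm_strength")
fit <- fit_distance_dependence(as.numeric(wr$values),
                               as.numeric(region_distance_matrix(lattice)))
fit$loglog$beta1   # log-log slope of weight vs inter-region distance
```

A thin command-line interface over the same functions ships in
`inst/scripts/kernelconn-cli.R` (subcommands `simulate`, `cv`,
`regionalize`, `fit-homog`, `analyze`).

## Documentation

Function-level documentation lives in the roxygen comments in `R/`. The
vignette `vignettes/voxel-connectome-methods.Rmd` explains the model,
the cross-validation protocol, the regional normalizations, the design
of the synthetic generator, and the package's numerical and statistical
design choices.
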