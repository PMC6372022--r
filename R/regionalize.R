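#' Voxel-to-region aggregation operators
#'
#' Builds the sparse aggregation operator `Pi` (r x n; row i indicates the
#' voxels of region i, so `Pi %*% x` sums a voxel vector over regions) and
#' its Moore-Penrose pseudoinverse `Pi_dagger` (n x r; entries
#' `1/|R_j|`, which spreads a regional vector evenly over each region's
#' voxels, or — acting from the right — averages over them). These satisfy
#' `Pi %*% Pi_dagger = I_r` exactly.
#'
#' @param lattice a [voxel_lattice].
#' @return An object of class `regionalization_operators`: list with
#'   sparse `Pi` (r x n), `Pi_dagger` (n x r) and `region_sizes`
#'   (voxel counts `|R_j|`).
#' @export
regionalization_operators <- function(lattice) {
  r <- lattice$n_regions
  n <- lattice$n
  Pi <- Matrix::sparseMatrix(i = lattice$region, j = seq_len(n), x = 1,
                             dims = c(r, n))
  sizes <- as.numeric(Matrix::rowSums(Pi))
  if (any(sizes == 0)) stop("every region must contain at least one voxel")
  Pi_dagger <- Matrix::t(Pi / sizes)
  structure(list(Pi = Pi, Pi_dagger = Pi_dagger, region_sizes = sizes),
            class = "regionalization_operators")
}

#' Aggregate a voxel vector to regions
#'
#' @param x length-n voxel vector.
#' @param ops a [regionalization_operators] object.
#' @param mode `"sum"` (`Pi %*% x`, regional totals) or `"mean"` (regional
#'   averages, i.e. the sum divided by region size).
#' @return length-r vector.
#' @export
regionalize_vector <- function(x, ops, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (length(x) != ncol(ops$Pi)) stop("x length does not match lattice")
  s <- as.numeric(ops$Pi %*% x)
  if (mode == "mean") s / ops$region_sizes else s
}

#' Regionalize the factored voxel connectome
#'
#' Aggregates `W = Ybar %*% A` to an r x r regional matrix through the
#' factorization — `(Pi %*% Ybar) %*% (A %*% t(Pi))` and variants — so the
#' n x n matrix W is never materialized. Three normalizations:
#' \describe{
#'   \item{`strength`}{`Pi W t(Pi)`: total connection weight between two
#'     regions; conserves the total weight of W.}
#'   \item{`norm_density`}{`t(Pi_dagger) W Pi_dagger`: strength divided by
#'     both the source and the target region size.}
#'   \item{`norm_strength`}{`Pi W Pi_dagger`: strength divided by the
#'     source region size only — the expected fluorescence volume in the
#'     target region per unit of virus in the source region, directly
#'     comparable with the homogeneous model.}
#' }
#'
#' @param model a `kernel_model`.
#' @param normalization one of `"strength"`, `"norm_density"`,
#'   `"norm_strength"`.
#' @return An object of class `regional_matrix`: list with `values`
#'   (dense r x r matrix), `normalization` and `region_sizes`.
#' @export
regionalize_connectome <- function(model,
                                   normalization = c("strength",
                                                     "norm_density",
                                                     "norm_strength")) {
  normalization <- match.arg(normalization)
  ops <- regionalization_operators(model$lattice)
  left <- switch(normalization,
                 strength = ops$Pi %*% model$Ybar,
                 norm_strength = ops$Pi %*% model$Ybar,
                 norm_density = Matrix::t(ops$Pi_dagger) %*% model$Ybar)
  right <- switch(normalization,
                  strength = model$A %*% Matrix::t(ops$Pi),
                  norm_strength = model$A %*% ops$Pi_dagger,
                  norm_density = model$A %*% ops$Pi_dagger)
  structure(list(values = as.matrix(left %*% right),
                 normalization = normalization,
                 region_sizes = ops$region_sizes),
            class = "regional_matrix")
}

#' @export
print.regional_matrix <- function(x, ...) {
  cat(sprintf("regional_matrix (%s): %d x %d, total weight %.4g\n",
              x$normalization, nrow(x$values), ncol(x$values),
              sum(x$values)))
  invisible(x)
}

#' Regionalized model prediction for one experiment
#'
#' Applies the aggregation operator to the voxel prediction at the
#' experiment's injection center: `Pi %*% W[, c_e]`. This is the
#' regionalized voxel model's prediction used for regional error and for
#' comparison with the homogeneous model.
#'
#' @param model a `kernel_model`.
#' @param experiment a [tracing_experiment] on the same lattice.
#' @return length-r vector.
#' @export
regionalized_prediction <- function(model, experiment) {
  ops <- regionalization_operators(model$lattice)
  as.numeric(ops$Pi %*% predict_projection(model, experiment$centroid_voxel))
}
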