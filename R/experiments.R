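#' Injection-density-weighted centroid of an injection
#'
#' The injection center of mass: the X-weighted mean of the voxel
#' coordinates over voxels with positive injection density.
#'
#' @param X length-n nonnegative injection-density vector.
#' @param lattice a [voxel_lattice].
#' @return numeric length-3 position (lattice units).
#' @export
compute_centroid <- function(X, lattice) {
  X <- as.numeric(X)
  if (length(X) != lattice$n) stop("X length does not match lattice")
  if (any(X < 0)) stop("injection density must be nonnegative")
  sx <- sum(X)
  if (sx <= 0) stop("empty injection: injection density sums to zero")
  as.numeric(crossprod(lattice$coords, X) / sx)
}

#' Normalized projection density
#'
#' The per-unit-virus projection pattern `(Y + X) / sum(X)`: the injection
#' pattern is included, so the result represents projections plus the
#' injected unit mass, normalized by total injected density.
#'
#' @param X length-n nonnegative injection-density vector with `sum(X) > 0`.
#' @param Y length-n nonnegative projection-density vector.
#' @return length-n nonnegative vector.
#' @export
normalize_projection <- function(X, Y) {
  X <- as.numeric(X); Y <- as.numeric(Y)
  if (length(X) != length(Y)) stop("X and Y must have equal length")
  if (any(X < 0) || any(Y < 0)) stop("densities must be nonnegative")
  sx <- sum(X)
  if (sx <= 0) stop("empty injection: injection density sums to zero")
  (Y + X) / sx
}

#' A single anterograde tracing experiment
#'
#' Bundles the injection density X, projection density Y, the derived
#' normalized projection density Ybar, the continuous injection centroid,
#' its snapped (nearest) lattice voxel and that voxel's division. Kernel
#' distances use the continuous centroid; the injection-center indicator
#' used by in-sample and leave-one-out predictions uses the snapped voxel.
#'
#' @param X,Y length-n nonnegative density vectors.
#' @param lattice a [voxel_lattice].
#' @return An object of class `tracing_experiment` with fields `X`, `Y`,
#'   `Ybar`, `centroid`, `centroid_voxel`, `centroid_division`.
#' @export
tracing_experiment <- function(X, Y, lattice) {
  X <- as.numeric(X); Y <- as.numeric(Y)
  if (length(X) != lattice$n || length(Y) != lattice$n) {
    stop("X/Y length does not match lattice voxel count")
  }
  centroid <- compute_centroid(X, lattice)
  cv <- nearest_voxel(lattice, centroid)
  structure(
    list(X = X, Y = Y, Ybar = normalize_projection(X, Y),
         centroid = centroid, centroid_voxel = cv,
         centroid_division = lattice$division[cv]),
    class = "tracing_experiment")
}

#' A set of tracing experiments on a shared lattice
#'
#' @param experiments list of [tracing_experiment] objects.
#' @param lattice the shared [voxel_lattice].
#' @param allow_spanning keep experiments whose injection density touches
#'   more than one major division? Default `FALSE`, mirroring the curation
#'   rule that removes injections with infected cell bodies in multiple
#'   divisions.
#' @return An object of class `experiment_set` with fields `experiments`
#'   and `lattice`. If curation drops experiments a message reports how
#'   many.
#' @export
experiment_set <- function(experiments, lattice, allow_spanning = FALSE) {
  if (length(experiments) < 1L) stop("need at least one experiment")
  ok <- vapply(experiments, inherits, logical(1), "tracing_experiment")
  if (!all(ok)) stop("all elements must be tracing_experiment objects")
  for (e in experiments) {
    if (length(e$X) != lattice$n) stop("experiment does not match lattice")
  }
  if (!allow_spanning) {
    spans <- vapply(experiments, function(e) {
      length(unique(lattice$division[e$X > 0])) > 1L
    }, logical(1))
    if (any(spans)) {
      message(sprintf("dropping %d experiment(s) with injection density in multiple divisions",
                      sum(spans)))
      experiments <- experiments[!spans]
      if (length(experiments) == 0L) {
        stop("all experiments span multiple divisions; none left")
      }
    }
  }
  structure(list(experiments = experiments, lattice = lattice),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  m <- length(x$experiments)
  divs <- table(factor(vapply(x$experiments, `[[`, integer(1),
                              "centroid_division"),
                       levels = seq_len(x$lattice$n_divisions)))
  cat(sprintf("experiment_set: %d experiments on %d voxels\n", m,
              x$lattice$n))
  cat("experiments per division:", paste(divs, collapse = " "), "\n")
  invisible(x)
}

#' @rdname experiment_set
#' @param x an `experiment_set`.
#' @export
n_experiments <- function(x) length(x$experiments)

#' Matrix of normalized projection densities (n x m)
#' @param x an `experiment_set`.
#' @return numeric n x m matrix; column e is experiment e's Ybar.
#' @export
ybar_matrix <- function(x) {
  vapply(x$experiments, `[[`, numeric(x$lattice$n), "Ybar")
}

#' Experiment centroids and their divisions
#' @param x an `experiment_set`.
#' @return list with `centroids` (m x 3), `voxels` (snapped voxel indices),
#'   `divisions` (division index per experiment).
#' @export
experiment_centroids <- function(x) {
  list(centroids = t(vapply(x$experiments, `[[`, numeric(3), "centroid")),
       voxels = vapply(x$experiments, `[[`, integer(1), "centroid_voxel"),
       divisions = vapply(x$experiments, `[[`, integer(1),
                          "centroid_division"))
}

# full-precision numeric formatting so CSV round-trips are bit exact
.fmt17 <- function(m) {
  out <- apply(m, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  out
}

#' Save / load an experiment set as a plain-text directory
#'
#' On-disk layout: `meta.json` (counts and voxel size), `lattice.csv`
#' (coords + labels) and `X.csv` / `Y.csv` (n x m density matrices, one
#' column per experiment). Numeric values are written with 17 significant
#' digits so that a save/load round trip reproduces every vector bit
#' exactly.
#'
#' @param x an `experiment_set`.
#' @param path directory to create/read.
#' @return `save_experiments` returns `path` invisibly; `load_experiments`
#'   returns an `experiment_set`.
#' @export
save_experiments <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  lat <- x$lattice
  m <- n_experiments(x)
  jsonlite::write_json(
    list(n = lat$n, m = m, n_divisions = lat$n_divisions,
         n_regions = lat$n_regions, voxel_size_um = lat$voxel_size_um),
    file.path(path, "meta.json"), auto_unbox = TRUE)
  fmt <- .fmt17(lat$coords)
  lat_dt <- data.table::data.table(x = fmt[, 1], y = fmt[, 2], z = fmt[, 3],
                                   division = lat$division,
                                   region = lat$region)
  data.table::fwrite(lat_dt, file.path(path, "lattice.csv"))
  Xm <- vapply(x$experiments, `[[`, numeric(lat$n), "X")
  Ym <- vapply(x$experiments, `[[`, numeric(lat$n), "Y")
  colnames(Xm) <- colnames(Ym) <- paste0("e", seq_len(m))
  data.table::fwrite(data.table::as.data.table(.fmt17(Xm)),
                     file.path(path, "X.csv"))
  data.table::fwrite(data.table::as.data.table(.fmt17(Ym)),
                     file.path(path, "Y.csv"))
  invisible(path)
}

#' @rdname save_experiments
#' @param allow_spanning passed to [experiment_set].
#' @export
load_experiments <- function(path, allow_spanning = FALSE) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  lat_dt <- data.table::fread(file.path(path, "lattice.csv"))
  lattice <- voxel_lattice(
    coords = as.matrix(lat_dt[, c("x", "y", "z")]),
    division = lat_dt$division, region = lat_dt$region,
    voxel_size_um = meta$voxel_size_um)
  Xm <- as.matrix(data.table::fread(file.path(path, "X.csv")))
  Ym <- as.matrix(data.table::fread(file.path(path, "Y.csv")))
  if (nrow(Xm) != lattice$n || nrow(Ym) != lattice$n) {
    stop(sprintf("density matrices have %d rows but lattice has %d voxels",
                 nrow(Xm), lattice$n))
  }
  exps <- lapply(seq_len(ncol(Xm)), function(e) {
    ex <- tryCatch(tracing_experiment(Xm[, e], Ym[, e], lattice),
                   error = function(err) {
                     stop(sprintf("experiment %d: %s", e,
                                  conditionMessage(err)), call. = FALSE)
                   })
    ex
  })
  experiment_set(exps, lattice, allow_spanning = allow_spanning)
}
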