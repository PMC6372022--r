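#' Voxel lattice with a two-level parcellation
#'
#' A `voxel_lattice` discretizes a brain volume into `n` cubic voxels, each
#' carrying a 3-D coordinate (in units of voxel side lengths; 100 um in the
#' Allen Mouse Brain Connectivity Atlas convention), a major-division label
#' and a region label. Divisions and regions each form a disjoint partition
#' of the voxels, and every region is nested inside exactly one division.
#'
#' @param coords numeric n x 3 matrix of voxel coordinates (lattice units).
#'   Rows must be unique.
#' @param division integer vector of length n; division label per voxel,
#'   values in `1:s`.
#' @param region integer vector of length n; region label per voxel, values
#'   in `1:r`. Each region must lie entirely within one division.
#' @param voxel_size_um physical voxel side length in micrometers (metadata
#'   only; all distances in the package are in lattice units).
#'
#' @return An object of class `voxel_lattice`: a list with elements
#'   `coords`, `division`, `region`, `n`, `n_divisions`, `n_regions`,
#'   `region_division` (length-r map region -> containing division) and
#'   `voxel_size_um`.
#' @export
voxel_lattice <- function(coords, division, region, voxel_size_um = 100) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  division <- as.integer(division)
  region <- as.integer(region)
  if (length(division) != n || length(region) != n) {
    stop("division and region labels must have one entry per voxel")
  }
  if (anyNA(division) || anyNA(region)) stop("labels must not contain NA")
  if (any(duplicated(coords))) stop("voxel coordinates must be unique")
  s <- max(division)
  r <- max(region)
  if (!setequal(unique(division), seq_len(s))) {
    stop("division labels must cover 1:s with no gaps")
  }
  if (!setequal(unique(region), seq_len(r))) {
    stop("region labels must cover 1:r with no gaps")
  }
  # nesting: each region must map to a single division
  region_division <- integer(r)
  for (j in seq_len(r)) {
    d <- unique(division[region == j])
    if (length(d) != 1L) {
      stop(sprintf("region %d spans %d divisions; regions must nest", j,
                   length(d)))
    }
    region_division[j] <- d
  }
  structure(
    list(coords = coords, division = division, region = region,
         n = n, n_divisions = s, n_regions = r,
         region_division = region_division,
         voxel_size_um = voxel_size_um),
    class = "voxel_lattice")
}

#' @export
print.voxel_lattice <- function(x, ...) {
  cat(sprintf("voxel_lattice: %d voxels, %d divisions, %d regions (%g um voxels)\n",
              x$n, x$n_divisions, x$n_regions, x$voxel_size_um))
  invisible(x)
}

#' Index of the lattice voxel nearest to a point
#'
#' Euclidean nearest voxel; ties are broken toward the lowest voxel index.
#'
#' @param lattice a [voxel_lattice].
#' @param point numeric length-3 position in lattice units.
#' @return integer voxel index.
#' @export
nearest_voxel <- function(lattice, point) {
  stopifnot(length(point) == 3L)
  d2 <- colSums((t(lattice$coords) - as.numeric(point))^2)
  which.min(d2)  # which.min returns the first (lowest-index) minimum
}
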